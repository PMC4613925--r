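test_that("zero-care baselines and saturation limits of the default family", {
  p <- fig5_params()
  expect_equal(mortality(0, "G", p), p$m_min)
  expect_equal(mortality(0, "P", p), p$rho_base * p$m_min)
  expect_equal(brood_productivity(0, p), p$b_min)
  # saturation of the productivity gain
  expect_equal(brood_productivity(1e4, p), p$b_min + p$alpha_B)
  expect_equal(competitiveness(0, p), p$f_min)
  # no parental effect: competitiveness flat at f_min
  p0 <- fig5_params(alpha_F = 0)
  expect_equal(competitiveness(c(0, 0.5, 3, 50), p0), rep(p0$f_min, 4))
})

test_that("grid checks: mortality convex, increasing, ordered; b and f concave increasing", {
  p <- fig5_params()
  cc <- seq(0, p$care_max, by = p$care_max / 60)
  mg <- mortality(cc, "G", p)
  mp <- mortality(cc, "P", p)
  expect_true(all(diff(mg, differences = 2) >= -1e-12))
  expect_true(all(diff(mp, differences = 2) >= -1e-12))
  expect_true(all(diff(mg) > 0) && all(diff(mp) > 0))
  expect_true(all(mp - mg > 0))          # poor strictly worse at every care level
  expect_true(all(mg > 0 & mg < 1 & mp > 0 & mp < 1))

  CC <- seq(0, 2 * p$care_max, length.out = 80)
  bb <- brood_productivity(CC, p)
  ff <- competitiveness(CC, p)
  expect_true(all(diff(bb) > 0) && all(diff(ff) > 0))
  expect_true(all(diff(bb, differences = 2) <= 1e-12))
  expect_true(all(diff(ff, differences = 2) <= 1e-12))
})

test_that("domain errors on invalid care inputs", {
  p <- fig5_params()
  expect_error(mortality(-0.1, "G", p), class = "carevol_domain_error")
  expect_error(mortality(p$care_max + 1, "P", p), class = "carevol_domain_error")
  expect_error(brood_productivity(-1, p), class = "carevol_domain_error")
  expect_error(competitiveness(-1e-6, p), class = "carevol_domain_error")
})

test_that("configuration errors on invalid parameter sets", {
  expect_error(care_params(g1 = 1.5), class = "carevol_config_error")
  expect_error(care_params(m_min = 0), class = "carevol_config_error")
  expect_error(care_params(m_min = 0.5, rho_base = 2.5),
               class = "carevol_config_error")  # baseline mortality >= 1
  expect_error(care_params(rho = 0.5), class = "carevol_config_error")
  expect_error(care_params(rho_base = 0.9), class = "carevol_config_error")
  expect_error(care_params(b_min = 0), class = "carevol_config_error")
  expect_error(care_params(alpha_F = -1), class = "carevol_config_error")
})

test_that("shape validation rejects families violating the model's assumptions", {
  # concave (square-root) mortality is not convex
  expect_error(
    care_params(mortality_fn = function(c, q)
      0.25 + 0.5 * sqrt(c / 5) + if (q == "P") 0.05 else 0,
      care_max = 2),
    class = "carevol_config_error")
  # identical mortality for both qualities violates strict ordering ...
  flat <- function(c, q) 0.3 + 0.5 * (c / 3)^2
  expect_error(care_params(mortality_fn = flat, care_max = 2),
               class = "carevol_config_error")
  # ... unless equality is explicitly allowed for symmetric-class analyses
  expect_s3_class(care_params(mortality_fn = flat, care_max = 2,
                              allow_equal_mortality = TRUE),
                  "care_params")
  # decreasing productivity is rejected
  expect_error(
    care_params(productivity_fn = function(C) 5 - 0.1 * C, care_max = 1),
    class = "carevol_config_error")
})

test_that("care_max defaults to just inside the mortality-certainty point", {
  p <- fig5_params()
  expect_equal(p$care_max, 0.95 * min(p$eta_G * p$beta_G, p$beta_P / p$rho))
  # the clamp is never active inside the box
  expect_lt(mortality(p$care_max, "P", p), 1 - 1e-6)
  expect_lt(mortality(p$care_max, "G", p), 1 - 1e-6)
})
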