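test_that("single-class limits collapse the demography", {
  p1 <- care_params(g1 = 1)
  d1 <- solve_demography(c(0.5, 0.4, 0.3, 0.2), p1)
  expect_equal(d1$g2, 1)
  expect_equal(d1$m_G, mortality(0.5, "G", p1))
  p0 <- care_params(g1 = 0)
  d0 <- solve_demography(c(0.5, 0.4, 0.3, 0.2), p0)
  expect_equal(d0$g2, 0)
  expect_equal(d0$m_P, mortality(0.2, "P", p0))
})

test_that("exchangeable quality classes give g2 = g1, m_G = m_P, v_G = v_P", {
  for (g1 in c(0.3, 0.5, 0.7)) {
    p <- symmetric_params(g1 = g1)
    rs <- resident_state(rep(0.8, 4), p)
    expect_equal(rs$demo$g2, g1, tolerance = 1e-12)
    expect_equal(rs$demo$m_G, rs$demo$m_P, tolerance = 1e-12)
    expect_equal(rs$rv$v_G, rs$rv$v_P, tolerance = 1e-10)
    expect_equal(rs$rv$v_G, 1, tolerance = 1e-10)  # normalization convention
  }
})

test_that("resident equilibrium satisfies its conservation and consistency laws", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_setting()
    rs <- resident_state(s$care, s$params)
    g1 <- s$params$g1
    # offspring-origin proportions sum to one
    expect_lt(abs(rs$brood$q_GG + rs$brood$q_GP + rs$brood$q_PP - 1), 1e-10)
    # normalized average lifetime reproductive success is one
    lrs <- (g1 / rs$demo$m_G) *
      (rs$demo$g2 * rs$brood$bp_GG + (1 - rs$demo$g2) * rs$brood$bp_GP) +
      ((1 - g1) / rs$demo$m_P) *
      (rs$demo$g2 * rs$brood$bp_GP + (1 - rs$demo$g2) * rs$brood$bp_PP)
    expect_lt(abs(lrs - 1), 1e-12)
    # equal success-odds ratios across pairings
    r <- c((1 - rs$qt$g_GG)^(1 / rs$qt$f_GG),
           (1 - rs$qt$g_GP)^(1 / rs$qt$f_GP),
           (1 - rs$qt$g_PP)^(1 / rs$qt$f_PP))
    expect_lt(diff(range(r)), 1e-10)
    # good-parent mass balance
    expect_lt(abs(rs$qt$g_GG * rs$brood$q_GG + rs$qt$g_GP * rs$brood$q_GP +
                  rs$qt$g_PP * rs$brood$q_PP - g1), 1e-10)
    # demographic fixed point holds
    expect_lt(abs(rs$demo$g2 -
                  (g1 / rs$demo$m_G) /
                  (g1 / rs$demo$m_G + (1 - g1) / rs$demo$m_P)), 1e-10)
    # resident projection matrix has eigenvalue 1
    expect_lt(abs(rs$rv$leading_eigenvalue - 1), 1e-8)
  }
})

test_that("quality transition depends only on the product kappa = k T", {
  p <- fig5_params()
  care <- c(0.9, 0.6, 0.2, 0.4)
  qt <- solve_quality_transition(care, params = p)
  # reconstructing g from any (k, T) split with the same product gives
  # identical probabilities
  for (k in c(0.01, 1, 37)) {
    T_ <- qt$kappa / k
    expect_equal(1 - exp(-k * T_ * qt$f_GG), qt$g_GG, tolerance = 1e-12)
    expect_equal(1 - exp(-k * T_ * qt$f_GP), qt$g_GP, tolerance = 1e-12)
    expect_equal(1 - exp(-k * T_ * qt$f_PP), qt$g_PP, tolerance = 1e-12)
  }
})

test_that("no care: flat productivity still normalizes mean fitness to one", {
  p <- fig5_params()
  rs <- resident_state(rep(0, 4), p)
  expect_equal(rs$brood$b_GG, p$b_min)
  expect_equal(rs$brood$b_GP, p$b_min)
  expect_equal(rs$brood$b_PP, p$b_min)
  expect_lt(abs(rs$rv$leading_eigenvalue - 1), 1e-10)
})

test_that("alpha_F = 0 collapses the quality transition to g1 exactly", {
  p <- fig5_params(alpha_F = 0)
  qt <- solve_quality_transition(c(1, 0.5, 0.2, 0.8) * p$care_max,
                                 params = p)
  expect_identical(c(qt$g_GG, qt$g_GP, qt$g_PP), rep(p$g1, 3))
  # equal total care in every pairing has the same consequence
  p5 <- fig5_params(alpha_F = 5)
  qt2 <- solve_quality_transition(rep(0.5, 4), params = p5)
  expect_equal(c(qt2$g_GG, qt2$g_GP, qt2$g_PP), rep(p5$g1, 3),
               tolerance = 1e-12)
})

test_that("reproductive values match an independent power-iteration oracle", {
  set.seed(11)
  for (i in 1:5) {
    s <- random_setting()
    rs <- resident_state(s$care, s$params)
    v_pi <- power_iteration(rs$M)
    v_pi <- v_pi / (s$params$g1 * v_pi[1] + (1 - s$params$g1) * v_pi[2])
    expect_equal(c(rs$rv$v_G, rs$rv$v_P), v_pi, tolerance = 1e-10)
  }
})

test_that("projection-matrix rows reproduce the reproductive-value recursions", {
  set.seed(13)
  s <- random_setting()
  rs <- resident_state(s$care, s$params)
  g2 <- rs$demo$g2; b <- rs$brood; q <- rs$qt
  v <- c(rs$rv$v_G, rs$rv$v_P)
  # hand-written recursion: per-mating genetic value of each class,
  # scaled by 2 to the package's genetic normalization
  vG <- 2 * 0.5 / rs$demo$m_G *
    (g2 * b$bp_GG * (q$g_GG * v[1] + (1 - q$g_GG) * v[2]) +
     (1 - g2) * b$bp_GP * (q$g_GP * v[1] + (1 - q$g_GP) * v[2]))
  vP <- 2 * 0.5 / rs$demo$m_P *
    (g2 * b$bp_GP * (q$g_GP * v[1] + (1 - q$g_GP) * v[2]) +
     (1 - g2) * b$bp_PP * (q$g_PP * v[1] + (1 - q$g_PP) * v[2]))
  expect_equal(c(vG, vP), v, tolerance = 1e-10)
})
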