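test_that("mutant identical to the resident reproduces the resident matrix", {
  set.seed(3)
  for (i in 1:5) {
    s <- random_setting()
    rs <- resident_state(s$care, s$params)
    for (mode in c("conflict", "no_conflict")) {
      Mh <- mutant_projection_matrix(s$care, rs, mode)
      expect_equal(Mh, rs$M, tolerance = 1e-14)
    }
  }
})

test_that("the resident is neutral against itself: invasion fitness one", {
  set.seed(5)
  for (i in 1:8) {
    s <- random_setting()
    rs <- resident_state(s$care, s$params)
    for (mode in c("conflict", "no_conflict")) {
      iv <- invasion_fitness(s$care, rs, mode)
      expect_lt(abs(iv$lambda - 1), 1e-8)
    }
  }
})

test_that("invasion fitness is continuous in the mutant strategy", {
  p <- fig5_params()
  care <- rep(0.4, 4)
  rs <- resident_state(care, p)
  lam0 <- invasion_fitness(care, rs, "conflict")$lambda
  hs <- 10^seq(-2, -7, by = -1)
  devs <- vapply(hs, function(h)
    abs(invasion_fitness(care + h, rs, "conflict")$lambda - lam0), numeric(1))
  expect_true(all(diff(devs) < 0))       # shrinks monotonically with h
  expect_lt(devs[length(devs)], 1e-6)
})

test_that("care invades a no-care population", {
  p <- fig5_params(alpha_F = 5)
  rs <- resident_state(rep(0, 4), p)
  s <- selection_gradient(rs, mode = "conflict")
  expect_true(all(s > 0))
  # brute-force scan: unilateral increases in care have invasion fitness > 1
  lam <- vapply(1:4, function(i) {
    ch <- rep(0, 4); ch[i] <- 0.2
    invasion_fitness(ch, rs, "conflict")$lambda
  }, numeric(1))
  expect_true(any(lam > 1))
})

test_that("finite-difference gradient agrees with Richardson extrapolation", {
  p <- fig5_params()
  care <- c(0.7, 0.75, 0.15, 0.2)
  rs <- resident_state(care, p)
  s <- selection_gradient(rs, mode = "conflict")
  # two-step central differences at h and h/2, Richardson-combined
  vfun <- function(ch, comp) {
    mh <- mutant_projection_matrix(ch, rs, "conflict")
    w <- mh %*% c(rs$rv$v_G, rs$rv$v_P)
    if (comp <= 2) w[1] else w[2]
  }
  for (i in 1:4) {
    h <- 1e-3
    d <- function(h) {
      cu <- care; cu[i] <- care[i] + h
      cd <- care; cd[i] <- care[i] - h
      (vfun(cu, i) - vfun(cd, i)) / (2 * h)
    }
    rich <- (4 * d(h / 2) - d(h)) / 3
    expect_equal(s[[i]], rich, tolerance = 1e-6)
  }
})

test_that("average care per brood weights pairings by their frequency", {
  expect_equal(average_care(rep(0.7, 4), g2 = 0.37), 1.4)   # equal care: 2c
  expect_equal(average_care(c(0.9, 0.2, 0.3, 0.1), g2 = 1), 1.8)  # only GG pairs
  expect_equal(average_care(c(0.9, 0.2, 0.3, 0.1), g2 = 0), 0.2)  # only PP pairs
  expect_error(average_care(rep(0.5, 4)), class = "carevol_domain_error")
})

test_that("gradient ascent converges to an equilibrium with vanishing gradient", {
  p <- fig5_params()
  fit <- ess_solve(p, mode = "conflict", tol = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
  expect_true(all(fit$care_star >= 0 & fit$care_star <= p$care_max))
  # re-solving from the solution terminates immediately
  fit2 <- ess_solve(p, mode = "conflict", c0 = fit$care_star, tol = 1e-6)
  expect_lt(fit2$iterations, 5)
  expect_equal(fit2$care_star, fit$care_star, tolerance = 1e-6)
})

test_that("widely spaced starting vectors reach the same equilibrium", {
  p <- fig5_params()
  starts <- list(rep(0.05, 4), rep(0.9, 4) * p$care_max,
                 c(0, p$care_max, 0, p$care_max))
  fits <- lapply(starts, function(c0)
    ess_solve(p, mode = "conflict", c0 = c0, tol = 1e-6))
  stars <- do.call(rbind, lapply(fits, coef))
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  expect_lt(max(apply(stars, 2, function(x) diff(range(x)))), 1e-3)
})

test_that("equilibria are invariant to the offspring-transmission scale", {
  p <- fig5_params()
  f1 <- ess_solve(p, mode = "no_conflict", tol = 1e-6)
  f2 <- ess_solve(p, mode = "no_conflict", tol = 1e-6, offspring_factor = 1)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
})

test_that("sweep over parental-effect strength is monotone and conflict-dominated", {
  p <- fig5_params()
  sw <- sweep_alpha_f(c(0, 5, 10), p, delta = 0.01, tol = 1e-6)
  expect_true(all(sw$converged))
  for (mode in c("conflict", "no_conflict"))
    expect_false(is.unsorted(sw$avg_care[sw$mode == mode]))
  byf <- split(sw, sw$alpha_F)
  for (d in byf)
    expect_gt(d$avg_care[d$mode == "no_conflict"],
              d$avg_care[d$mode == "conflict"])
})

test_that("ess_solve rejects degenerate single-class populations", {
  expect_error(ess_solve(care_params(g1 = 1)), class = "carevol_config_error")
})
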