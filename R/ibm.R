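# Autocorrelation-corrected batch-means standard error: block means of
# slowly mixing series (the pool composition relaxes over roughly
# pool_size / (2 m) events) are positively correlated, so the naive
# sd/sqrt(k) understates the error; inflate by the AR(1) long-run
# variance factor estimated from the lag-1 block correlation.
batch_se <- function(v) {
  k <- length(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(0)
  r1 <- suppressWarnings(stats::cor(v[-1], v[-k]))
  if (!is.finite(r1)) r1 <- 0
  r1 <- min(max(r1, 0), 0.95)
  s / sqrt(k) * sqrt((1 + r1) / (1 - r1))
}

# Delta-method standard error of a ratio of sums R = sum(x)/sum(y)
# over an autocorrelated epoch series: long-run variance of the
# residual series z = x - R*y under an AR(1) approximation.
ratio_se <- function(x, y, R) {
  z <- x - R * y
  n <- length(z)
  v <- stats::var(z)
  if (!is.finite(v) || v == 0 || sum(y) == 0) return(0)
  r1 <- suppressWarnings(stats::cor(z[-1], z[-n]))
  if (!is.finite(r1)) r1 <- 0
  r1 <- min(max(r1, 0), 0.95)
  sqrt(v * (1 + r1) / (1 - r1) * n) / sum(y)
}

#' Individual-based simulation of the resident life cycle
#'
#' Event-driven Monte Carlo implementation of the idealized life cycle:
#' a fixed-size, well-mixed adult pool; each breeding event pairs two
#' adults drawn at random (the first two individuals to reach a corpse);
#' the pair provides quality-dependent care, the brood yields a Poisson
#' number of maturing offspring with mean `b(total care)`, and each
#' parent then dies with probability `m_A(own care)`. Dead adults are
#' replaced, in recruitment epochs, by offspring sampled from the
#' epoch's cohort; recruits compete for good-parent development slots by
#' an exponential race (arrival time `Exp(rate = f)`), with the fastest
#' `g1` fraction becoming good parents -- the stochastic analogue of the
#' analytic quality transition with its fixed population-level quota.
#'
#' The simulator shares no code with the analytic equilibrium solver and
#' serves as its brute-force cross-check; its discretization error (a
#' fixed pool replenished per epoch rather than an infinite continuously
#' renewed population) shrinks with `pool_size`.
#'
#' @param care resident care vector `(c_GG, c_GP, c_PG, c_PP)`.
#' @param params a [care_params] object.
#' @param n_events number of breeding events (at least 1e4 for
#'   SE-based comparisons).
#' @param seed RNG seed; identical seed and configuration give bitwise
#'   identical summaries.
#' @param pool_size number of adults in the pool.
#' @param epoch_events breeding events per recruitment epoch; small
#'   epochs keep the within-epoch approximation (deaths applied at epoch
#'   end) negligible.
#' @param init_g2 initial good-parent share of the pool; defaults to
#'   `g1`. For cross-checks against the analytic equilibrium, seed at
#'   the analytic `g2`: the pool composition relaxes on a timescale of
#'   `pool_size / (2 * mortality)` events, so starting away from
#'   stationarity leaves a transient that the default burn-in only
#'   partially removes.
#' @param burn_frac fraction of events discarded as burn-in.
#' @param n_blocks number of post-burn-in blocks for batch-means
#'   standard errors (lag-1 autocorrelation corrected).
#' @return An object of class `care_sim` with elements `estimates` (a
#'   data frame of estimate and block SE for `g2_hat`, `m_G_hat`,
#'   `m_P_hat`, `q_GG_hat`, `q_GP_hat`, `q_PP_hat`,
#'   `mean_total_care`, `recruit_good_frac`) plus settings and flags.
#' @examples
#' \donttest{
#' p <- care_params()
#' sim <- simulate_resident(c(1, 1, 1, 1), p, n_events = 2e4, seed = 1)
#' sim$estimates
#' }
#' @export
simulate_resident <- function(care, params, n_events, seed = 1L,
                              pool_size = 10000L, epoch_events = 50L,
                              init_g2 = NULL, burn_frac = 0.1,
                              n_blocks = 20L) {
  care <- as_care_vector(care, params)
  if (n_events < 1e4)
    config_error("n_events must be at least 1e4 for SE-based summaries")
  set.seed(as.integer(seed))
  N <- as.integer(pool_size)
  E <- as.integer(epoch_events)
  n_epochs <- as.integer(ceiling(n_events / E))
  burn_epochs <- as.integer(ceiling(burn_frac * n_epochs))
  if (is.null(init_g2)) init_g2 <- params$g1

  # per-pairing constants: index 1 = GG, 2 = GP (good side), 3 = PG
  # (poor side of a mixed pair), 4 = PP
  m_pair <- c(mortality(care[["c_GG"]], "G", params),
              mortality(care[["c_GP"]], "G", params),
              mortality(care[["c_PG"]], "P", params),
              mortality(care[["c_PP"]], "P", params))
  tot_GG <- 2 * care[["c_GG"]]
  tot_GP <- care[["c_GP"]] + care[["c_PG"]]
  tot_PP <- 2 * care[["c_PP"]]
  b_type <- c(brood_productivity(tot_GG, params),
              brood_productivity(tot_GP, params),
              brood_productivity(tot_PP, params))
  f_type <- c(competitiveness(tot_GG, params),
              competitiveness(tot_GP, params),
              competitiveness(tot_PP, params))
  tot_type <- c(tot_GG, tot_GP, tot_PP)

  good <- c(rep(TRUE, round(init_g2 * N)),
            rep(FALSE, N - round(init_g2 * N)))
  quota_carry <- 0
  extinct_flag <- FALSE

  ep <- data.frame(part_G = numeric(n_epochs), part_P = numeric(n_epochs),
                   die_G = numeric(n_epochs), die_P = numeric(n_epochs),
                   care_sum = numeric(n_epochs), events = numeric(n_epochs),
                   rec_GG = numeric(n_epochs), rec_GP = numeric(n_epochs),
                   rec_PP = numeric(n_epochs), rec = numeric(n_epochs),
                   rec_good = numeric(n_epochs))

  # larval cohort of the previous epoch; recruiting from the *lagged*
  # cohort decouples recruitment intensity (deaths, driven by this
  # epoch's pairing mix) from the cohort's brood composition -- the
  # same-epoch coupling biases the recruit-origin proportions
  prev_cohort <- NULL

  for (e in seq_len(n_epochs)) {
    i1 <- sample.int(N, E, replace = TRUE)
    i2 <- sample.int(N, E, replace = TRUE)
    same <- i1 == i2
    while (any(same)) {          # a pair is two distinct adults
      i2[same] <- sample.int(N, sum(same), replace = TRUE)
      same <- i1 == i2
    }
    q1 <- good[i1]; q2 <- good[i2]
    type <- ifelse(q1 & q2, 1L, ifelse(q1 | q2, 2L, 3L))
    # own-side mortality index: good parent -> 1 (GG) or 2 (GP);
    # poor parent -> 3 (PG) or 4 (PP)
    mi1 <- ifelse(q1, ifelse(q2, 1L, 2L), ifelse(q2, 3L, 4L))
    mi2 <- ifelse(q2, ifelse(q1, 1L, 2L), ifelse(q1, 3L, 4L))
    brood_n <- stats::rpois(E, b_type[type])
    d1 <- stats::runif(E) < m_pair[mi1]
    d2 <- stats::runif(E) < m_pair[mi2]

    dead <- unique(c(i1[d1], i2[d2]))
    D <- length(dead)
    cohort <- if (!is.null(prev_cohort) && sum(prev_cohort$n) > 0)
      prev_cohort else list(type = type, n = brood_n)
    if (D > 0 && sum(cohort$n) > 0) {
      ev <- sample.int(length(cohort$n), D, replace = TRUE, prob = cohort$n)
      r_type <- cohort$type[ev]
      # exponential race for good-parent slots, fixed g1 quota
      want <- params$g1 * D + quota_carry
      n_good <- floor(want)
      quota_carry <- want - n_good
      t_arr <- stats::rexp(D, rate = f_type[r_type])
      r_good <- rep(FALSE, D)
      if (n_good > 0) r_good[order(t_arr)[seq_len(n_good)]] <- TRUE
      good[dead] <- r_good
      ep$rec_GG[e] <- sum(r_type == 1L)
      ep$rec_GP[e] <- sum(r_type == 2L)
      ep$rec_PP[e] <- sum(r_type == 3L)
      ep$rec[e] <- D
      ep$rec_good[e] <- sum(r_good)
    }
    prev_cohort <- list(type = type, n = brood_n)
    ep$part_G[e] <- sum(q1) + sum(q2)
    ep$part_P[e] <- 2 * E - ep$part_G[e]
    ep$die_G[e] <- sum(d1 & q1) + sum(d2 & q2)
    ep$die_P[e] <- sum(d1 & !q1) + sum(d2 & !q2)
    ep$care_sum[e] <- sum(tot_type[type])
    ep$events[e] <- E
    if (all(good) || !any(good)) extinct_flag <- TRUE
  }

  keep <- ep[(burn_epochs + 1):n_epochs, ]
  # ratio-of-sums estimate with a delta-method standard error: the
  # epoch series of X - R*Y is AR(1)-corrected (the pool composition
  # relaxes smoothly), giving a long-run variance with ~n_epochs
  # degrees of freedom
  agg <- function(x, y) {
    R <- sum(x) / sum(y)
    c(est = R, se = ratio_se(x, y, R))
  }
  est <- rbind(
    g2_hat = agg(keep$part_G, keep$part_G + keep$part_P),
    m_G_hat = agg(keep$die_G, keep$part_G),
    m_P_hat = agg(keep$die_P, keep$part_P),
    q_GG_hat = agg(keep$rec_GG, keep$rec),
    q_GP_hat = agg(keep$rec_GP, keep$rec),
    q_PP_hat = agg(keep$rec_PP, keep$rec),
    mean_total_care = agg(keep$care_sum, keep$events),
    recruit_good_frac = agg(keep$rec_good, keep$rec))
  estimates <- data.frame(estimate = est[, "est"], se = est[, "se"])

  structure(list(mode = "resident", estimates = estimates,
                 n_events = n_epochs * E, n_used = nrow(keep) * E,
                 pool_size = N, epoch_events = E, seed = as.integer(seed),
                 care = care, extinction_flag = extinct_flag),
            class = "care_sim")
}

#' Individual-based simulation of care evolution
#'
#' Same life cycle as [simulate_resident()], but each adult carries four
#' haploid care alleles (one per pairing context); a recruit inherits
#' each allele from one of its two parents at random (free
#' recombination) with a small Gaussian mutation, reflected into
#' `[0, care_max]`. Coparents are unrelated random draws from the pool,
#' so the simulated dynamics are the sexual-conflict scenario. After
#' burn-in, the time-averaged pool mean of each allele estimates the
#' evolutionarily stable care vector.
#'
#' @inheritParams simulate_resident
#' @param init_care initial (monomorphic) allele values.
#' @param mutation_sd per-birth mutation standard deviation; `0` freezes
#'   the alleles.
#' @param burn_frac fraction of events discarded before time-averaging
#'   (evolution needs a long transient; default one half).
#' @return An object of class `care_sim`; `allele_means` holds the
#'   time-averaged means and block SEs of the four care alleles, and
#'   `equilibrated` flags whether first- and second-half block means
#'   agree within three combined SEs.
#' @export
simulate_evolution <- function(params, n_events, seed = 1L,
                               pool_size = 2000L, epoch_events = 100L,
                               init_care = NULL, mutation_sd = 0.02,
                               init_g2 = NULL, burn_frac = 0.5,
                               n_blocks = 20L) {
  if (mutation_sd < 0) config_error("mutation_sd must be non-negative")
  if (is.null(init_care)) init_care <- rep(min(1, params$care_max), 4)
  init_care <- as_care_vector(init_care, params)
  set.seed(as.integer(seed))
  N <- as.integer(pool_size)
  E <- as.integer(epoch_events)
  n_epochs <- as.integer(ceiling(n_events / E))
  burn_epochs <- as.integer(ceiling(burn_frac * n_epochs))
  if (is.null(init_g2)) init_g2 <- params$g1
  cmax <- params$care_max

  good <- c(rep(TRUE, round(init_g2 * N)),
            rep(FALSE, N - round(init_g2 * N)))
  alleles <- matrix(rep(init_care, each = N), nrow = N)
  quota_carry <- 0
  allele_trace <- matrix(NA_real_, nrow = n_epochs, ncol = 4)

  reflect <- function(x) {
    x <- abs(x)
    x <- cmax - abs(cmax - x)
    pmin(pmax(x, 0), cmax)
  }

  # lagged larval cohort, as in simulate_resident(); parental alleles
  # are copied at breeding time since parents may die before
  # recruitment
  prev_cohort <- NULL

  for (e in seq_len(n_epochs)) {
    i1 <- sample.int(N, E, replace = TRUE)
    i2 <- sample.int(N, E, replace = TRUE)
    same <- i1 == i2
    while (any(same)) {
      i2[same] <- sample.int(N, sum(same), replace = TRUE)
      same <- i1 == i2
    }
    q1 <- good[i1]; q2 <- good[i2]
    # expressed allele: column 1 GG, 2 GP, 3 PG, 4 PP (own x partner)
    col1 <- ifelse(q1, ifelse(q2, 1L, 2L), ifelse(q2, 3L, 4L))
    col2 <- ifelse(q2, ifelse(q1, 1L, 2L), ifelse(q1, 3L, 4L))
    c1 <- alleles[cbind(i1, col1)]
    c2 <- alleles[cbind(i2, col2)]
    total <- c1 + c2
    m1 <- ifelse(q1, mortality(c1, "G", params), mortality(c1, "P", params))
    m2 <- ifelse(q2, mortality(c2, "G", params), mortality(c2, "P", params))
    brood_n <- stats::rpois(E, brood_productivity(total, params))
    d1 <- stats::runif(E) < m1
    d2 <- stats::runif(E) < m2

    dead <- unique(c(i1[d1], i2[d2]))
    D <- length(dead)
    cohort <- if (!is.null(prev_cohort) && sum(prev_cohort$n) > 0)
      prev_cohort else list(n = brood_n, total = total,
                            a1 = alleles[i1, , drop = FALSE],
                            a2 = alleles[i2, , drop = FALSE])
    if (D > 0 && sum(cohort$n) > 0) {
      ev <- sample.int(length(cohort$n), D, replace = TRUE, prob = cohort$n)
      f_rec <- competitiveness(cohort$total[ev], params)
      want <- params$g1 * D + quota_carry
      n_good <- floor(want)
      quota_carry <- want - n_good
      t_arr <- stats::rexp(D, rate = f_rec)
      r_good <- rep(FALSE, D)
      if (n_good > 0) r_good[order(t_arr)[seq_len(n_good)]] <- TRUE
      # haploid inheritance with free recombination + mutation
      from1 <- matrix(stats::runif(4 * D) < 0.5, nrow = D)
      inh <- ifelse(from1, cohort$a1[ev, , drop = FALSE],
                    cohort$a2[ev, , drop = FALSE])
      if (mutation_sd > 0)
        inh <- reflect(inh + stats::rnorm(4 * D, sd = mutation_sd))
      alleles[dead, ] <- inh
      good[dead] <- r_good
    }
    prev_cohort <- list(n = brood_n, total = total,
                        a1 = alleles[i1, , drop = FALSE],
                        a2 = alleles[i2, , drop = FALSE])
    allele_trace[e, ] <- colMeans(alleles)
  }

  keep <- allele_trace[(burn_epochs + 1):n_epochs, , drop = FALSE]
  block <- cut(seq_len(nrow(keep)), breaks = n_blocks, labels = FALSE)
  bm <- apply(keep, 2, function(col) tapply(col, block, mean))
  means <- colMeans(keep)
  ses <- apply(bm, 2, batch_se)
  half <- seq_len(floor(n_blocks / 2))
  drift <- abs(colMeans(bm[half, , drop = FALSE]) -
               colMeans(bm[-half, , drop = FALSE]))
  se_half <- sqrt(apply(bm[half, , drop = FALSE], 2, stats::var) /
                    length(half) +
                  apply(bm[-half, , drop = FALSE], 2, stats::var) /
                    (n_blocks - length(half)))
  allele_means <- data.frame(
    estimate = means, se = ses,
    row.names = c("c_GG", "c_GP", "c_PG", "c_PP"))

  structure(list(mode = "evolution", allele_means = allele_means,
                 equilibrated = all(drift <= 3 * se_half + 1e-12),
                 n_events = n_epochs * E, n_used = nrow(keep) * E,
                 pool_size = N, epoch_events = E, seed = as.integer(seed),
                 mutation_sd = mutation_sd, init_care = init_care),
            class = "care_sim")
}

#' @export
print.care_sim <- function(x, ...) {
  cat(sprintf("Individual-based simulation (%s mode): %d events, pool %d, seed %d\n",
              x$mode, x$n_events, x$pool_size, x$seed))
  if (x$mode == "resident") {
    print(round(x$estimates, 6))
    if (x$extinction_flag)
      cat("  warning: one quality class hit zero at some point; increase pool_size\n")
  } else {
    print(round(x$allele_means, 5))
    cat(sprintf("  equilibrated (no first/second half trend): %s\n",
                x$equilibrated))
  }
  invisible(x)
}
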