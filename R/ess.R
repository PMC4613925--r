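#' Projection matrix of a rare mutant strategy
#'
#' Builds the 2x2 matrix governing the growth of a rare mutant lineage
#' whose care vector differs from the resident's, against the resident
#' demographic background (pairing probabilities `g2`, productivity
#' normalization `b_bar` and race calibration `kappa` are all resident
#' quantities; the mutant is too rare to affect them).
#'
#' In `"conflict"` mode the mutant's partner is a resident: a mutant of
#' quality A paired with quality B provides `chat_AB`, its partner
#' provides the resident `c_BA`, the mutant suffers `m_A(chat_AB)`, the
#' brood yields `b(chat_AB + c_BA)` offspring of which a fraction
#' `ghat_AB = 1 - exp(-kappa * f(chat_AB + c_BA))` become good parents.
#' In `"no_conflict"` mode coparents are genetically identical, so the
#' partner expresses the mutant allele too and every total is
#' `chat_AB + chat_BA`; this removes sexual conflict while retaining
#' quality variation.
#'
#' At `mutant_care` equal to the resident care vector the matrix equals
#' the resident projection matrix exactly, in both modes.
#'
#' @param mutant_care mutant care vector `(c_GG, c_GP, c_PG, c_PP)`.
#' @param resident a [resident_state] snapshot.
#' @param mode `"conflict"` (partner is a resident) or `"no_conflict"`
#'   (partner carries the same mutant allele).
#' @param offspring_factor weight of the offspring term; the default 1/2
#'   is the parent-offspring relatedness. A uniform rescale (e.g. 1 for
#'   the r = 1 sensitivity variant) leaves all equilibria unchanged.
#' @return numeric 2x2 matrix.
#' @export
mutant_projection_matrix <- function(mutant_care, resident,
                                     mode = c("conflict", "no_conflict"),
                                     offspring_factor = 0.5) {
  mode <- match.arg(mode)
  params <- resident$params
  ch <- as_care_vector(mutant_care, params)
  c_res <- resident$care
  g2 <- resident$demo$g2
  kappa <- resident$qt$kappa
  b_bar <- resident$brood$b_bar

  # partner care per pairing, seen from the mutant's side
  if (mode == "conflict") {
    tot_GG <- ch[["c_GG"]] + c_res[["c_GG"]]
    tot_GP <- ch[["c_GP"]] + c_res[["c_PG"]]
    tot_PG <- ch[["c_PG"]] + c_res[["c_GP"]]
    tot_PP <- ch[["c_PP"]] + c_res[["c_PP"]]
  } else {
    tot_GG <- 2 * ch[["c_GG"]]
    tot_GP <- ch[["c_GP"]] + ch[["c_PG"]]
    tot_PG <- ch[["c_PG"]] + ch[["c_GP"]]
    tot_PP <- 2 * ch[["c_PP"]]
  }

  m_G <- g2 * mortality(ch[["c_GG"]], "G", params) +
    (1 - g2) * mortality(ch[["c_GP"]], "G", params)
  m_P <- g2 * mortality(ch[["c_PG"]], "P", params) +
    (1 - g2) * mortality(ch[["c_PP"]], "P", params)

  bp_GG <- brood_productivity(tot_GG, params) / b_bar
  bp_GP <- brood_productivity(tot_GP, params) / b_bar
  bp_PG <- brood_productivity(tot_PG, params) / b_bar
  bp_PP <- brood_productivity(tot_PP, params) / b_bar

  g_GG <- 1 - exp(-kappa * competitiveness(tot_GG, params))
  g_GP <- 1 - exp(-kappa * competitiveness(tot_GP, params))
  g_PG <- 1 - exp(-kappa * competitiveness(tot_PG, params))
  g_PP <- 1 - exp(-kappa * competitiveness(tot_PP, params))

  off <- offspring_factor / 0.5  # relative to the standard relatedness
  M11 <- off * 0.5 * 2 / m_G * (g2 * bp_GG * g_GG + (1 - g2) * bp_GP * g_GP)
  M12 <- off * 0.5 * 2 / m_G *
    (g2 * bp_GG * (1 - g_GG) + (1 - g2) * bp_GP * (1 - g_GP))
  M21 <- off * 0.5 * 2 / m_P * (g2 * bp_PG * g_PG + (1 - g2) * bp_PP * g_PP)
  M22 <- off * 0.5 * 2 / m_P *
    (g2 * bp_PG * (1 - g_PG) + (1 - g2) * bp_PP * (1 - g_PP))
  matrix(c(M11, M12, M21, M22), nrow = 2, byrow = TRUE,
         dimnames = list(c("G", "P"), c("G", "P")))
}

# One-generation mutant reproductive values: the mutant's expected
# production of the two offspring classes valued at resident reproductive
# values. Equals (v_G, v_P) when the mutant is the resident; its partial
# derivatives vanish exactly where the invasion-fitness gradient does.
mutant_values <- function(mutant_care, resident, mode,
                          offspring_factor = 0.5) {
  Mh <- mutant_projection_matrix(mutant_care, resident, mode,
                                 offspring_factor)
  v <- c(resident$rv$v_G, resident$rv$v_P)
  w <- Mh %*% v
  list(v_G = w[1], v_P = w[2], Mhat = Mh)
}

#' Invasion fitness of a rare mutant
#'
#' Dominant eigenvalue of the mutant projection matrix against the
#' resident background, together with the corresponding mutant
#' reproductive values (normalized like the resident ones). Equals 1
#' when the mutant strategy is the resident strategy.
#'
#' @inheritParams mutant_projection_matrix
#' @return list with `lambda`, `v_G`, `v_P`, `Mhat`.
#' @export
invasion_fitness <- function(mutant_care, resident,
                             mode = c("conflict", "no_conflict"),
                             offspring_factor = 0.5) {
  mode <- match.arg(mode)
  Mh <- mutant_projection_matrix(mutant_care, resident, mode,
                                 offspring_factor)
  e <- eigen(Mh)
  i <- which.max(Re(e$values))
  lambda <- Re(e$values[i])
  v <- Re(e$vectors[, i])
  if (all(v <= 0)) v <- -v
  g1 <- resident$params$g1
  v <- v / (g1 * v[1] + (1 - g1) * v[2])
  list(lambda = lambda, v_G = v[1], v_P = v[2], Mhat = Mh)
}

#' Selection gradient on the four care components
#'
#' Partial derivatives of a rare mutant's reproductive value with
#' respect to its own care components, evaluated at the resident
#' strategy: the gradient on `c_GG` and `c_GP` is taken through the
#' good-quality mutant value and the gradient on `c_PG` and `c_PP`
#' through the poor-quality mutant value. In `"no_conflict"` mode each
#' allele is expressed by both coparents, so a component can affect both
#' class values; there the gradient is the class-weighted total
#' derivative of `g1 vhat_G + (1 - g1) vhat_P`.
#'
#' Derivatives are central finite differences with step
#' `1e-6 * max(1, c)`, one-sided at the box boundaries.
#'
#' @param resident a [resident_state], or a care vector if `params` is
#'   given.
#' @param params a [care_params] object (ignored when `resident` is
#'   already a `resident_state`).
#' @inheritParams mutant_projection_matrix
#' @return named numeric vector `(s_GG, s_GP, s_PG, s_PP)`.
#' @export
selection_gradient <- function(resident, params = NULL,
                               mode = c("conflict", "no_conflict"),
                               offspring_factor = 0.5) {
  mode <- match.arg(mode)
  if (!inherits(resident, "resident_state"))
    resident <- resident_state(resident, params)
  params <- resident$params
  care <- resident$care
  g1 <- params$g1

  value_of <- function(ch, comp) {
    mv <- mutant_values(ch, resident, mode, offspring_factor)
    if (mode == "no_conflict") g1 * mv$v_G + (1 - g1) * mv$v_P
    else if (comp <= 2) mv$v_G else mv$v_P
  }
  s <- numeric(4)
  for (i in 1:4) {
    h <- 1e-6 * max(1, care[i])
    up <- min(care[i] + h, params$care_max)
    dn <- max(care[i] - h, 0)
    cu <- care; cu[i] <- up
    cd <- care; cd[i] <- dn
    s[i] <- (value_of(cu, i) - value_of(cd, i)) / (up - dn)
    if (!is.finite(s[i]))
      stop(errorCondition(
        sprintf("non-finite selection gradient in component %s", names(care)[i]),
        class = c("carevol_numeric_error", "carevol_error")))
  }
  names(s) <- c("s_GG", "s_GP", "s_PG", "s_PP")
  s
}

# KKT-projected gradient: zero out ascent directions blocked by the box.
effective_gradient <- function(s, care, care_max, eps = 1e-12) {
  at_lo <- care <= eps & s < 0
  at_hi <- care >= care_max - eps & s > 0
  s[at_lo | at_hi] <- 0
  s
}

#' Solve for evolutionarily stable care levels
#'
#' Locates the joint equilibrium of the four care components by
#' following the selection gradient: `c_{t+1} = c_t + delta * S(c_t)`,
#' with iterates projected onto the box `[0, care_max]^4`. Each step
#' re-solves the full resident equilibrium (demography, brood
#' normalization, quality transition, reproductive values) at the
#' current strategy. Convergence is declared on the gradient: the
#' KKT-projected gradient norm (components pinned at a boundary with the
#' gradient pointing outward are discounted) must fall below `tol`.
#'
#' @param params a [care_params] object with `g1` strictly inside
#'   (0, 1).
#' @param mode `"conflict"` (unrelated coparents) or `"no_conflict"`
#'   (coparents genetically identical, removing sexual conflict).
#' @param c0 starting care vector; default `(1, 1, 1, 1)` clamped to the
#'   box.
#' @param delta gradient-ascent step size (default 0.01).
#' @param tol convergence tolerance on the projected gradient norm
#'   (default 1e-8).
#' @param max_iter iteration cap.
#' @param offspring_factor see [mutant_projection_matrix()].
#' @param trace if positive, print the gradient norm every `trace`
#'   iterations.
#' @return An object of class `care_ess`: converged care vector
#'   `care_star`, resident snapshot at the solution, final gradient and
#'   its norm, iteration count, convergence flag and solver settings.
#' @examples
#' \donttest{
#' p <- care_params(alpha_F = 5)
#' fit <- ess_solve(p, mode = "conflict", tol = 1e-6)
#' coef(fit)
#' }
#' @export
ess_solve <- function(params, mode = c("conflict", "no_conflict"),
                      c0 = NULL, delta = 0.01, tol = 1e-8,
                      max_iter = 200000L, offspring_factor = 0.5,
                      trace = 0L) {
  mode <- match.arg(mode)
  if (params$g1 <= 0 || params$g1 >= 1)
    config_error("ess_solve requires g1 strictly inside (0, 1)")
  if (delta <= 0) config_error("delta must be positive")
  if (is.null(c0)) c0 <- rep(min(1, params$care_max), 4)
  care <- as_care_vector(pmin(pmax(c0, 0), params$care_max), params)
  c0 <- care

  iter <- 0L
  converged <- FALSE
  s_eff <- rep(NA_real_, 4)
  res <- NULL
  repeat {
    res <- tryCatch(resident_state(care, params), error = function(e) {
      stop(errorCondition(
        sprintf("resident solve failed at iteration %d: %s", iter,
                conditionMessage(e)),
        class = c("carevol_solver_error", "carevol_error")))
    })
    s <- selection_gradient(res, mode = mode,
                            offspring_factor = offspring_factor)
    s_eff <- effective_gradient(s, care, params$care_max)
    gnorm <- max(abs(s_eff))
    if (trace > 0 && iter %% trace == 0L)
      message(sprintf("iter %6d  |S| = %.3e  care = %s", iter, gnorm,
                      paste(sprintf("%.5f", care), collapse = " ")))
    if (gnorm < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    new_care <- pmin(pmax(care + delta * s, 0), params$care_max)
    if (max(abs(new_care - care)) < 1e-10 && gnorm >= tol) {
      care <- new_care
      break  # stalled below representable step without meeting tol
    }
    care <- new_care
    iter <- iter + 1L
  }

  structure(list(care_star = care, resident = res,
                 gradient = s_eff, gradient_norm = max(abs(s_eff)),
                 iterations = iter, converged = converged, mode = mode,
                 delta = delta, tol = tol, c0 = c0,
                 offspring_factor = offspring_factor,
                 params = params),
            class = "care_ess")
}

#' Average care received by a brood at a given strategy
#'
#' Expected total (both-parent) care per breeding event under the
#' resident pairing frequencies: pairings GG, GP and PP occur with
#' probabilities `g2^2`, `2 g2 (1 - g2)` and `(1 - g2)^2`, contributing
#' total care `2 c_GG`, `c_GP + c_PG` and `2 c_PP`.
#'
#' @param x a `care_ess` fit, a [resident_state], or a care vector (in
#'   which case `g2` must be supplied).
#' @param g2 good-parent share of the mating pool (only when `x` is a
#'   bare care vector).
#' @return scalar expected total care per brood.
#' @export
average_care <- function(x, g2 = NULL) {
  if (inherits(x, "care_ess")) {
    care <- x$care_star; g2 <- x$resident$demo$g2
  } else if (inherits(x, "resident_state")) {
    care <- x$care; g2 <- x$demo$g2
  } else {
    care <- x
    if (is.null(g2)) domain_error("g2 must be supplied with a bare care vector")
  }
  g2^2 * 2 * care[[1]] + 2 * g2 * (1 - g2) * (care[[2]] + care[[3]]) +
    (1 - g2)^2 * 2 * care[[4]]
}

#' @export
print.care_ess <- function(x, ...) {
  cat(sprintf("Evolutionarily stable care levels (%s mode)\n",
              sub("_", " ", x$mode)))
  cat("  care*:", paste(sprintf("%s = %.5f", names(x$care_star), x$care_star),
                        collapse = ", "), "\n")
  cat(sprintf("  converged: %s after %d iterations (|S| = %.2e, tol %.1e)\n",
              x$converged, x$iterations, x$gradient_norm, x$tol))
  invisible(x)
}

#' @export
coef.care_ess <- function(object, ...) object$care_star

#' @export
summary.care_ess <- function(object, ...) {
  out <- list(fit = object,
              g2 = object$resident$demo$g2,
              m_G = object$resident$demo$m_G,
              m_P = object$resident$demo$m_P,
              v_G = object$resident$rv$v_G,
              v_P = object$resident$rv$v_P,
              g_GG = object$resident$qt$g_GG,
              g_GP = object$resident$qt$g_GP,
              g_PP = object$resident$qt$g_PP,
              avg_care = average_care(object))
  class(out) <- "summary.care_ess"
  out
}

#' @export
print.summary.care_ess <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  g2 = %.5f, m_G = %.5f, m_P = %.5f\n", x$g2, x$m_G, x$m_P))
  cat(sprintf("  v_G = %.5f, v_P = %.5f\n", x$v_G, x$v_P))
  cat(sprintf("  quality transition: g_GG = %.4f, g_GP = %.4f, g_PP = %.4f\n",
              x$g_GG, x$g_GP, x$g_PP))
  cat(sprintf("  average care per brood = %.5f\n", x$avg_care))
  invisible(x)
}

#' Individual-based simulation at a fitted ESS
#'
#' Runs the resident-mode Monte Carlo simulator with the fitted care
#' vector, as a stochastic cross-check of the analytic equilibrium.
#'
#' @param object a `care_ess` fit.
#' @param nsim number of breeding events.
#' @param seed RNG seed.
#' @param ... passed to [simulate_resident()].
#' @return a `care_sim` summary (see [simulate_resident()]).
#' @export
simulate.care_ess <- function(object, nsim = 1e5, seed = 1L, ...) {
  simulate_resident(object$care_star, object$params, n_events = nsim,
                    seed = seed, ...)
}

#' Sweep of evolutionarily stable care over parental-effect strength
#'
#' Re-solves the ESS along a grid of `alpha_F` values (the strength of
#' the transgenerational parental effect), in conflict and/or
#' no-conflict mode, warm-starting each solve from the previous grid
#' point's solution.
#'
#' @param alpha_f increasing grid of parental-effect strengths.
#' @param params a [care_params] object; its own `alpha_F` is replaced
#'   by each grid value in turn.
#' @param modes subset of `c("conflict", "no_conflict")`.
#' @param delta,tol,max_iter,c0 passed to [ess_solve()] (`c0` seeds the
#'   first grid point of each mode).
#' @return An object of class `care_sweep`: a data frame with one row
#'   per (alpha_F, mode) holding the converged care vector, `g2`,
#'   mortalities, reproductive values, average care and diagnostics.
#'   Non-converged points are flagged, not fatal.
#' @export
sweep_alpha_f <- function(alpha_f, params,
                          modes = c("conflict", "no_conflict"),
                          delta = 0.01, tol = 1e-8, max_iter = 200000L,
                          c0 = NULL) {
  if (length(alpha_f) < 1L || any(diff(alpha_f) <= 0))
    config_error("alpha_f must be a non-empty strictly increasing grid")
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (mode in modes) {
    warm <- c0
    for (a in alpha_f) {
      pa <- params
      pa$alpha_F <- a
      validate_shapes(pa)
      fit <- ess_solve(pa, mode = mode, c0 = warm, delta = delta,
                       tol = tol, max_iter = max_iter)
      if (fit$converged) warm <- fit$care_star
      rows[[length(rows) + 1L]] <- data.frame(
        alpha_F = a, mode = mode,
        c_GG = fit$care_star[["c_GG"]], c_GP = fit$care_star[["c_GP"]],
        c_PG = fit$care_star[["c_PG"]], c_PP = fit$care_star[["c_PP"]],
        g2 = fit$resident$demo$g2,
        m_G = fit$resident$demo$m_G, m_P = fit$resident$demo$m_P,
        v_G = fit$resident$rv$v_G, v_P = fit$resident$rv$v_P,
        avg_care = average_care(fit),
        iterations = fit$iterations, converged = fit$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("care_sweep", "data.frame")
  out
}

#' @export
print.care_sweep <- function(x, ...) {
  cat("ESS sweep over parental-effect strength alpha_F\n")
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Plot average care against parental-effect strength
#'
#' Base-graphics rendering of a [sweep_alpha_f()] result: average care
#' per brood against `alpha_F`, circles for the conflict mode and
#' squares for the no-conflict mode.
#'
#' @param x a `care_sweep` object.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.care_sweep <- function(x, ...) {
  pchs <- c(conflict = 1, no_conflict = 0)
  graphics::plot(range(x$alpha_F), range(x$avg_care), type = "n",
                 xlab = expression(alpha[F] ~ "(strength of parental effects)"),
                 ylab = "average care received by a brood", ...)
  for (mode in unique(x$mode)) {
    d <- x[x$mode == mode, ]
    graphics::lines(d$alpha_F, d$avg_care, lty = 2)
    graphics::points(d$alpha_F, d$avg_care, pch = pchs[[mode]])
  }
  graphics::legend("topleft", legend = sub("_", " ", unique(x$mode)),
                   pch = pchs[unique(x$mode)], bty = "n")
  invisible(x)
}
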