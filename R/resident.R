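#' Demographic fixed point of a monomorphic resident population
#'
#' Solves for the composition of the mating pool. Pairing-specific
#' mortalities are `m_AB = m_A(c_AB)`; the class averages are
#' `m_G = g2 m_GG + (1 - g2) m_GP` and `m_P = g2 m_PG + (1 - g2) m_PP`,
#' and the good-parent share of mating adults must satisfy
#' `g2 = (g1 / m_G) / (g1 / m_G + (1 - g1) / m_P)` because each class
#' mates on average `1/m` times. The three relations are solved
#' simultaneously by a bracketed one-dimensional root-find in `g2` on
#' \[0, 1\].
#'
#' The degenerate single-class limits `g1 = 0` and `g1 = 1` are handled
#' directly (the absent class's average mortality is reported as `NA`).
#'
#' @param care care vector `(c_GG, c_GP, c_PG, c_PP)`: care provided by a
#'   parent of the first-subscript quality when paired with the
#'   second-subscript quality.
#' @param params a [care_params] object.
#' @return An object of class `demographic_state`: `g2`, `m_G`, `m_P` and
#'   the four pairing-specific mortalities.
#' @export
solve_demography <- function(care, params) {
  care <- as_care_vector(care, params)
  g1 <- params$g1
  m_GG <- mortality(care[["c_GG"]], "G", params)
  m_GP <- mortality(care[["c_GP"]], "G", params)
  m_PG <- mortality(care[["c_PG"]], "P", params)
  m_PP <- mortality(care[["c_PP"]], "P", params)

  out <- function(g2, m_G, m_P) {
    structure(list(g2 = g2, m_G = m_G, m_P = m_P,
                   m_GG = m_GG, m_GP = m_GP, m_PG = m_PG, m_PP = m_PP),
              class = "demographic_state")
  }
  if (g1 == 1) return(out(1, m_GG, NA_real_))
  if (g1 == 0) return(out(0, NA_real_, m_PP))

  residual <- function(g2) {
    m_G <- g2 * m_GG + (1 - g2) * m_GP
    m_P <- g2 * m_PG + (1 - g2) * m_PP
    g2 - (g1 / m_G) / (g1 / m_G + (1 - g1) / m_P)
  }
  # residual(0) = -share < 0 and residual(1) = 1 - share > 0: bracketed.
  sol <- stats::uniroot(residual, interval = c(0, 1), tol = 1e-14)
  g2 <- sol$root
  if (abs(residual(g2)) > 1e-10)
    stop(errorCondition(
      sprintf("demography root-find did not converge (residual %.3e)",
              residual(g2)),
      class = c("carevol_solver_error", "carevol_error")))
  out(g2, g2 * m_GG + (1 - g2) * m_GP, g2 * m_PG + (1 - g2) * m_PP)
}

#' Brood productivities, normalization and offspring-origin proportions
#'
#' Raw brood productivities are `b_AB = b(c_AB + c_BA)`. Average
#' lifetime reproductive success (each parent credited with its full
#' broods) is
#' `b_bar = (g1/m_G)[g2 b_GG + (1-g2) b_GP] + ((1-g1)/m_P)[g2 b_GP + (1-g2) b_PP]`
#' and normalized productivities are `bp_AB = b_AB / b_bar`, so that the
#' population-average normalized lifetime reproductive success is 1. The
#' proportions of newly mature offspring raised by each pairing type are
#' `q_GG = (g1/m_G) g2 bp_GG`,
#' `q_GP = [(g1/m_G)(1-g2) + ((1-g1)/m_P) g2] bp_GP`,
#' `q_PP = ((1-g1)/m_P)(1-g2) bp_PP`; they sum to one.
#'
#' @param care care vector.
#' @param demo a `demographic_state` solved for the same care vector
#'   (computed internally if missing).
#' @param params a [care_params] object.
#' @return An object of class `brood_table` with fields `b_*`, `b_bar`,
#'   `bp_*` and `q_*`.
#' @export
brood_table <- function(care, demo = NULL, params) {
  care <- as_care_vector(care, params)
  if (is.null(demo)) demo <- solve_demography(care, params)
  g1 <- params$g1
  b_GG <- brood_productivity(2 * care[["c_GG"]], params)
  b_GP <- brood_productivity(care[["c_GP"]] + care[["c_PG"]], params)
  b_PP <- brood_productivity(2 * care[["c_PP"]], params)
  g2 <- demo$g2

  if (g1 == 1) {
    b_bar <- b_GG / demo$m_G
    return(structure(list(b_GG = b_GG, b_GP = b_GP, b_PP = b_PP,
                          b_bar = b_bar, bp_GG = b_GG / b_bar,
                          bp_GP = NA_real_, bp_PP = NA_real_,
                          q_GG = 1, q_GP = 0, q_PP = 0),
                     class = "brood_table"))
  }
  if (g1 == 0) {
    b_bar <- b_PP / demo$m_P
    return(structure(list(b_GG = b_GG, b_GP = b_GP, b_PP = b_PP,
                          b_bar = b_bar, bp_GG = NA_real_,
                          bp_GP = NA_real_, bp_PP = b_PP / b_bar,
                          q_GG = 0, q_GP = 0, q_PP = 1),
                     class = "brood_table"))
  }

  wG <- g1 / demo$m_G          # lifetime matings of the good class
  wP <- (1 - g1) / demo$m_P
  b_bar <- wG * (g2 * b_GG + (1 - g2) * b_GP) +
           wP * (g2 * b_GP + (1 - g2) * b_PP)
  bp_GG <- b_GG / b_bar; bp_GP <- b_GP / b_bar; bp_PP <- b_PP / b_bar
  q_GG <- wG * g2 * bp_GG
  q_GP <- (wG * (1 - g2) + wP * g2) * bp_GP
  q_PP <- wP * (1 - g2) * bp_PP
  structure(list(b_GG = b_GG, b_GP = b_GP, b_PP = b_PP, b_bar = b_bar,
                 bp_GG = bp_GG, bp_GP = bp_GP, bp_PP = bp_PP,
                 q_GG = q_GG, q_GP = q_GP, q_PP = q_PP),
            class = "brood_table")
}

#' Transgenerational quality transition
#'
#' Maturing offspring compete for a limited number of good-parent
#' development opportunities; an offspring whose brood received total
#' care `C` has competitiveness `f(C)` and succeeds with probability
#' `g_AB = 1 - exp(-kappa * f_AB)` where `kappa = k T` is the product of
#' race intensity and competition time. Because the overall proportion
#' of recruits that become good parents is fixed at `g1`,
#' `g_GG q_GG + g_GP q_GP + g_PP q_PP = g1` pins down `kappa`
#' (the mass-balance residual is strictly increasing in `kappa`, so a
#' bracketed one-dimensional root-find always converges); the equal-ratio
#' relations `(1 - g_AB)^(1/f_AB)` then hold by construction. Only the
#' product `kappa = k T` matters, never `k` or `T` separately.
#'
#' When all pairings yield equal competitiveness (e.g. `alpha_F = 0`),
#' the transition collapses exactly to `g_AB = g1` for every pairing.
#'
#' @param care care vector.
#' @param brood a `brood_table` for the same care vector (computed
#'   internally if missing).
#' @param params a [care_params] object.
#' @return An object of class `quality_transition`: `g_GG`, `g_GP`,
#'   `g_PP`, `kappa`, and the competitiveness values `f_GG`, `f_GP`,
#'   `f_PP`.
#' @export
solve_quality_transition <- function(care, brood = NULL, params) {
  care <- as_care_vector(care, params)
  if (is.null(brood)) brood <- brood_table(care, params = params)
  g1 <- params$g1
  f_GG <- competitiveness(2 * care[["c_GG"]], params)
  f_GP <- competitiveness(care[["c_GP"]] + care[["c_PG"]], params)
  f_PP <- competitiveness(2 * care[["c_PP"]], params)
  f <- c(f_GG, f_GP, f_PP)
  q <- c(brood$q_GG, brood$q_GP, brood$q_PP)

  mk <- function(g, kappa) {
    structure(list(g_GG = g[1], g_GP = g[2], g_PP = g[3], kappa = kappa,
                   f_GG = f_GG, f_GP = f_GP, f_PP = f_PP),
              class = "quality_transition")
  }
  if (g1 == 1) return(mk(c(1, 1, 1), Inf))
  if (g1 == 0) return(mk(c(0, 0, 0), 0))
  if (diff(range(f)) < 1e-12) {
    # equal competitiveness: mass balance forces g_AB = g1 exactly
    return(mk(rep(g1, 3), -log(1 - g1) / mean(f)))
  }

  residual <- function(kappa) sum((1 - exp(-kappa * f)) * q) - g1
  lo <- 1e-8; hi <- 1
  while (residual(lo) > 0) lo <- lo / 10
  while (residual(hi) < 0) hi <- hi * 10
  kappa <- stats::uniroot(residual, c(lo, hi), tol = 1e-15)$root
  if (abs(residual(kappa)) > 1e-10)
    stop(errorCondition(
      sprintf("quality-transition root-find did not converge (residual %.3e)",
              residual(kappa)),
      class = c("carevol_solver_error", "carevol_error")))
  mk(1 - exp(-kappa * f), kappa)
}

#' Class projection matrix of the resident population
#'
#' The 2x2 matrix `M` mapping next-generation class reproductive values
#' to current ones, `(v_G, v_P)' = M (v_G, v_P)'`. Row A weights, over
#' the partner distribution (`g2`, `1 - g2`), the normalized genetic
#' brood share times the offspring quality split `g_AB` / `1 - g_AB`,
#' all multiplied by the expected number of matings `1/m_A`.
#'
#' The offspring term per brood is `relatedness * genetic_scale * bp_AB`
#' with relatedness 1/2 (an offspring carries the focal allele with
#' probability one half) and `genetic_scale = 2`. The scale-2 factor
#' converts the per-parent full-brood normalization (in which every brood
#' is credited to both of its parents, so the population-average
#' lifetime brood credit is 1 but the average *genetic* credit is 1/2)
#' into a genetic normalization in which the resident matrix has leading
#' eigenvalue exactly 1. Reproductive values and all equilibria are
#' invariant to this uniform scale.
#'
#' @param care care vector.
#' @param demo,brood,qt resident quantities for the same care vector
#'   (computed internally if missing).
#' @param params a [care_params] object.
#' @return numeric 2x2 matrix with dimnames `G`, `P`.
#' @export
projection_matrix <- function(care, demo = NULL, brood = NULL, qt = NULL,
                              params) {
  care <- as_care_vector(care, params)
  if (is.null(demo)) demo <- solve_demography(care, params)
  if (is.null(brood)) brood <- brood_table(care, demo, params)
  if (is.null(qt)) qt <- solve_quality_transition(care, brood, params)
  g2 <- demo$g2
  off <- 0.5 * 2  # relatedness x genetic scale (see description)
  M11 <- off / demo$m_G *
    (g2 * brood$bp_GG * qt$g_GG + (1 - g2) * brood$bp_GP * qt$g_GP)
  M12 <- off / demo$m_G *
    (g2 * brood$bp_GG * (1 - qt$g_GG) + (1 - g2) * brood$bp_GP * (1 - qt$g_GP))
  M21 <- off / demo$m_P *
    (g2 * brood$bp_GP * qt$g_GP + (1 - g2) * brood$bp_PP * qt$g_PP)
  M22 <- off / demo$m_P *
    (g2 * brood$bp_GP * (1 - qt$g_GP) + (1 - g2) * brood$bp_PP * (1 - qt$g_PP))
  matrix(c(M11, M12, M21, M22), nrow = 2, byrow = TRUE,
         dimnames = list(c("G", "P"), c("G", "P")))
}

#' Class reproductive values from the projection matrix
#'
#' Right eigenvector of `M` for the eigenvalue closest to 1 (which equals
#' 1 for a resident population, a consequence of the productivity
#' normalization), rescaled so `g1 v_G + (1 - g1) v_P = 1` to make values
#' comparable across parameter sets.
#'
#' @param M 2x2 projection matrix, e.g. from [projection_matrix()].
#' @param g1 good-parent share of newly mature adults (used only for the
#'   normalization convention).
#' @return An object of class `reproductive_values`: `v_G`, `v_P`, `M`,
#'   `leading_eigenvalue`.
#' @export
reproductive_values <- function(M, g1) {
  e <- eigen(M)
  if (any(Mod(Im(e$values)) > 1e-9))
    stop(errorCondition("projection matrix has complex eigenvalues",
                        class = c("carevol_numeric_error", "carevol_error")))
  vals <- Re(e$values)
  i <- which.min(abs(vals - 1))
  v <- Re(e$vectors[, i])
  if (all(v <= 0)) v <- -v
  if (any(v <= 0))
    stop(errorCondition(
      paste0("non-positive reproductive-value eigenvector; M = ",
             paste(signif(M, 6), collapse = " ")),
      class = c("carevol_numeric_error", "carevol_error")))
  v <- v / (g1 * v[1] + (1 - g1) * v[2])
  structure(list(v_G = v[1], v_P = v[2], M = M,
                 leading_eigenvalue = vals[i]),
            class = "reproductive_values")
}

#' Full resident equilibrium for a monomorphic care strategy
#'
#' Convenience wrapper chaining [solve_demography()], [brood_table()],
#' [solve_quality_transition()], [projection_matrix()] and
#' [reproductive_values()]; the returned snapshot is what the mutant
#' machinery in [selection_gradient()] and [ess_solve()] conditions on.
#'
#' @param care care vector `(c_GG, c_GP, c_PG, c_PP)`.
#' @param params a [care_params] object.
#' @return An object of class `resident_state` with components `care`,
#'   `params`, `demo`, `brood`, `qt`, `M`, `rv`.
#' @examples
#' p <- care_params()
#' rs <- resident_state(c(1, 1, 1, 1), p)
#' rs$demo$g2
#' rs$rv$leading_eigenvalue   # 1 up to round-off
#' @export
resident_state <- function(care, params) {
  care <- as_care_vector(care, params)
  demo <- solve_demography(care, params)
  brood <- brood_table(care, demo, params)
  qt <- solve_quality_transition(care, brood, params)
  if (params$g1 %in% c(0, 1)) {
    # single-class reduction: v = 1 for the present class
    rv <- structure(list(
      v_G = if (params$g1 == 1) 1 else NA_real_,
      v_P = if (params$g1 == 0) 1 else NA_real_,
      M = NULL, leading_eigenvalue = 1), class = "reproductive_values")
    return(structure(list(care = care, params = params, demo = demo,
                          brood = brood, qt = qt, M = NULL, rv = rv),
                     class = "resident_state"))
  }
  M <- projection_matrix(care, demo, brood, qt, params)
  rv <- reproductive_values(M, params$g1)
  structure(list(care = care, params = params, demo = demo, brood = brood,
                 qt = qt, M = M, rv = rv),
            class = "resident_state")
}

#' @export
print.resident_state <- function(x, ...) {
  cat("Resident equilibrium (resident_state)\n")
  cat("  care:", paste(sprintf("%s = %.4f", names(x$care), x$care),
                       collapse = ", "), "\n")
  cat(sprintf("  g2 = %.6f, m_G = %.6f, m_P = %.6f\n",
              x$demo$g2, x$demo$m_G, x$demo$m_P))
  cat(sprintf("  b_bar = %.6f; q = (%.4f, %.4f, %.4f)\n",
              x$brood$b_bar, x$brood$q_GG, x$brood$q_GP, x$brood$q_PP))
  cat(sprintf("  g_GG = %.4f, g_GP = %.4f, g_PP = %.4f (kappa = %.4g)\n",
              x$qt$g_GG, x$qt$g_GP, x$qt$g_PP, x$qt$kappa))
  cat(sprintf("  v_G = %.6f, v_P = %.6f (eigenvalue %.10f)\n",
              x$rv$v_G, x$rv$v_P, x$rv$leading_eigenvalue))
  invisible(x)
}

#' @export
print.demographic_state <- function(x, ...) {
  cat(sprintf("demographic_state: g2 = %.6f, m_G = %.6f, m_P = %.6f\n",
              x$g2, x$m_G, x$m_P))
  invisible(x)
}
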