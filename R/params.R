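#' Life-history parameters for the quality-structured care model
#'
#' Bundles the parameters of the three life-history functions --
#' quality-dependent mortality, brood productivity and offspring
#' competitiveness -- together with the proportion `g1` of newly mature
#' adults that are good parents. The default functional families are
#'
#' * mortality of a good parent:
#'   `m_G(c) = m_min + (1 - m_min) * (c / (eta_G * beta_G))^4` -- a
#'   flat-then-steep (quartic) cost curve: moderate care is nearly free
#'   for a resilient parent, but costs accelerate sharply beyond the
#'   onset scale `eta_G * beta_G`;
#' * mortality of a poor parent:
#'   `m_P(c) = rho_base * m_min + (1 - rho_base * m_min) * (rho * c / beta_P)^2`
#'   -- a slightly higher baseline (`rho_base`) and a quadratic cost
#'   paid from the very first unit of care at rate `rho`. Together the
#'   two curves give `m_G(c) < m_P(c)` pointwise on the care box while
#'   the *relative marginal* cost `m'(c)/m(c)` is lower for good
#'   parents, which is what lets good parents evolve substantially more
#'   care (and, through that care gap, higher realized mortality) at
#'   equilibrium. Both are clamped below `1 - 1e-6`;
#' * brood productivity:
#'   `b(C) = b_min + alpha_B * (1 - exp(-C / scale_B))`, concave,
#'   increasing, saturating at `b_min + alpha_B`;
#' * competitiveness:
#'   `f(C) = f_min + alpha_F * (1 - exp(-C / scale_F))`, concave,
#'   increasing, near-linear over the care box (`scale_F` is large);
#'   constant at `f_min` when `alpha_F = 0` (no parental effect on
#'   offspring quality).
#'
#' Alternative families can be plugged in through `mortality_fn`,
#' `productivity_fn` and `competitiveness_fn`; whatever family is used,
#' the shape properties the model assumes (convex increasing mortality
#' with `m_G < m_P` pointwise; concave increasing `b` and `f`) are
#' verified over a dense grid at construction time.
#'
#' @param g1 proportion of newly mature adults that are good parents,
#'   in (0, 1); the values 0 and 1 are accepted and collapse the model to
#'   a single quality class.
#' @param m_min baseline between-bout mortality of a good parent at zero
#'   care, in (0, 1).
#' @param beta_G,beta_P mortality cost scales for good and poor parents;
#'   positive. The care level at which mortality approaches certainty is
#'   `eta_G * beta_G` for good parents and `beta_P / rho` for poor ones.
#' @param rho poor-parent care-cost rate multiplier, `>= 1`: how many
#'   times faster a poor parent's mortality rises with care. The main
#'   quality-gap knob.
#' @param rho_base poor-parent baseline mortality multiplier, `>= 1`
#'   with `rho_base * m_min < 1`; kept close to 1 so the quality gap
#'   acts through the cost of caring rather than through baseline
#'   mortality.
#' @param eta_G onset fraction of the good-parent quartic cost curve,
#'   in (0, 1]; good-parent mortality reaches certainty at
#'   `eta_G * beta_G`.
#' @param b_min brood productivity with no care at all; positive.
#' @param alpha_B productivity gain scale (asymptotic extra productivity
#'   under abundant care); non-negative.
#' @param scale_B,scale_F saturation scales (in units of total care) of
#'   the productivity and competitiveness gains; positive.
#' @param f_min competitiveness of an offspring that received no care;
#'   positive.
#' @param alpha_F strength of the transgenerational parental effect: how
#'   strongly care received raises an offspring's competitiveness for
#'   good-parent development slots; non-negative.
#' @param care_max upper bound on a single parent's care. Defaults to
#'   `0.95 * min(eta_G * beta_G, beta_P / rho)`, just inside the care
#'   level at which mortality reaches certainty, so that the mortality
#'   clamp is never active inside the strategy box and extra care beyond
#'   the bound is never favoured. Must be given explicitly for custom
#'   mortality families.
#' @param allow_equal_mortality if `TRUE`, the pointwise mortality check
#'   accepts `m_G == m_P` (used for symmetric-class limiting analyses,
#'   e.g. `rho = 1` with equal betas); by default strict ordering
#'   `m_G < m_P` is required on the whole grid.
#' @param mortality_fn optional replacement family,
#'   `function(c, quality)` with `quality` `"G"` or `"P"`.
#' @param productivity_fn,competitiveness_fn optional replacement
#'   families, `function(total_care)`.
#' @param check_shapes run the grid-based shape validation (default
#'   `TRUE`).
#'
#' @return An object of class `care_params`.
#' @examples
#' p <- care_params()                  # Fig-5 style defaults
#' mortality(0, "P", p)                # rho * m_min
#' brood_productivity(0, p)            # b_min
#' @export
care_params <- function(g1 = 0.5,
                        m_min = 0.25,
                        beta_G = 5,
                        beta_P = 5,
                        rho = 4.5,
                        rho_base = 1.01,
                        eta_G = 0.36,
                        b_min = 1,
                        alpha_B = 5,
                        scale_B = 4,
                        f_min = 1,
                        alpha_F = 5,
                        scale_F = 10,
                        care_max = NULL,
                        allow_equal_mortality = FALSE,
                        mortality_fn = NULL,
                        productivity_fn = NULL,
                        competitiveness_fn = NULL,
                        check_shapes = TRUE) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      config_error(sprintf("'%s' must be a single finite number", nm))
    as.numeric(x)
  }
  g1 <- num1(g1, "g1"); m_min <- num1(m_min, "m_min")
  beta_G <- num1(beta_G, "beta_G"); beta_P <- num1(beta_P, "beta_P")
  rho <- num1(rho, "rho"); rho_base <- num1(rho_base, "rho_base")
  eta_G <- num1(eta_G, "eta_G"); b_min <- num1(b_min, "b_min")
  alpha_B <- num1(alpha_B, "alpha_B"); scale_B <- num1(scale_B, "scale_B")
  f_min <- num1(f_min, "f_min"); alpha_F <- num1(alpha_F, "alpha_F")
  scale_F <- num1(scale_F, "scale_F")

  if (g1 < 0 || g1 > 1)
    config_error("g1 must lie in [0, 1] (0 and 1 are single-class limits)")
  if (m_min <= 0 || m_min >= 1)
    config_error("m_min must lie strictly in (0, 1)")
  if (beta_G <= 0 || beta_P <= 0)
    config_error("beta_G and beta_P must be positive")
  if (rho < 1)
    config_error("rho must be >= 1 (poor parents cannot be cheaper carers)")
  if (rho_base < 1)
    config_error("rho_base must be >= 1 (poor parents cannot have lower baseline mortality)")
  if (rho_base * m_min >= 1)
    config_error(sprintf(
      "rho_base * m_min = %.4f must be < 1 (poor-parent zero-care mortality)",
      rho_base * m_min))
  if (eta_G <= 0 || eta_G > 1)
    config_error("eta_G must lie in (0, 1]")
  if (b_min <= 0 || f_min <= 0)
    config_error("b_min and f_min must be positive")
  if (alpha_B < 0 || alpha_F < 0)
    config_error("alpha_B and alpha_F must be non-negative")
  if (scale_B <= 0 || scale_F <= 0)
    config_error("scale_B and scale_F must be positive")

  if (is.null(care_max)) {
    if (!is.null(mortality_fn))
      config_error("care_max must be given explicitly for a custom mortality family")
    care_max <- 0.95 * min(eta_G * beta_G, beta_P / rho)
  } else {
    care_max <- num1(care_max, "care_max")
    if (care_max <= 0) config_error("care_max must be positive")
  }

  p <- structure(
    list(g1 = g1, m_min = m_min, beta_G = beta_G, beta_P = beta_P,
         rho = rho, rho_base = rho_base, eta_G = eta_G,
         b_min = b_min, alpha_B = alpha_B, scale_B = scale_B,
         f_min = f_min, alpha_F = alpha_F, scale_F = scale_F,
         care_max = care_max,
         allow_equal_mortality = isTRUE(allow_equal_mortality),
         mortality_fn = mortality_fn,
         productivity_fn = productivity_fn,
         competitiveness_fn = competitiveness_fn),
    class = "care_params")

  if (isTRUE(check_shapes)) validate_shapes(p)
  p
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("carevol_config_error", "carevol_error")))
}

domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("carevol_domain_error", "carevol_error")))
}

#' Between-bout mortality of a parent
#'
#' Probability that a parent dies during the search phase after providing
#' care `c` in the previous bout. Convex and increasing in `c`; good
#' parents pay less than poor parents for the same care.
#'
#' @param c care level(s), in `[0, care_max]`.
#' @param quality `"G"` (good) or `"P"` (poor).
#' @param params a [care_params] object.
#' @return mortality probabilities in (0, 1), same length as `c`.
#' @export
mortality <- function(c, quality = c("G", "P"), params) {
  quality <- match.arg(quality)
  if (any(!is.finite(c)) || any(c < 0) || any(c > params$care_max + 1e-12))
    domain_error("care must lie in [0, care_max]")
  if (!is.null(params$mortality_fn))
    return(pmin(1 - 1e-6, params$mortality_fn(c, quality)))
  if (quality == "G") {
    m0 <- params$m_min
    pmin(1 - 1e-6, m0 + (1 - m0) * (c / (params$eta_G * params$beta_G))^4)
  } else {
    m0 <- params$rho_base * params$m_min
    pmin(1 - 1e-6, m0 + (1 - m0) * (params$rho * c / params$beta_P)^2)
  }
}

#' Expected brood productivity
#'
#' Expected number of offspring surviving from a brood, as a function of
#' the total care provided by the two parents. Concave and increasing.
#'
#' @param total_care sum of both parents' care; non-negative.
#' @inheritParams mortality
#' @return expected surviving offspring, positive.
#' @export
brood_productivity <- function(total_care, params) {
  if (any(!is.finite(total_care)) || any(total_care < 0))
    domain_error("total_care must be non-negative")
  if (!is.null(params$productivity_fn))
    return(params$productivity_fn(total_care))
  params$b_min + params$alpha_B * (1 - exp(-total_care / params$scale_B))
}

#' Offspring competitiveness
#'
#' Relative competitiveness of a maturing offspring in the race for
#' good-parent development opportunities, as a function of the total care
#' its brood received. Concave and increasing for `alpha_F > 0`;
#' identically `f_min` when `alpha_F = 0` (no parental effect).
#'
#' @inheritParams brood_productivity
#' @return relative competitiveness, positive.
#' @export
competitiveness <- function(total_care, params) {
  if (any(!is.finite(total_care)) || any(total_care < 0))
    domain_error("total_care must be non-negative")
  if (!is.null(params$competitiveness_fn))
    return(params$competitiveness_fn(total_care))
  params$f_min + params$alpha_F * (1 - exp(-total_care / params$scale_F))
}

#' Grid-based shape validation of the life-history functions
#'
#' Checks, over a dense grid, the shape properties the model assumes:
#' mortality convex, increasing, within (0, 1) and strictly ordered
#' `m_G < m_P` pointwise (non-strict if the parameter set was built with
#' `allow_equal_mortality = TRUE`); brood productivity and
#' competitiveness concave and non-decreasing. Runs automatically inside
#' [care_params()]; exported so plugged-in families can be re-validated.
#'
#' @param params a [care_params] object.
#' @param n grid resolution.
#' @return `params`, invisibly; errors (class `carevol_config_error`) on
#'   any violated shape property.
#' @export
validate_shapes <- function(params, n = 201L) {
  cc <- seq(0, params$care_max, length.out = n)
  mg <- mortality(cc, "G", params)
  mp <- mortality(cc, "P", params)
  if (any(mg <= 0) || any(mg >= 1) || any(mp <= 0) || any(mp >= 1))
    config_error("mortality must stay strictly inside (0, 1) on [0, care_max]")
  if (any(diff(mg) < -1e-12) || any(diff(mp) < -1e-12))
    config_error("mortality must be non-decreasing in care")
  if (mg[n] <= mg[1] || mp[n] <= mp[1])
    config_error("mortality must increase over [0, care_max]")
  if (any(diff(mg, differences = 2) < -1e-9) ||
      any(diff(mp, differences = 2) < -1e-9))
    config_error("mortality must be convex in care")
  gap <- mp - mg
  if (params$allow_equal_mortality) {
    if (any(gap < -1e-12))
      config_error("m_G(c) <= m_P(c) violated on the grid")
  } else if (any(gap <= 0)) {
    config_error(
      "m_G(c) < m_P(c) violated on the grid (set rho > 1, or allow_equal_mortality = TRUE for symmetric-class analyses)")
  }

  CC <- seq(0, 2 * params$care_max, length.out = n)
  bb <- brood_productivity(CC, params)
  ff <- competitiveness(CC, params)
  if (any(bb <= 0) || any(ff <= 0))
    config_error("brood productivity and competitiveness must be positive")
  if (any(diff(bb) <= 0))
    config_error("brood productivity must be strictly increasing")
  if (any(diff(bb, differences = 2) > 1e-9))
    config_error("brood productivity must be concave")
  if (any(diff(ff) < -1e-12))
    config_error("competitiveness must be non-decreasing")
  if (any(diff(ff, differences = 2) > 1e-9))
    config_error("competitiveness must be concave")
  invisible(params)
}

#' @export
print.care_params <- function(x, ...) {
  cat("Life-history parameters (care_params)\n")
  cat(sprintf("  g1 = %g (good-parent share of new adults)\n", x$g1))
  cat(sprintf("  mortality: m_min = %g, beta_G = %g (eta_G = %g), beta_P = %g (rho = %g, rho_base = %g)\n",
              x$m_min, x$beta_G, x$eta_G, x$beta_P, x$rho, x$rho_base))
  cat(sprintf("  productivity: b_min = %g, alpha_B = %g, scale_B = %g\n",
              x$b_min, x$alpha_B, x$scale_B))
  cat(sprintf("  competitiveness: f_min = %g, alpha_F = %g, scale_F = %g\n",
              x$f_min, x$alpha_F, x$scale_F))
  cat(sprintf("  care_max = %g\n", x$care_max))
  if (!is.null(x$mortality_fn) || !is.null(x$productivity_fn) ||
      !is.null(x$competitiveness_fn))
    cat("  (custom function family in use)\n")
  invisible(x)
}

# Validate and normalise a care vector (c_GG, c_GP, c_PG, c_PP).
as_care_vector <- function(care, params) {
  if (is.list(care)) care <- unlist(care)
  if (!is.numeric(care) || length(care) != 4L || any(!is.finite(care)))
    domain_error("care must be a numeric vector (c_GG, c_GP, c_PG, c_PP)")
  if (any(care < 0) || any(care > params$care_max + 1e-9))
    domain_error("all care components must lie in [0, care_max]")
  names(care) <- c("c_GG", "c_GP", "c_PG", "c_PP")
  care
}
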