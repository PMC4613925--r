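#' Default run configuration
#'
#' Flat key-value configuration consumed by the command-line interface
#' and the `run_*` drivers. Parameter keys mirror [care_params()];
#' solver keys mirror [ess_solve()]; sweep keys define the `alpha_F`
#' grid; sim keys mirror the simulators.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    g1 = 0.5, m_min = 0.25, beta_G = 5, beta_P = 5, rho = 4.5,
    rho_base = 1.01, eta_G = 0.36, b_min = 1, alpha_B = 5, scale_B = 4,
    f_min = 1, alpha_F = 5, scale_F = 10, care_max = NULL,
    allow_equal_mortality = FALSE,
    delta = 0.01, tol = 1e-8, max_iter = 200000, n_starts = 1,
    mode = "both",
    alpha_F_min = 0, alpha_F_max = 10, n_points = 11,
    n_events = 100000, pool_size = 10000, epoch_events = 200,
    mutation_sd = 0.02, sim_mode = "resident",
    care = c(1, 1, 1, 1),
    output = NULL, log_level = "info", seed = 1),
    class = "run_config")
}

#' Read a run configuration file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`) flat key-value
#' documents; keys absent from the file take their defaults, unknown
#' keys are rejected.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    from_file <- switch(ext,
      yml = , yaml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      config_error(sprintf("unsupported config format '.%s' (use yaml or json)", ext)))
    if (is.null(from_file)) from_file <- list()
  }
  for (src in list(from_file, overrides)) {
    if (length(src) == 0) next
    bad <- setdiff(names(src), names(cfg))
    if (length(bad))
      config_error(paste("unknown config keys:", paste(bad, collapse = ", ")))
    cfg[names(src)] <- src
  }
  validate_run_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#'
#' Checks every invariant the downstream types assert (constructing the
#' [care_params()] object validates the life-history block, including
#' shapes) plus solver, sweep and simulation controls.
#'
#' @param cfg `run_config` list.
#' @return the validated configuration, invisibly classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  params_from_config(cfg)  # errors on any invalid life-history setting
  if (!cfg$mode %in% c("conflict", "no_conflict", "both"))
    config_error("mode must be one of conflict, no_conflict, both")
  if (cfg$delta <= 0 || cfg$tol <= 0 || cfg$max_iter < 1)
    config_error("solver controls require delta > 0, tol > 0, max_iter >= 1")
  if (cfg$n_points < 1 || cfg$alpha_F_min < 0 ||
      cfg$alpha_F_max < cfg$alpha_F_min)
    config_error("sweep grid requires 0 <= alpha_F_min <= alpha_F_max, n_points >= 1")
  if (!cfg$sim_mode %in% c("resident", "evolution"))
    config_error("sim_mode must be resident or evolution")
  if (cfg$mutation_sd < 0) config_error("mutation_sd must be non-negative")
  if (length(cfg$care) != 4) config_error("care must have four components")
  invisible(structure(cfg, class = "run_config"))
}

# Life-history parameter block of a config.
params_from_config <- function(cfg) {
  care_params(g1 = cfg$g1, m_min = cfg$m_min, beta_G = cfg$beta_G,
              beta_P = cfg$beta_P, rho = cfg$rho, rho_base = cfg$rho_base,
              eta_G = cfg$eta_G, b_min = cfg$b_min, alpha_B = cfg$alpha_B,
              scale_B = cfg$scale_B, f_min = cfg$f_min,
              alpha_F = cfg$alpha_F, scale_F = cfg$scale_F,
              care_max = cfg$care_max,
              allow_equal_mortality = cfg$allow_equal_mortality)
}

#' Write a run configuration to file
#'
#' Serializes to YAML or JSON by extension; [read_run_config()] on the
#' written file round-trips to an identical configuration.
#'
#' @param cfg `run_config` list.
#' @param path destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = , yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    config_error(sprintf("unsupported config format '.%s'", ext)))
  invisible(path)
}

# 12-significant-digit CSV writer used by the CLI drivers.
write_result_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sweep_row <- function(fit, alpha_F) {
  data.frame(alpha_F = alpha_F, mode = fit$mode,
             c_GG = fit$care_star[["c_GG"]], c_GP = fit$care_star[["c_GP"]],
             c_PG = fit$care_star[["c_PG"]], c_PP = fit$care_star[["c_PP"]],
             g2 = fit$resident$demo$g2, m_G = fit$resident$demo$m_G,
             m_P = fit$resident$demo$m_P, v_G = fit$resident$rv$v_G,
             v_P = fit$resident$rv$v_P, avg_care = average_care(fit),
             iterations = fit$iterations, converged = fit$converged)
}

#' Solve the ESS for one configuration
#'
#' Driver behind the CLI `solve` subcommand: one [ess_solve()] per
#' requested mode, emitted as a one-row-per-mode data frame (the sweep
#' CSV schema) and optionally written to `cfg$output`.
#'
#' @param cfg validated `run_config`.
#' @return data frame (invisible CSV side effect if `cfg$output` set).
#' @export
run_solve <- function(cfg) {
  cfg <- validate_run_config(cfg)
  params <- params_from_config(cfg)
  modes <- if (cfg$mode == "both") c("conflict", "no_conflict") else cfg$mode
  rows <- lapply(modes, function(mode) {
    fit <- ess_solve(params, mode = mode, delta = cfg$delta, tol = cfg$tol,
                     max_iter = cfg$max_iter)
    sweep_row(fit, cfg$alpha_F)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$output)) write_result_csv(out, cfg$output)
  out
}

#' Sweep the ESS over the configured alpha_F grid
#'
#' Driver behind the CLI `sweep` subcommand; see [sweep_alpha_f()].
#'
#' @param cfg validated `run_config`.
#' @return `care_sweep` data frame.
#' @export
run_sweep <- function(cfg) {
  cfg <- validate_run_config(cfg)
  params <- params_from_config(cfg)
  grid <- seq(cfg$alpha_F_min, cfg$alpha_F_max, length.out = cfg$n_points)
  modes <- if (cfg$mode == "both") c("conflict", "no_conflict") else cfg$mode
  out <- sweep_alpha_f(grid, params, modes = modes, delta = cfg$delta,
                       tol = cfg$tol, max_iter = cfg$max_iter)
  if (!is.null(cfg$output)) write_result_csv(out, cfg$output)
  out
}

#' Run the individual-based simulator for one configuration
#'
#' Driver behind the CLI `simulate` subcommand.
#'
#' @param cfg validated `run_config`.
#' @return `care_sim` object.
#' @export
run_simulate <- function(cfg) {
  cfg <- validate_run_config(cfg)
  params <- params_from_config(cfg)
  if (cfg$sim_mode == "resident") {
    sim <- simulate_resident(cfg$care, params, n_events = cfg$n_events,
                             seed = cfg$seed, pool_size = cfg$pool_size,
                             epoch_events = cfg$epoch_events)
    tab <- cbind(quantity = rownames(sim$estimates), sim$estimates)
  } else {
    sim <- simulate_evolution(params, n_events = cfg$n_events,
                              seed = cfg$seed, pool_size = cfg$pool_size,
                              epoch_events = cfg$epoch_events,
                              init_care = cfg$care,
                              mutation_sd = cfg$mutation_sd)
    tab <- cbind(quantity = rownames(sim$allele_means), sim$allele_means)
  }
  if (!is.null(cfg$output)) write_result_csv(tab, cfg$output)
  sim
}

#' Model self-check: run the full invariant suite
#'
#' Executes, for the configured parameter set, every structural property
#' the model asserts: life-history shape validation; conservation and
#' consistency of the resident equilibrium over random care draws
#' (offspring-origin proportions summing to one, normalized mean
#' lifetime reproductive success of one, equal quality-transition
#' ratios, the good-parent mass balance, resident eigenvalue one,
#' invariance to the k/T split); the parental-effect collapse at
#' `alpha_F = 0`; mutant neutrality; and a reduced-size cross-check of
#' the analytic equilibrium against the individual-based simulator.
#'
#' @param cfg `run_config` (defaults used when omitted).
#' @param n_draws random resident draws for the property checks.
#' @param sim_events breeding events for the stochastic cross-check.
#' @param seed RNG seed for draws and simulation.
#' @return data frame with one row per property (`property`, `pass`,
#'   `detail`), classed `care_check`; overall success as attribute
#'   `"ok"`.
#' @export
check_model <- function(cfg = default_run_config(), n_draws = 25,
                        sim_events = 20000, seed = 1) {
  cfg <- validate_run_config(cfg)
  params <- params_from_config(cfg)
  set.seed(seed)
  rows <- list()
  add <- function(property, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      property = property, pass = pass, detail = detail)
  }

  add("life-history shapes",
      !inherits(tryCatch(validate_shapes(params), error = identity), "error"))

  worst <- c(q = 0, lrs = 0, ratio = 0, mass = 0, eig = 0, kt = 0)
  for (i in seq_len(n_draws)) {
    care <- stats::runif(4, 0, params$care_max)
    rs <- resident_state(care, params)
    worst["q"] <- max(worst["q"],
                      abs(rs$brood$q_GG + rs$brood$q_GP + rs$brood$q_PP - 1))
    lrs <- (params$g1 / rs$demo$m_G) *
      (rs$demo$g2 * rs$brood$bp_GG + (1 - rs$demo$g2) * rs$brood$bp_GP) +
      ((1 - params$g1) / rs$demo$m_P) *
      (rs$demo$g2 * rs$brood$bp_GP + (1 - rs$demo$g2) * rs$brood$bp_PP)
    worst["lrs"] <- max(worst["lrs"], abs(lrs - 1))
    r <- c((1 - rs$qt$g_GG)^(1 / rs$qt$f_GG),
           (1 - rs$qt$g_GP)^(1 / rs$qt$f_GP),
           (1 - rs$qt$g_PP)^(1 / rs$qt$f_PP))
    worst["ratio"] <- max(worst["ratio"], diff(range(r)))
    worst["mass"] <- max(worst["mass"],
                         abs(rs$qt$g_GG * rs$brood$q_GG +
                             rs$qt$g_GP * rs$brood$q_GP +
                             rs$qt$g_PP * rs$brood$q_PP - params$g1))
    worst["eig"] <- max(worst["eig"], abs(rs$rv$leading_eigenvalue - 1))
  }
  add("offspring-origin proportions sum to 1", worst[["q"]] < 1e-10,
      sprintf("max |err| = %.2e", worst[["q"]]))
  add("normalized mean lifetime reproductive success = 1",
      worst[["lrs"]] < 1e-12, sprintf("max |err| = %.2e", worst[["lrs"]]))
  add("quality-transition ratios equal", worst[["ratio"]] < 1e-10,
      sprintf("max spread = %.2e", worst[["ratio"]]))
  add("good-parent mass balance", worst[["mass"]] < 1e-10,
      sprintf("max |err| = %.2e", worst[["mass"]]))
  add("resident eigenvalue = 1", worst[["eig"]] < 1e-8,
      sprintf("max |err| = %.2e", worst[["eig"]]))

  p0 <- params; p0$alpha_F <- 0
  qt0 <- solve_quality_transition(stats::runif(4, 0, p0$care_max),
                                  params = p0)
  add("alpha_F = 0 collapses transition to g1",
      identical(c(qt0$g_GG, qt0$g_GP, qt0$g_PP), rep(p0$g1, 3)))

  care <- stats::runif(4, 0.2, params$care_max)
  rs <- resident_state(care, params)
  lam <- vapply(c("conflict", "no_conflict"), function(m)
    invasion_fitness(care, rs, mode = m)$lambda, numeric(1))
  add("resident neutrality (lambda-hat = 1)", all(abs(lam - 1) < 1e-8),
      sprintf("max |lambda - 1| = %.2e", max(abs(lam - 1))))

  sim_care <- c(1, 1, 1, 1) * min(1, params$care_max)
  rs1 <- resident_state(sim_care, params)
  sim <- simulate_resident(sim_care, params, n_events = sim_events,
                           seed = seed, pool_size = 4000L,
                           init_g2 = rs1$demo$g2)
  z <- function(name, target)
    abs(sim$estimates[name, "estimate"] - target) /
      max(sim$estimates[name, "se"], 1e-12)
  zs <- c(z("g2_hat", rs1$demo$g2), z("m_G_hat", rs1$demo$m_G),
          z("m_P_hat", rs1$demo$m_P), z("q_GG_hat", rs1$brood$q_GG),
          z("q_GP_hat", rs1$brood$q_GP), z("q_PP_hat", rs1$brood$q_PP))
  add("analytics match individual-based simulation (3 SE)", all(zs < 3),
      sprintf("max |z| = %.2f", max(zs)))

  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  class(out) <- c("care_check", "data.frame")
  out
}

#' @export
print.care_check <- function(x, ...) {
  cat("Model invariant suite:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s %s\n", if (x$pass[i]) "PASS" else "FAIL",
                x$property[i],
                if (nzchar(x$detail[i])) paste0("(", x$detail[i], ")") else ""))
  cat(if (isTRUE(attr(x, "ok"))) "All properties pass.\n"
      else "SOME PROPERTIES FAILED.\n")
  invisible(x)
}
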