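## Homeostasis perturbations -------------------------------------------------
##
## Complete thymectomy is simulated by clamping the SP4 thymocyte state (and
## hence thymic egress) to zero from the time of surgery, starting from the
## healthy steady state at the surgery age. Adaptation knockouts disable the
## RTE-concentration feedback on naive proliferation and/or RTE death,
## freezing the affected rate at a constant reference value.

#' Age bounds (years) of the six thymectomy groups
#' @return data.frame with columns `group`, `lo`, `hi`, `label`.
#' @export
thymectomy_group_bounds <- function() {
  data.frame(group = 1:6,
             lo = c(0, 1 / 12, 2 / 12, 1, 1.5, 3),
             hi = c(1 / 12, 2 / 12, 1, 1.5, 3, 6),
             label = c("0-1 mo", "1-2 mo", "2 mo-1 y", "1-1.5 y",
                       "1.5-3 y", ">3 y"),
             stringsAsFactors = FALSE)
}

#' Group label for an age at thymectomy
#' @param age_at_surgery Age in years.
#' @return Integer group 1-6 (ages above 6 years fall in group 6).
#' @export
thymectomy_group <- function(age_at_surgery) {
  b <- thymectomy_group_bounds()
  vapply(age_at_surgery, function(a) {
    if (a < 0) stop("age at surgery must be non-negative", call. = FALSE)
    g <- which(a >= b$lo & a < b$hi)
    if (length(g)) g[1] else 6L
  }, integer(1))
}

.trajectory_observables <- function(traj, modulations) {
  n <- nrow(traj)
  bv <- blood_volume(traj$age_years, modulations$physiology)
  states <- as.matrix(traj[, names(.IDX)])
  tot_bl <- rowSums(states[, c("RTE_BL", "N_BL", "A_BL", "CM_BL", "EM_BL",
                               "EFF_BL"), drop = FALSE])
  naive_bl <- states[, "N_BL"] + states[, "RTE_BL"]
  lt_total <- rowSums(states[, c("RTE_LT", "N_LT", "A_LT", "CM_LT", "EM_LT",
                                 "EFF_LT"), drop = FALSE])
  data.frame(age = traj$age_years,
             total_blood_conc = tot_bl / (bv * 1e6),
             naive_blood_conc = naive_bl / (bv * 1e6),
             total_RTE = states[, "RTE_BL"] + states[, "RTE_LT"],
             total_LT = lt_total)
}

#' Simulate complete thymectomy
#'
#' The initial state is the healthy steady state at the surgery age (or a
#' baseline-corrected state); from surgery onwards the SP4 thymocyte count
#' is clamped to zero so thymic egress stops. A paired healthy reference
#' trajectory from the same initial state (without the clamp) is returned
#' alongside.
#'
#' @param age_at_surgery Age in years at complete thymectomy.
#' @param params,modulations Calibrated model.
#' @param until_age Final age (years) of the simulation.
#' @param observation_ages Optional ages at which observables are reported
#'   (defaults to ~monthly within 2 years of surgery, yearly after).
#' @param initial Optional initial 24-state override (e.g. after
#'   [baseline_correction()]).
#' @return A list of class `cd4_thymectomy`: `scenario`/`reference`
#'   trajectories (state columns), `observed`/`reference_observed`
#'   (total and naive blood concentrations, total RTE and lymphoid-tissue
#'   counts), `age_at_surgery`, `group`.
#' @export
simulate_thymectomy <- function(age_at_surgery, params = default_parameters(),
                                modulations = default_modulations(),
                                until_age = age_at_surgery + 20,
                                observation_ages = NULL, initial = NULL) {
  if (until_age <= age_at_surgery) {
    stop("until_age must exceed the age at surgery", call. = FALSE)
  }
  if (is.null(initial)) {
    initial <- solve_steady_state(params, modulations,
                                  age_fixed = age_at_surgery)
  }
  if (is.null(observation_ages)) {
    early <- seq(age_at_surgery, min(until_age, age_at_surgery + 2),
                 by = 1 / 12)
    late <- if (until_age > age_at_surgery + 2) {
      seq(ceiling(age_at_surgery + 2), until_age, by = 1)
    } else numeric(0)
    observation_ages <- sort(unique(c(early, late, until_age)))
  }
  observation_ages <- observation_ages[observation_ages >= age_at_surgery]
  t_grid <- unique(c(0, (observation_ages - age_at_surgery) * 365.25))
  t_grid <- sort(t_grid)
  scen <- simulate_trajectory(initial, params, modulations, t_grid,
                              age0 = age_at_surgery, sp4_clamp_from = 0)
  ref <- simulate_trajectory(initial, params, modulations, t_grid,
                             age0 = age_at_surgery)
  structure(list(scenario = scen, reference = ref,
                 observed = .trajectory_observables(scen, modulations),
                 reference_observed = .trajectory_observables(ref,
                                                              modulations),
                 age_at_surgery = age_at_surgery,
                 group = thymectomy_group(age_at_surgery)),
            class = "cd4_thymectomy")
}

#' Correct a model baseline against pre-surgery observations
#'
#' Scales the predicted healthy state by the ratio of observed to predicted
#' values at the pre-surgery age: states matched by name are scaled by
#' their own ratio; unmatched states are scaled by the ratio of total
#' CD4+ counts over the matched states.
#'
#' @param predicted Named 24-state vector (predicted healthy baseline).
#' @param observed Named numeric vector: either state labels (same count
#'   units as `predicted`) or the single name `"TOTAL"` (total CD4+ count).
#' @return Corrected 24-state vector.
#' @export
baseline_correction <- function(predicted, observed) {
  if (is.null(names(observed))) {
    stop("observed values must be named", call. = FALSE)
  }
  x <- predicted
  if (identical(names(observed), "TOTAL")) {
    tot_pred <- sum(predicted[5:24])
    if (tot_pred <= 0) stop("predicted baseline is zero", call. = FALSE)
    return(predicted * unname(observed) / tot_pred)
  }
  bad <- setdiff(names(observed), names(.IDX))
  if (length(bad)) stop("unknown state label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  m <- names(observed)
  if (any(predicted[m] <= 0)) stop("predicted baseline is zero",
                                   call. = FALSE)
  x[m] <- predicted[m] * observed[m] / predicted[m]
  ratio_total <- sum(observed) / sum(predicted[m])
  rest <- setdiff(names(.IDX), m)
  x[rest] <- predicted[rest] * ratio_total
  x
}

#' Disable RTE-driven adaptation mechanisms
#'
#' Runs the feedback-variant model with the naive-proliferation adaptation,
#' the RTE-death adaptation, or both, replaced by a constant rate, and
#' quantifies the resulting loss of lymphoid-organ CD4+ T cells relative to
#' the full model. By default the knocked-out rate is frozen at the value
#' the full model exhibits at the healthy newborn steady state, so the
#' scenario difference isolates the adaptation (not a baseline shift); the
#' alternative freezes at the zero-concentration base value.
#'
#' @param mode `"none"` (full model), `"no_naive_prolif_adapt"`,
#'   `"no_rte_death_adapt"` or `"neither"` (both disabled).
#' @param params,modulations Calibrated model (variant must be
#'   `"AGE_PLUS_FEEDBACK"`).
#' @param ages Ages (years) at which the percent reduction is reported.
#' @param freeze_at `"newborn"` (default) or `"zero_conc"`.
#' @return A list of class `cd4_knockout`: `report` (data.frame `age`,
#'   `reference_LT`, `scenario_LT`, `reduction_pct`), `mode`, trajectories
#'   `scenario`/`reference`.
#' @export
adaptation_knockout <- function(mode = c("none", "no_naive_prolif_adapt",
                                         "no_rte_death_adapt", "neither"),
                                params = default_parameters(),
                                modulations = default_modulations(),
                                ages = c(20, 50, 80),
                                freeze_at = c("newborn", "zero_conc")) {
  mode <- match.arg(mode)
  freeze_at <- match.arg(freeze_at)
  if (modulations$variant != "AGE_PLUS_FEEDBACK") {
    stop("adaptation knockouts require the feedback variant", call. = FALSE)
  }
  fb <- modulations$feedback
  if (freeze_at == "newborn") {
    ss0 <- solve_steady_state(params, modulations, age_fixed = 0)
    c0 <- attr(ss0, "C_RTE")
    lam_frozen <- feedback_naive_prolif(c0, fb$lamN4base, fb$lamN4_fmax,
                                        fb$C50_lamN4, fb$Nh_lamN4)
    mu_frozen <- feedback_rte_death(c0, fb$muRTE4base, fb$muRTE4_fmax,
                                    fb$C50_muRTE4, fb$Nh_muRTE4)
  } else {
    lam_frozen <- fb$lamN4base
    mu_frozen <- fb$muRTE4base
  }
  mod_scen <- modulations
  if (mode %in% c("no_naive_prolif_adapt", "neither")) {
    mod_scen$feedback$lamN4base <- lam_frozen
    mod_scen$feedback$lamN4_fmax <- 0
  }
  if (mode %in% c("no_rte_death_adapt", "neither")) {
    mod_scen$feedback$muRTE4base <- mu_frozen
    mod_scen$feedback$muRTE4_fmax <- 0
  }
  init <- solve_steady_state(params, modulations, age_fixed = 0)
  t_grid <- unique(sort(c(0, ages * 365.25,
                          seq(0, max(ages), by = 2) * 365.25)))
  ref <- simulate_trajectory(init, params, modulations, t_grid, age0 = 0)
  scen <- if (mode == "none") ref else {
    init_scen <- solve_steady_state(params, mod_scen, age_fixed = 0)
    simulate_trajectory(init_scen, params, mod_scen, t_grid, age0 = 0)
  }
  lt_cols <- c("RTE_LT", "N_LT", "A_LT", "CM_LT", "EM_LT", "EFF_LT")
  at_ages <- function(traj, a) {
    k <- vapply(a, function(x) which.min(abs(traj$age_years - x)),
                integer(1))
    rowSums(as.matrix(traj[k, lt_cols, drop = FALSE]))
  }
  ref_lt <- at_ages(ref, ages)
  scen_lt <- at_ages(scen, ages)
  report <- data.frame(age = ages, reference_LT = ref_lt,
                       scenario_LT = scen_lt,
                       reduction_pct = mapply(scenario_percent_reduction,
                                              scen_lt, ref_lt))
  structure(list(report = report, mode = mode, freeze_at = freeze_at,
                 scenario = scen, reference = ref),
            class = "cd4_knockout")
}

#' Percent reduction of a scenario relative to a reference
#'
#' `100 * (reference - scenario) / reference`; the convention used to
#' report the loss of lymphoid-organ CD4+ T cells in knockout scenarios.
#'
#' @param scenario Scenario value (`a`).
#' @param reference Reference value (`b`, `> 0`).
#' @return Percent reduction (negative when the scenario exceeds the
#'   reference).
#' @export
scenario_percent_reduction <- function(scenario, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  100 * (reference - scenario) / reference
}
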