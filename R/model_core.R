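## The 24-state ODE system ---------------------------------------------------
##
## Thymus: DN -> DP under a cortical carrying capacity; DP -> SP4/SP8 under a
## medullary capacity; SP4 egress feeds blood RTE. Periphery: RTE -> naive ->
## activated (lymphoid tissue), activated cells expand logistically against a
## whole-body capacity and differentiate into central-memory (fraction f4)
## and effector cells; differentiation of activated cells, like
## CM -> EM -> EFF, proceeds in every compartment where the source resides
## (at the published rate constants this keeps the activated pool stably
## below its carrying capacity). Naive and CM recirculate blood <-> lymphoid tissue and
## blood <-> gut/lung; EM and EFF leave lymphoid tissue without return; flows
## to unmodelled peripheral tissues (om*bl_tis) are pure losses.

.IDX <- local({
  lab <- c("DN_THY", "DP_THY", "SP4_THY", "SP8_THY",
           "RTE_BL", "RTE_LT",
           "N_BL", "N_LT", "N_GIT", "N_LUNG",
           "A_BL", "A_LT",
           "CM_BL", "CM_LT", "CM_GIT", "CM_LUNG",
           "EM_BL", "EM_LT", "EM_GIT", "EM_LUNG",
           "EFF_BL", "EFF_LT", "EFF_GIT", "EFF_LUNG")
  as.list(setNames(seq_along(lab), lab))
})

#' Time derivative of the 24-state homeostasis model
#'
#' Assembles `d(state)/dt` (cells/day) from first-order mass-action terms
#' given a set of effective rates (already evaluated at the relevant age and
#' RTE concentration).
#'
#' @param state Numeric vector of 24 non-negative cell counts in layout
#'   order (see [compartment_layout()]).
#' @param effective A `cd4_effective_rates` object from
#'   [effective_parameters()].
#' @return Numeric vector of 24 derivatives, cells/day.
#' @export
full_rhs <- function(state, effective) {
  if (length(state) != 24L) {
    stop("state vector must have 24 elements", call. = FALSE)
  }
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  v <- effective$values
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("effective rates must be finite and non-negative", call. = FALSE)
  }
  d <- .rhs_core(unname(state), v, effective$Tcortmax, effective$Tmedmax)
  names(d) <- names(.IDX)
  d
}

## unchecked arithmetic core shared by full_rhs and the ODE integrator
.rhs_core <- function(S, v, Tcortmax, Tmedmax) {
  i <- .IDX
  d <- numeric(24L)

  ## thymus
  cortOcc <- (S[i$DN_THY] + S[i$DP_THY]) / Tcortmax
  medOcc  <- (S[i$SP4_THY] + S[i$SP8_THY]) / Tmedmax
  d[i$DN_THY] <- v[["pDN"]] * S[i$DN_THY] * (1 - cortOcc) -
    (v[["dltDN"]] + v[["muDN"]]) * S[i$DN_THY]
  d[i$DP_THY] <- v[["dltDN"]] * S[i$DN_THY] +
    v[["pDP"]] * S[i$DP_THY] * (1 - cortOcc) -
    (v[["dltDP"]] + v[["muDP"]]) * S[i$DP_THY]
  d[i$SP4_THY] <- v[["alphaSP4"]] * v[["dltDP"]] * S[i$DP_THY] +
    v[["pSP"]] * S[i$SP4_THY] * (1 - medOcc) -
    (v[["muSP"]] + v[["sigmaSP4"]]) * S[i$SP4_THY]
  d[i$SP8_THY] <- (1 - v[["alphaSP4"]]) * v[["dltDP"]] * S[i$DP_THY] +
    v[["pSP"]] * S[i$SP8_THY] * (1 - medOcc) -
    (v[["muSP"]] + v[["sigmaSP4"]]) * S[i$SP8_THY]

  ## recent thymic emigrants
  d[i$RTE_BL] <- v[["sigmaSP4"]] * S[i$SP4_THY] -
    (v[["muRTE4"]] + v[["omRTE4bl_lt"]]) * S[i$RTE_BL]
  d[i$RTE_LT] <- v[["omRTE4bl_lt"]] * S[i$RTE_BL] -
    (v[["muRTE4"]] + v[["phiRTE4"]]) * S[i$RTE_LT]

  ## naive
  d[i$N_BL] <- (v[["lamN4"]] - v[["muN4"]] -
                  (v[["omN4bl_lt"]] + v[["omN4bl_git"]] +
                     v[["omN4bl_lung"]] + v[["omN4bl_tis"]])) * S[i$N_BL] +
    v[["omN4lt_bl"]] * S[i$N_LT] + v[["omN4git_bl"]] * S[i$N_GIT] +
    v[["omN4lung_bl"]] * S[i$N_LUNG]
  d[i$N_LT] <- v[["phiRTE4"]] * S[i$RTE_LT] + v[["omN4bl_lt"]] * S[i$N_BL] +
    (v[["lamN4"]] - v[["muN4"]] - v[["phiN4"]] - v[["omN4lt_bl"]]) * S[i$N_LT]
  ## homeostatic proliferation of naive cells requires the IL-7-rich
  ## lymphoid/blood environment; gut and lung hold non-proliferating
  ## transit pools
  d[i$N_GIT] <- v[["omN4bl_git"]] * S[i$N_BL] -
    (v[["muN4"]] + v[["omN4git_bl"]]) * S[i$N_GIT]
  d[i$N_LUNG] <- v[["omN4bl_lung"]] * S[i$N_BL] -
    (v[["muN4"]] + v[["omN4lung_bl"]]) * S[i$N_LUNG]

  ## activated: logistic expansion against the whole-body capacity
  lamA <- v[["lamA4"]] * (1 - (S[i$A_BL] + S[i$A_LT]) / v[["TA4max"]])
  d[i$A_BL] <- (lamA - v[["muA4"]] - v[["phiA4"]] -
                  (v[["omA4bl_lt"]] + v[["omA4bl_tis"]])) * S[i$A_BL] +
    v[["omA4lt_bl"]] * S[i$A_LT]
  d[i$A_LT] <- v[["phiN4"]] * S[i$N_LT] + v[["omA4bl_lt"]] * S[i$A_BL] +
    (lamA - v[["muA4"]] - v[["phiA4"]] - v[["omA4lt_bl"]]) * S[i$A_LT]

  ## central-memory
  d[i$CM_BL] <- v[["f4"]] * v[["phiA4"]] * S[i$A_BL] +
    (v[["lamCM4"]] - v[["muCM4"]] - v[["phiCM4"]] -
       (v[["omCM4bl_lt"]] + v[["omCM4bl_git"]] +
          v[["omCM4bl_lung"]] + v[["omCM4bl_tis"]])) * S[i$CM_BL] +
    v[["omCM4lt_bl"]] * S[i$CM_LT] + v[["omCM4git_bl"]] * S[i$CM_GIT] +
    v[["omCM4lung_bl"]] * S[i$CM_LUNG]
  d[i$CM_LT] <- v[["f4"]] * v[["phiA4"]] * S[i$A_LT] +
    v[["omCM4bl_lt"]] * S[i$CM_BL] +
    (v[["lamCM4"]] - v[["muCM4"]] - v[["phiCM4"]] -
       v[["omCM4lt_bl"]]) * S[i$CM_LT]
  d[i$CM_GIT] <- v[["omCM4bl_git"]] * S[i$CM_BL] +
    (v[["lamCM4"]] - v[["muCM4"]] - v[["phiCM4"]] -
       v[["omCM4git_bl"]]) * S[i$CM_GIT]
  d[i$CM_LUNG] <- v[["omCM4bl_lung"]] * S[i$CM_BL] +
    (v[["lamCM4"]] - v[["muCM4"]] - v[["phiCM4"]] -
       v[["omCM4lung_bl"]]) * S[i$CM_LUNG]

  ## effector-memory (no return to lymphoid tissue)
  d[i$EM_BL] <- v[["phiCM4"]] * S[i$CM_BL] +
    (v[["lamEM4"]] - v[["muEM4"]] - v[["phiEM4"]] -
       (v[["omEM4bl_git"]] + v[["omEM4bl_lung"]] +
          v[["omEM4bl_tis"]])) * S[i$EM_BL] +
    v[["omEM4lt_bl"]] * S[i$EM_LT] + v[["omEM4git_bl"]] * S[i$EM_GIT] +
    v[["omEM4lung_bl"]] * S[i$EM_LUNG]
  d[i$EM_LT] <- v[["phiCM4"]] * S[i$CM_LT] +
    (v[["lamEM4"]] - v[["muEM4"]] - v[["phiEM4"]] -
       v[["omEM4lt_bl"]]) * S[i$EM_LT]
  d[i$EM_GIT] <- v[["phiCM4"]] * S[i$CM_GIT] +
    v[["omEM4bl_git"]] * S[i$EM_BL] +
    (v[["lamEM4"]] - v[["muEM4"]] - v[["phiEM4"]] -
       v[["omEM4git_bl"]]) * S[i$EM_GIT]
  d[i$EM_LUNG] <- v[["phiCM4"]] * S[i$CM_LUNG] +
    v[["omEM4bl_lung"]] * S[i$EM_BL] +
    (v[["lamEM4"]] - v[["muEM4"]] - v[["phiEM4"]] -
       v[["omEM4lung_bl"]]) * S[i$EM_LUNG]

  ## effector (terminal, non-proliferating; egress to tissues only)
  d[i$EFF_BL] <- (1 - v[["f4"]]) * v[["phiA4"]] * S[i$A_BL] +
    v[["phiEM4"]] * S[i$EM_BL] +
    v[["omEFF4lt_bl"]] * S[i$EFF_LT] -
    (v[["muEFF4"]] + v[["omEFF4bl_git"]] + v[["omEFF4bl_lung"]] +
       v[["omEFF4bl_tis"]]) * S[i$EFF_BL]
  d[i$EFF_LT] <- (1 - v[["f4"]]) * v[["phiA4"]] * S[i$A_LT] +
    v[["phiEM4"]] * S[i$EM_LT] -
    (v[["muEFF4"]] + v[["omEFF4lt_bl"]]) * S[i$EFF_LT]
  d[i$EFF_GIT] <- v[["phiEM4"]] * S[i$EM_GIT] +
    v[["omEFF4bl_git"]] * S[i$EFF_BL] - v[["muEFF4"]] * S[i$EFF_GIT]
  d[i$EFF_LUNG] <- v[["phiEM4"]] * S[i$EM_LUNG] +
    v[["omEFF4bl_lung"]] * S[i$EFF_BL] - v[["muEFF4"]] * S[i$EFF_LUNG]

  d
}

## Declarative flux inventory used by flow_audit -----------------------------

.MIGRATION_EDGES <- local({
  e <- rbind(
    c("SP4_THY", "RTE_BL",  "sigmaSP4"),
    c("RTE_BL",  "RTE_LT",  "omRTE4bl_lt"),
    c("N_BL",    "N_LT",    "omN4bl_lt"),
    c("N_LT",    "N_BL",    "omN4lt_bl"),
    c("N_BL",    "N_GIT",   "omN4bl_git"),
    c("N_GIT",   "N_BL",    "omN4git_bl"),
    c("N_BL",    "N_LUNG",  "omN4bl_lung"),
    c("N_LUNG",  "N_BL",    "omN4lung_bl"),
    c("N_BL",    NA,        "omN4bl_tis"),
    c("A_BL",    "A_LT",    "omA4bl_lt"),
    c("A_LT",    "A_BL",    "omA4lt_bl"),
    c("A_BL",    NA,        "omA4bl_tis"),
    c("CM_BL",   "CM_LT",   "omCM4bl_lt"),
    c("CM_LT",   "CM_BL",   "omCM4lt_bl"),
    c("CM_BL",   "CM_GIT",  "omCM4bl_git"),
    c("CM_GIT",  "CM_BL",   "omCM4git_bl"),
    c("CM_BL",   "CM_LUNG", "omCM4bl_lung"),
    c("CM_LUNG", "CM_BL",   "omCM4lung_bl"),
    c("CM_BL",   NA,        "omCM4bl_tis"),
    c("EM_LT",   "EM_BL",   "omEM4lt_bl"),
    c("EM_BL",   "EM_GIT",  "omEM4bl_git"),
    c("EM_GIT",  "EM_BL",   "omEM4git_bl"),
    c("EM_BL",   "EM_LUNG", "omEM4bl_lung"),
    c("EM_LUNG", "EM_BL",   "omEM4lung_bl"),
    c("EM_BL",   NA,        "omEM4bl_tis"),
    c("EFF_LT",  "EFF_BL",  "omEFF4lt_bl"),
    c("EFF_BL",  "EFF_GIT", "omEFF4bl_git"),
    c("EFF_BL",  "EFF_LUNG","omEFF4bl_lung"),
    c("EFF_BL",  NA,        "omEFF4bl_tis")
  )
  data.frame(from = e[, 1], to = e[, 2], rate = e[, 3],
             stringsAsFactors = FALSE)
})

.DIFFERENTIATION_EDGES <- local({
  e <- rbind(
    c("DN_THY", "DP_THY", "dltDN",  "1"),
    c("DP_THY", "SP4_THY","dltDP",  "alphaSP4"),
    c("DP_THY", "SP8_THY","dltDP",  "1-alphaSP4"),
    c("RTE_LT", "N_LT",   "phiRTE4","1"),
    c("N_LT",   "A_LT",   "phiN4",  "1"),
    c("A_LT",   "CM_LT",  "phiA4",  "f4"),
    c("A_LT",   "EFF_LT", "phiA4",  "1-f4"),
    c("A_BL",   "CM_BL",  "phiA4",  "f4"),
    c("A_BL",   "EFF_BL", "phiA4",  "1-f4"),
    c("CM_BL",  "EM_BL",  "phiCM4", "1"),
    c("CM_LT",  "EM_LT",  "phiCM4", "1"),
    c("CM_GIT", "EM_GIT", "phiCM4", "1"),
    c("CM_LUNG","EM_LUNG","phiCM4", "1"),
    c("EM_BL",  "EFF_BL", "phiEM4", "1"),
    c("EM_LT",  "EFF_LT", "phiEM4", "1"),
    c("EM_GIT", "EFF_GIT","phiEM4", "1"),
    c("EM_LUNG","EFF_LUNG","phiEM4","1")
  )
  data.frame(from = e[, 1], to = e[, 2], rate = e[, 3], frac = e[, 4],
             stringsAsFactors = FALSE)
})

.DEATH_RATES <- c(
  DN_THY = "muDN", DP_THY = "muDP", SP4_THY = "muSP", SP8_THY = "muSP",
  RTE_BL = "muRTE4", RTE_LT = "muRTE4",
  N_BL = "muN4", N_LT = "muN4", N_GIT = "muN4", N_LUNG = "muN4",
  A_BL = "muA4", A_LT = "muA4",
  CM_BL = "muCM4", CM_LT = "muCM4", CM_GIT = "muCM4", CM_LUNG = "muCM4",
  EM_BL = "muEM4", EM_LT = "muEM4", EM_GIT = "muEM4", EM_LUNG = "muEM4",
  EFF_BL = "muEFF4", EFF_LT = "muEFF4", EFF_GIT = "muEFF4",
  EFF_LUNG = "muEFF4"
)

.PROLIF_RATES <- c(
  N_BL = "lamN4", N_LT = "lamN4",
  A_BL = "lamA4", A_LT = "lamA4",
  CM_BL = "lamCM4", CM_LT = "lamCM4", CM_GIT = "lamCM4", CM_LUNG = "lamCM4",
  EM_BL = "lamEM4", EM_LT = "lamEM4", EM_GIT = "lamEM4", EM_LUNG = "lamEM4"
)

.frac_value <- function(frac, v) {
  switch(frac,
         "1" = 1,
         "alphaSP4" = v[["alphaSP4"]],
         "1-alphaSP4" = 1 - v[["alphaSP4"]],
         "f4" = v[["f4"]],
         "1-f4" = 1 - v[["f4"]])
}

#' Named flux decomposition of the model derivative
#'
#' Breaks the time derivative of every state into named contributions
#' (proliferation, death, differentiation in/out, migration in/out) built
#' from a declarative inventory of the model's flux topology. The per-state
#' sums reproduce [full_rhs()] exactly, and every migration flux out of one
#' modelled state appears as a migration flux into another, except the
#' irreversible losses to unmodelled peripheral tissues.
#'
#' @inheritParams full_rhs
#' @return A data.frame (class `cd4_flux_breakdown`) with columns `state`,
#'   `proliferation`, `death`, `differentiation_in`, `differentiation_out`,
#'   `migration_in`, `migration_out`, `total` (all cells/day).
#' @export
flow_audit <- function(state, effective) {
  if (length(state) != 24L) {
    stop("state vector must have 24 elements", call. = FALSE)
  }
  v <- effective$values
  lab <- names(.IDX)
  S <- setNames(unname(state), lab)
  out <- data.frame(state = lab, proliferation = 0, death = 0,
                    differentiation_in = 0, differentiation_out = 0,
                    migration_in = 0, migration_out = 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- lab

  ## proliferation: plain for peripheral subsets, logistic for activated
  ## cells and thymocytes
  lamA <- v[["lamA4"]] * (1 - (S[["A_BL"]] + S[["A_LT"]]) / v[["TA4max"]])
  cortOcc <- (S[["DN_THY"]] + S[["DP_THY"]]) / effective$Tcortmax
  medOcc <- (S[["SP4_THY"]] + S[["SP8_THY"]]) / effective$Tmedmax
  for (st in names(.PROLIF_RATES)) {
    r <- if (st %in% c("A_BL", "A_LT")) lamA else v[[.PROLIF_RATES[[st]]]]
    out[st, "proliferation"] <- r * S[[st]]
  }
  out["DN_THY", "proliferation"] <- v[["pDN"]] * S[["DN_THY"]] * (1 - cortOcc)
  out["DP_THY", "proliferation"] <- v[["pDP"]] * S[["DP_THY"]] * (1 - cortOcc)
  out["SP4_THY", "proliferation"] <- v[["pSP"]] * S[["SP4_THY"]] * (1 - medOcc)
  out["SP8_THY", "proliferation"] <- v[["pSP"]] * S[["SP8_THY"]] * (1 - medOcc)

  for (st in lab) out[st, "death"] <- -v[[.DEATH_RATES[[st]]]] * S[[st]]
  ## SP8 egress leaves the modelled system (no CD8 periphery): a pure loss
  out["SP8_THY", "migration_out"] <- -v[["sigmaSP4"]] * S[["SP8_THY"]]

  for (k in seq_len(nrow(.DIFFERENTIATION_EDGES))) {
    ed <- .DIFFERENTIATION_EDGES[k, ]
    fl <- v[[ed$rate]] * .frac_value(ed$frac, v) * S[[ed$from]]
    out[ed$from, "differentiation_out"] <-
      out[ed$from, "differentiation_out"] - fl
    out[ed$to, "differentiation_in"] <- out[ed$to, "differentiation_in"] + fl
  }
  for (k in seq_len(nrow(.MIGRATION_EDGES))) {
    ed <- .MIGRATION_EDGES[k, ]
    fl <- v[[ed$rate]] * S[[ed$from]]
    out[ed$from, "migration_out"] <- out[ed$from, "migration_out"] - fl
    if (!is.na(ed$to)) {
      out[ed$to, "migration_in"] <- out[ed$to, "migration_in"] + fl
    }
  }
  out$total <- out$proliferation + out$death + out$differentiation_in +
    out$differentiation_out + out$migration_in + out$migration_out
  class(out) <- c("cd4_flux_breakdown", "data.frame")
  out
}

## Trajectory integration ----------------------------------------------------

#' Simulate a trajectory of the homeostasis model
#'
#' Stiff-capable integration (deSolve's `lsoda`) with the age- and
#' concentration-dependent rates re-evaluated continuously along the
#' trajectory: at each step the chronological age is `age0 + t / 365.25`
#' and, in the feedback variant, the RTE blood concentration is read off the
#' current state.
#'
#' @param initial Initial state (24 non-negative counts; see
#'   [state_vector()]).
#' @param params Base `cd4_parameters`.
#' @param modulations A `cd4_modulations` object.
#' @param t_grid Strictly increasing output times in days (first element is
#'   the start time, typically 0).
#' @param age0 Age in years at `t_grid[1]`.
#' @param sp4_clamp_from Optional time (days) from which the SP4 thymocyte
#'   state is clamped to zero (complete thymectomy).
#' @param rtol,atol Solver tolerances (relative; absolute in cells).
#' @return A data.frame with columns `time_days`, `age_years` and the 24
#'   state columns; negative solver undershoots below `atol` are clipped
#'   to 0.
#' @export
simulate_trajectory <- function(initial, params = default_parameters(),
                                modulations = default_modulations(),
                                t_grid, age0 = 0, sp4_clamp_from = NULL,
                                rtol = 1e-8, atol = 1e-3) {
  if (any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (any(initial < 0)) stop("initial state must be non-negative",
                             call. = FALSE)
  params <- validate_parameters(params)
  iRTE <- .IDX$RTE_BL
  iSP4 <- .IDX$SP4_THY
  clamp <- !is.null(sp4_clamp_from)
  if (clamp && t_grid[1] >= sp4_clamp_from) initial[iSP4] <- 0

  vbase <- params$values
  compiled <- .compile_modulations(modulations, names(vbase))
  phys <- modulations$physiology
  func <- function(t, y, parms) {
    y <- pmax(y, 0)
    if (clamp && t >= sp4_clamp_from) y[iSP4] <- 0
    age <- age0 + t / 365.25
    bw <- phys$bw_adult * (phys$bw_birth / phys$bw_adult)^exp(-phys$k_bw *
                                                                age)
    bv <- phys$bv_adult * bw / phys$bw_adult
    cRTE <- y[iRTE] / (bv * 1e6)
    v <- .fast_effective_values(age, cRTE, vbase, compiled)
    w <- phys$w_birth * (1 + phys$w_growth *
                           (1 - exp(-age / phys$tau_growth))) *
      exp(-phys$k_involution * age)
    matur <- 1 + phys$cap_growth * (1 - exp(-age / phys$cap_tau))
    d <- .rhs_core(y, v, phys$kappa_cort * w * matur,
                   phys$kappa_med * w * matur)
    if (clamp && t >= sp4_clamp_from) d[iSP4] <- 0
    list(d)
  }
  sol <- deSolve::lsoda(y = unname(as.numeric(initial)), times = t_grid,
                        func = func, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed at t = ", max(sol[, 1]), " days (state: ",
         paste(signif(sol[nrow(sol), -1], 4), collapse = ", "), ")",
         call. = FALSE)
  }
  m <- as.matrix(sol[, -1, drop = FALSE])
  m[m < 0 & m > -atol] <- 0
  colnames(m) <- names(.IDX)
  out <- data.frame(time_days = sol[, 1],
                    age_years = age0 + sol[, 1] / 365.25)
  cbind(out, as.data.frame(m))
}

#' Write a trajectory as tidy CSV
#'
#' @param trajectory Output of [simulate_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly. Columns: `time_days`, `age_years`,
#'   `subpopulation`, `compartment`, `count`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  lay <- compartment_layout()
  long <- do.call(rbind, lapply(seq_len(nrow(lay)), function(k) {
    data.frame(time_days = trajectory$time_days,
               age_years = trajectory$age_years,
               subpopulation = lay$subpop[k],
               compartment = lay$compartment[k],
               count = trajectory[[lay$label[k]]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

## Steady state --------------------------------------------------------------

.thymus_steady_state <- function(v, Tcort, Tmed) {
  ## DN requires net positive logistic growth for a non-trivial fixed point
  net <- v[["dltDN"]] + v[["muDN"]]
  if (v[["pDN"]] <= net || Tcort <= 0) {
    return(c(DN = 0, DP = 0, SP4 = 0, SP8 = 0))
  }
  u <- 1 - net / v[["pDN"]]            # cortical occupancy (DN+DP)/Tcort
  denDP <- v[["dltDP"]] + v[["muDP"]] - v[["pDP"]] * (1 - u)
  if (denDP <= 0) {
    stop("thymocyte submodel has no stable fixed point (DP growth exceeds ",
         "loss at cortical occupancy)", call. = FALSE)
  }
  cDP <- v[["dltDN"]] / denDP
  DN <- u * Tcort / (1 + cDP)
  DP <- cDP * DN
  Iin <- v[["dltDP"]] * DP             # flux into the SP pool
  L <- v[["muSP"]] + v[["sigmaSP4"]]
  r <- v[["pSP"]]
  ## (SP4+SP8)/Tmed solves r*Tmed*vv^2 + (L - r)*Tmed*vv - Iin = 0
  if (r > 0) {
    aa <- r * Tmed; bb <- (L - r) * Tmed
    vv <- (-bb + sqrt(bb^2 + 4 * aa * Iin)) / (2 * aa)
  } else {
    vv <- Iin / (L * Tmed)
  }
  den <- L - r * (1 - vv)
  SP4 <- v[["alphaSP4"]] * Iin / den
  SP8 <- (1 - v[["alphaSP4"]]) * Iin / den
  c(DN = DN, DP = DP, SP4 = SP4, SP8 = SP8)
}

## Linear peripheral system: for fixed activated-cell proliferation rate
## lamA the 20 peripheral states satisfy M x + b = 0 with b the thymic
## egress into blood RTE. The matrix is assembled from the same declarative
## flux inventory as flow_audit; the assembly is compiled once into flat
## index/rate/sign vectors so repeated builds inside the logistic root
## find stay cheap.
.PERIPHERAL_ASSEMBLY <- local({
  lab <- names(.IDX)[5:24]
  pos <- integer(0); rate <- character(0); sgn <- numeric(0)
  frac <- character(0)
  flat <- function(row, col) (match(col, lab) - 1L) * 20L + match(row, lab)
  put <- function(row, col, r, s, fr = "1") {
    pos <<- c(pos, flat(row, col)); rate <<- c(rate, r)
    sgn <<- c(sgn, s); frac <<- c(frac, fr)
  }
  for (st in lab) {
    put(st, st, .DEATH_RATES[[st]], -1)
    if (st %in% names(.PROLIF_RATES) && !st %in% c("A_BL", "A_LT")) {
      put(st, st, .PROLIF_RATES[[st]], +1)
    }
  }
  for (k in seq_len(nrow(.DIFFERENTIATION_EDGES))) {
    ed <- .DIFFERENTIATION_EDGES[k, ]
    if (!ed$from %in% lab) next
    put(ed$from, ed$from, ed$rate, -1, ed$frac)
    if (ed$to %in% lab) put(ed$to, ed$from, ed$rate, +1, ed$frac)
  }
  for (k in seq_len(nrow(.MIGRATION_EDGES))) {
    ed <- .MIGRATION_EDGES[k, ]
    if (!ed$from %in% lab) next
    put(ed$from, ed$from, ed$rate, -1)
    if (!is.na(ed$to) && ed$to %in% lab) put(ed$to, ed$from, ed$rate, +1)
  }
  list(lab = lab, pos = pos, rate = rate, sgn = sgn, frac = frac,
       lamA_pos = c(flat("A_BL", "A_BL"), flat("A_LT", "A_LT")))
})

.frac_multiplier <- function(frac, v) {
  out <- rep(1, length(frac))
  out[frac == "alphaSP4"] <- v[["alphaSP4"]]
  out[frac == "1-alphaSP4"] <- 1 - v[["alphaSP4"]]
  out[frac == "f4"] <- v[["f4"]]
  out[frac == "1-f4"] <- 1 - v[["f4"]]
  out
}

## base matrix with the activated-cell proliferation left out
.peripheral_base_matrix <- function(v) {
  sp <- .PERIPHERAL_ASSEMBLY
  w <- sp$sgn * unname(v[sp$rate]) * .frac_multiplier(sp$frac, v)
  agg <- rowsum(w, sp$pos)
  M <- numeric(400L)
  M[as.integer(rownames(agg))] <- agg
  dim(M) <- c(20L, 20L)
  dimnames(M) <- list(sp$lab, sp$lab)
  M
}

.peripheral_matrix <- function(v, lamA) {
  M <- .peripheral_base_matrix(v)
  M[.PERIPHERAL_ASSEMBLY$lamA_pos] <- M[.PERIPHERAL_ASSEMBLY$lamA_pos] + lamA
  M
}

.peripheral_solve <- function(v, lamA, egress, raw = FALSE,
                              base_M = NULL) {
  if (is.null(base_M)) base_M <- .peripheral_base_matrix(v)
  M <- base_M
  M[.PERIPHERAL_ASSEMBLY$lamA_pos] <- M[.PERIPHERAL_ASSEMBLY$lamA_pos] + lamA
  b <- setNames(numeric(20), rownames(M))
  b[["RTE_BL"]] <- egress
  if (egress == 0) return(b * 0)
  x <- tryCatch(solve(M, -b), error = function(e) rep(NA_real_, 20))
  names(x) <- rownames(M)
  if (raw) x else pmax(x, 0)
}

#' Steady state of the homeostasis model at a fixed age
#'
#' Computes the non-negative fixed point of the 24-state system with the
#' age-dependent rates frozen at `age_fixed`. The thymocyte subsystem is
#' solved in closed form; the RTE-concentration feedback (if active) is
#' resolved by scalar root finding; the peripheral subsystem is solved as a
#' linear system for each trial value of the total activated-cell count,
#' whose logistic self-limitation is closed by a second scalar root find.
#' The result is verified against [full_rhs()] and, if needed, polished by
#' a damped Newton iteration.
#'
#' @param params Base `cd4_parameters`.
#' @param modulations A `cd4_modulations` object.
#' @param age_fixed Age in years at which rates are frozen.
#' @param tol Relative residual tolerance (default 1e-8).
#' @return A named 24-state vector with attributes `age`, `residual`
#'   (relative), `C_RTE` (cells/uL) and `effective` (the frozen rates).
#' @export
solve_steady_state <- function(params = default_parameters(),
                               modulations = default_modulations(),
                               age_fixed = 0, tol = 1e-8) {
  if (age_fixed < 0) stop("age_fixed must be non-negative", call. = FALSE)
  params <- validate_parameters(params)
  eff0 <- effective_parameters(age_fixed, 0, params, modulations)
  v0 <- eff0$values
  thy <- .thymus_steady_state(v0, eff0$Tcortmax, eff0$Tmedmax)
  egress <- v0[["sigmaSP4"]] * thy[["SP4"]]
  bv_uL <- eff0$BV * 1e6

  ## resolve the RTE-concentration feedback (RTE is upstream of everything
  ## else, so its blood concentration solves a scalar fixed-point equation)
  cRTE <- 0
  if (modulations$variant == "AGE_PLUS_FEEDBACK" && egress > 0) {
    fb <- modulations$feedback
    cfun <- function(cc) {
      mu <- feedback_rte_death(cc, fb$muRTE4base, fb$muRTE4_fmax, fb$C50_muRTE4,
                               fb$Nh_muRTE4)
      egress / (mu + v0[["omRTE4bl_lt"]]) / bv_uL - cc
    }
    chi <- egress / (fb$muRTE4base + v0[["omRTE4bl_lt"]]) / bv_uL
    cRTE <- stats::uniroot(cfun, c(0, chi * (1 + 1e-9)),
                           tol = max(1e-12, chi * 1e-12))$root
  } else if (egress > 0) {
    cRTE <- egress / (v0[["muRTE4"]] + v0[["omRTE4bl_lt"]]) / bv_uL
  }
  eff <- effective_parameters(age_fixed, cRTE, params, modulations)
  v <- eff$values

  ## close the activated-cell logistic term by root finding on the total;
  ## an infeasible (negative or singular) linear solution means the
  ## saturation is not yet strong enough, i.e. the total must grow
  if (egress > 0) {
    base_M <- .peripheral_base_matrix(v)
    asum <- function(s) {
      lamA <- v[["lamA4"]] * (1 - s / v[["TA4max"]])
      x <- .peripheral_solve(v, lamA, egress, raw = TRUE, base_M = base_M)
      if (any(!is.finite(x)) || any(x < -1e-9 * max(abs(x)))) return(NA_real_)
      x[["A_BL"]] + x[["A_LT"]]
    }
    gfun <- function(s) {
      a <- asum(s)
      if (is.na(a)) 1 else a - s
    }
    ## fixed-point iteration handles the common weakly-saturated case in a
    ## couple of linear solves; fall back to bracketed root finding
    sA <- NA_real_
    s <- 0
    for (it in 1:12) {
      a <- asum(s)
      if (is.na(a)) break
      if (abs(a - s) <= 1e-10 * max(a, 1)) { sA <- a; break }
      s <- a
    }
    if (is.na(sA)) {
      hi <- v[["TA4max"]]
      while (gfun(hi) > 0 && hi < v[["TA4max"]] * 1e6) hi <- hi * 10
      if (gfun(hi) > 0) {
        stop("peripheral system has no non-negative fixed point at this ",
             "age (a subpopulation's growth exceeds its losses)",
             call. = FALSE)
      }
      sA <- if (gfun(0) <= 0) 0 else
        stats::uniroot(gfun, c(0, hi), tol = 1e-10 * v[["TA4max"]])$root
    }
    lamA <- v[["lamA4"]] * (1 - sA / v[["TA4max"]])
    xper <- .peripheral_solve(v, lamA, egress, base_M = base_M)
  } else {
    xper <- setNames(numeric(20), names(.IDX)[5:24])
  }
  x <- c(DN_THY = unname(thy[["DN"]]), DP_THY = unname(thy[["DP"]]),
         SP4_THY = unname(thy[["SP4"]]), SP8_THY = unname(thy[["SP8"]]),
         xper)

  res <- .rel_residual(x, eff)
  if (res > tol) {
    pol <- .newton_polish(x, eff, tol)
    x <- pol$x
    res <- pol$residual
  }
  if (res > tol) {
    stop("steady-state solve did not converge: relative residual ",
         signif(res, 3), call. = FALSE)
  }
  if (any(x < 0)) stop("negative component in refined steady state",
                       call. = FALSE)
  attr(x, "age") <- age_fixed
  attr(x, "residual") <- res
  attr(x, "C_RTE") <- if (bv_uL > 0) x[["RTE_BL"]] / bv_uL else 0
  attr(x, "effective") <- eff
  x
}

.rel_residual <- function(x, eff) {
  f <- full_rhs(x, eff)
  scale <- pmax(x, 1e-6 * max(x, 1))
  max(abs(f) / scale)
}

.newton_polish <- function(x, eff, tol, max_iter = 40) {
  act <- which(x > 0)
  for (it in seq_len(max_iter)) {
    f <- full_rhs(x, eff)
    res <- .rel_residual(x, eff)
    if (res <= tol) break
    J <- matrix(0, length(act), length(act))
    for (jj in seq_along(act)) {
      h <- max(1e-7 * x[act[jj]], 1e-4)
      xp <- x; xp[act[jj]] <- xp[act[jj]] + h
      J[, jj] <- (full_rhs(xp, eff)[act] - f[act]) / h
    }
    step <- tryCatch(solve(J, -f[act]), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x
      xn[act] <- pmax(x[act] + lam * step, 0)
      if (.rel_residual(xn, eff) < res || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
  }
  list(x = x, residual = .rel_residual(x, eff))
}
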