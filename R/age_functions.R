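## Age- and concentration-dependent modulation of kinetic rates --------------
##
## Three model variants are supported:
##   STATIC            - only thymic capacities and blood volume vary with age;
##   AGE               - 13 empirical hyperbolic (Hill-type) age functions
##                       modulate peripheral rates;
##   AGE_PLUS_FEEDBACK - the naive-proliferation and RTE-death age functions
##                       are replaced by feedback on the blood concentration
##                       of recent thymic emigrants; the other 11 persist.

#' Saturating (Hill) increase of a rate with age
#'
#' `base * (1 + amax * age^h / (age50^h + age^h))`: equals `base` at age 0,
#' `base * (1 + amax/2)` at `age50`, and saturates at `base * (1 + amax)`.
#'
#' @param age Age in years (vectorised, `>= 0`).
#' @param base Baseline (age-0) rate, 1/day.
#' @param amax Maximal relative increase (dimensionless, `>= 0`).
#' @param age50 Age of half-maximal effect, years (`> 0`).
#' @param h Hill coefficient (`>= 1`).
#' @return Modulated rate(s), same units as `base`.
#' @export
hill_up <- function(age, base, amax, age50, h = 1) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  if (age50 <= 0) stop("age50 must be positive", call. = FALSE)
  if (amax < 0) stop("amax must be non-negative", call. = FALSE)
  base * (1 + amax * age^h / (age50^h + age^h))
}

#' Saturating (Hill) decrease of a rate with age
#'
#' `base * (1 - dmax * age^h / (age50^h + age^h))`: equals `base` at age 0
#' and tends to `base * (1 - dmax)`; `dmax = 1` means a 100% decrease.
#'
#' @inheritParams hill_up
#' @param dmax Maximal relative decrease, in \[0, 1\].
#' @return Modulated rate(s).
#' @export
hill_down <- function(age, base, dmax, age50, h = 1) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  if (age50 <= 0) stop("age50 must be positive", call. = FALSE)
  if (dmax < 0 || dmax > 1) stop("dmax must lie in [0, 1]", call. = FALSE)
  base * (1 - dmax * age^h / (age50^h + age^h))
}

#' Empirical age-dependency curve (four candidate functional forms)
#'
#' Generic evaluation of the candidate forms screened during stepwise
#' selection. The hyperbolic form is the package default; linear,
#' exponential and quadratic forms are provided as alternatives for model
#' selection only. Decreasing forms are clipped at zero.
#'
#' @param age Age in years.
#' @param base Baseline rate at age 0.
#' @param direction `"up"` or `"down"`.
#' @param form One of `"hyperbolic"`, `"linear"`, `"exponential"`,
#'   `"quadratic"`.
#' @param pars Named list of form parameters: hyperbolic uses `max_change`,
#'   `age50`, `hill`; linear uses `slope` (1/years); exponential uses
#'   `max_change`, `tau` (years); quadratic uses `s1` (1/years), `s2`
#'   (1/years^2).
#' @return Rate(s) at `age`.
#' @export
age_curve <- function(age, base, direction = c("up", "down"),
                      form = c("hyperbolic", "linear", "exponential",
                               "quadratic"),
                      pars) {
  direction <- match.arg(direction)
  form <- match.arg(form)
  sgn <- if (direction == "up") 1 else -1
  val <- switch(form,
    hyperbolic = if (direction == "up") {
      hill_up(age, base, pars$max_change, pars$age50,
              if (is.null(pars$hill)) 1 else pars$hill)
    } else {
      hill_down(age, base, pars$max_change, pars$age50,
                if (is.null(pars$hill)) 1 else pars$hill)
    },
    linear = base * (1 + sgn * pars$slope * age),
    exponential = base * (1 + sgn * pars$max_change *
                            (1 - exp(-age / pars$tau))),
    quadratic = base * (1 + sgn * (pars$s1 * age + pars$s2 * age^2))
  )
  pmax(val, 0)
}

## Physiology: body weight, blood volume, thymus wet weight ------------------

.PHYSIOLOGY_DEFAULTS <- list(
  bw_birth = 3.5,    # kg
  bw_adult = 70,     # kg
  k_bw     = 0.18,   # 1/years, Gompertz growth-rate constant
  bv_adult = 5,      # litres
  w_birth  = 15,     # g, thymus wet weight at birth
  w_growth = 1.5,    # relative early-childhood thymic growth amplitude
  tau_growth = 0.5,  # years, time constant of early thymic growth
  k_involution = 0.044, # 1/years, exponential involution rate
  kappa_cort = 3e8,  # cells per gram wet weight, cortical capacity
  kappa_med  = 1.65e7, # cells per gram wet weight, medullary capacity
  cap_growth = 6,    # maturation amplitude of thymopoietic capacity
  cap_tau    = 5     # years, time constant of capacity maturation
)

#' Body weight versus age (Gompertz growth curve)
#' @param age Age in years.
#' @param constants Physiology constant list (see [default_modulations()]).
#' @return Body weight in kg.
#' @export
body_weight <- function(age, constants = .PHYSIOLOGY_DEFAULTS) {
  with(constants,
       bw_adult * (bw_birth / bw_adult)^exp(-k_bw * age))
}

#' Blood volume versus age
#'
#' Adult blood volume scaled by the body-weight growth curve:
#' `BV(age) = bv_adult * BW(age) / bw_adult`. With the defaults (3.5 kg at
#' birth, 70 kg adult, 5 L adult) the newborn volume is 0.25 L.
#'
#' @inheritParams body_weight
#' @return Blood volume in litres.
#' @export
blood_volume <- function(age, constants = .PHYSIOLOGY_DEFAULTS) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  constants$bv_adult * body_weight(age, constants) / constants$bw_adult
}

#' Thymus wet weight versus age
#'
#' Product of a saturating early-childhood growth term and exponential
#' involution: `W(age) = w_birth * (1 + g * (1 - exp(-age/tau))) *
#' exp(-k_inv * age)`. With the defaults the curve peaks within the first
#' ~2 years of life and then declines.
#'
#' @inheritParams body_weight
#' @return Wet weight in grams.
#' @export
thymus_wet_weight <- function(age, constants = .PHYSIOLOGY_DEFAULTS) {
  with(constants,
       w_birth * (1 + w_growth * (1 - exp(-age / tau_growth))) *
         exp(-k_involution * age))
}

#' Thymic cortical and medullary carrying capacities versus age
#'
#' Capacities proportional to the wet-weight curve times a maturation
#' factor `1 + cap_growth * (1 - exp(-age/cap_tau))`: the thymopoietically
#' active epithelial space matures through childhood far more than organ
#' wet weight does (thymic output rises roughly tenfold from birth to young
#' adulthood before involution dominates). The capacities bound logistic
#' proliferation of (DN + DP) and (SP4 + SP8) thymocytes respectively, so
#' thymic involution is expressed as a shrinking niche.
#'
#' @inheritParams body_weight
#' @return Named numeric vector `c(Tcortmax =, Tmedmax =)` in cells.
#' @export
thymus_capacity <- function(age, constants = .PHYSIOLOGY_DEFAULTS) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  w <- thymus_wet_weight(age, constants)
  matur <- 1 + constants$cap_growth * (1 - exp(-age / constants$cap_tau))
  c(Tcortmax = constants$kappa_cort * w * matur,
    Tmedmax = constants$kappa_med * w * matur)
}

## RTE-concentration feedback ------------------------------------------------

#' Naive-cell proliferation rate under RTE-concentration feedback
#'
#' Proliferation of naive CD4+ T cells adapts to thymic output: it is maximal
#' (`lamN4base`) when recent thymic emigrants are absent from blood and is
#' repressed towards `lamN4base * (1 - fmax)` at high RTE concentrations.
#' The steep Hill coefficient (default 10) expresses the switch-like onset
#' of the adaptation once RTE concentration falls below `C50`.
#'
#' @param C_RTE RTE blood concentration, cells/uL (`>= 0`).
#' @param lamN4base Proliferation rate at `C_RTE = 0`, 1/day.
#' @param fmax Maximal relative repression, in \[0, 1\].
#' @param C50 Half-effect RTE concentration, cells/uL.
#' @param Nh Hill coefficient.
#' @return Proliferation rate, 1/day.
#' @export
feedback_naive_prolif <- function(C_RTE, lamN4base, fmax, C50, Nh = 10) {
  if (any(C_RTE < 0)) stop("C_RTE must be non-negative", call. = FALSE)
  if (fmax < 0 || fmax > 1) stop("fmax must lie in [0, 1]", call. = FALSE)
  lamN4base * (1 - fmax * C_RTE^Nh / (C50^Nh + C_RTE^Nh))
}

#' RTE death rate under RTE-concentration feedback
#'
#' Death of recent thymic emigrants increases with their own blood
#' concentration (density-dependent survival): the rate equals `muRTE4base`
#' at zero concentration and rises towards `muRTE4base * (1 + fmax)`.
#'
#' @inheritParams feedback_naive_prolif
#' @param muRTE4base Death rate at `C_RTE = 0`, 1/day.
#' @param fmax Maximal relative increase (`>= 0`).
#' @return Death rate, 1/day.
#' @export
feedback_rte_death <- function(C_RTE, muRTE4base, fmax, C50, Nh = 10) {
  if (any(C_RTE < 0)) stop("C_RTE must be non-negative", call. = FALSE)
  if (fmax < 0) stop("fmax must be non-negative", call. = FALSE)
  muRTE4base * (1 + fmax * C_RTE^Nh / (C50^Nh + C_RTE^Nh))
}

## Modulation sets -----------------------------------------------------------

.mod_entry <- function(target, direction, max_change, age50, hill = 1,
                       group = NA_character_, form = "hyperbolic",
                       slope = NA_real_, tau = NA_real_,
                       s1 = NA_real_, s2 = NA_real_) {
  list(target = target, direction = direction, form = form,
       max_change = max_change, age50 = age50, hill = hill, group = group,
       slope = slope, tau = tau, s1 = s1, s2 = s2)
}

#' Default age/feedback modulation set (the packaged calibrated model)
#'
#' Returns the package's calibrated set of 13 hyperbolic age functions
#' (variant `"AGE"`), or 11 age functions plus the two RTE-concentration
#' feedback functions (variant `"AGE_PLUS_FEEDBACK"`), or no rate modulation
#' at all (variant `"STATIC"`). Six increasing functions target naive and
#' activated proliferation, effector-memory lung egress and effector
#' dissemination; seven decreasing functions target RTE death and lymphoid
#' homing, memory differentiation and lymphoid-tissue egress. Hill
#' coefficients are fixed at 10 for the naive-proliferation age shift, 3 for
#' the central-memory differentiation decline, and 1 elsewhere; the maximal
#' relative decrease is fixed at 1 (100%) for all decreasing functions
#' except RTE death. The five effector/effector-memory migration functions
#' share one half-effect age (`group = "eff_onset"`).
#'
#' @param variant `"STATIC"`, `"AGE"` or `"AGE_PLUS_FEEDBACK"`.
#' @return An object of class `cd4_modulations`: a list with fields
#'   `variant`, `entries` (list of per-parameter modulation descriptors),
#'   `feedback` (feedback constants) and `physiology`.
#' @export
default_modulations <- function(variant = c("AGE_PLUS_FEEDBACK", "AGE",
                                            "STATIC")) {
  variant <- match.arg(variant)
  entries <- list(
    .mod_entry("lamN4",        "up",   0.0012 / 0.0007 - 1, 50, hill = 10),
    .mod_entry("lamA4",        "up",   0.024, 10),
    .mod_entry("omEM4lung_bl", "up",   1.00, 15, group = "eff_onset"),
    .mod_entry("omEFF4bl_git", "up",   1.00, 15, group = "eff_onset"),
    .mod_entry("omEFF4bl_lung","up",   1.00, 15, group = "eff_onset"),
    .mod_entry("omEFF4bl_tis", "up",   1.00, 15, group = "eff_onset"),
    .mod_entry("muRTE4",       "down", 0.80, 40),
    .mod_entry("omRTE4bl_lt",  "down", 1.00, 30),
    .mod_entry("phiCM4",       "down", 1.00, 40, hill = 3),
    .mod_entry("phiEM4",       "down", 1.00, 15, group = "eff_onset"),
    .mod_entry("omA4lt_bl",    "down", 1.00, 30),
    .mod_entry("omCM4lt_bl",   "down", 1.00, 30),
    .mod_entry("omEFF4lt_bl",  "down", 1.00, 30)
  )
  names(entries) <- vapply(entries, `[[`, "", "target")
  feedback <- list(
    lamN4base = 0.0012,    # naive proliferation at zero RTE concentration
    lamN4_fmax = 1 - 0.0007 / 0.0012,  # repressed back to the newborn value
    muRTE4base = 0.00152,  # RTE death at zero RTE concentration
    muRTE4_fmax = 4,       # raised 5-fold at high RTE concentration
    C50_lamN4 = 195,       # cells/uL: naive-proliferation adaptation sets
                           # in when RTE fall below the ~age-55 level
    C50_muRTE4 = 310,      # cells/uL: RTE-survival adaptation sets in
                           # earlier, around the ~age-40 level
    Nh_lamN4 = 10, Nh_muRTE4 = 10
  )
  structure(list(variant = variant, entries = entries, feedback = feedback,
                 physiology = .PHYSIOLOGY_DEFAULTS),
            class = "cd4_modulations")
}

#' @export
print.cd4_modulations <- function(x, ...) {
  cat("CD4+ homeostasis modulation set, variant", x$variant, "with",
      length(x$entries), "age functions\n")
  invisible(x)
}

.eval_entry <- function(entry, age, base) {
  age_curve(age, base, entry$direction, entry$form,
            pars = entry)
}

#' Effective kinetic rates at a given age and RTE concentration
#'
#' Applies the modulation set to the base kinetic parameters and evaluates
#' the age-dependent physiology. Under `"STATIC"` only thymic capacities and
#' blood volume vary with age; under `"AGE"` the 13 age functions are
#' applied; under `"AGE_PLUS_FEEDBACK"` the naive-proliferation and
#' RTE-death rates respond to `C_RTE` instead of age while the remaining 11
#' age functions persist.
#'
#' @param age Age in years (scalar).
#' @param C_RTE RTE blood concentration in cells/uL (scalar; only used by
#'   the feedback variant).
#' @param params Base `cd4_parameters`.
#' @param modulations A `cd4_modulations` object.
#' @return A list of class `cd4_effective_rates` with fields `values`
#'   (named rate vector), `Tcortmax`, `Tmedmax`, `BV` (litres), `age`,
#'   `C_RTE`.
#' @export
effective_parameters <- function(age, C_RTE = 0, params = default_parameters(),
                                 modulations = default_modulations()) {
  params <- as_parameters(params)
  v <- params$values
  variant <- modulations$variant
  if (!variant %in% c("STATIC", "AGE", "AGE_PLUS_FEEDBACK")) {
    stop("unknown model variant: ", variant, call. = FALSE)
  }
  if (variant != "STATIC") {
    entries <- modulations$entries
    if (variant == "AGE_PLUS_FEEDBACK") {
      entries <- entries[setdiff(names(entries), c("lamN4", "muRTE4"))]
    }
    for (e in entries) {
      if (!e$target %in% names(v)) {
        stop("modulation targets unknown parameter: ", e$target,
             call. = FALSE)
      }
      v[[e$target]] <- .eval_entry(e, age, v[[e$target]])
    }
    if (variant == "AGE_PLUS_FEEDBACK") {
      fb <- modulations$feedback
      v[["lamN4"]] <- feedback_naive_prolif(C_RTE, fb$lamN4base,
                                            fb$lamN4_fmax, fb$C50_lamN4,
                                            fb$Nh_lamN4)
      v[["muRTE4"]] <- feedback_rte_death(C_RTE, fb$muRTE4base,
                                          fb$muRTE4_fmax, fb$C50_muRTE4,
                                          fb$Nh_muRTE4)
    }
  }
  caps <- thymus_capacity(age, modulations$physiology)
  structure(list(values = v,
                 Tcortmax = caps[["Tcortmax"]],
                 Tmedmax = caps[["Tmedmax"]],
                 BV = blood_volume(age, modulations$physiology),
                 age = age, C_RTE = C_RTE),
            class = "cd4_effective_rates")
}

## Compiled fast path for ODE integration: the modulation set is flattened
## once into index/constant vectors so that per-step evaluation involves no
## list construction or argument matching.
.compile_modulations <- function(modulations, vnames) {
  entries <- modulations$entries
  if (modulations$variant == "AGE_PLUS_FEEDBACK") {
    entries <- entries[setdiff(names(entries), c("lamN4", "muRTE4"))]
  }
  if (modulations$variant == "STATIC") entries <- list()
  plan <- lapply(entries, function(e) {
    list(idx = match(e$target, vnames),
         sgn = if (e$direction == "up") 1 else -1,
         form = e$form, mc = e$max_change, a50 = e$age50, h = e$hill,
         slope = e$slope, tau = e$tau, s1 = e$s1, s2 = e$s2)
  })
  fb <- modulations$feedback
  list(variant = modulations$variant, plan = plan, fb = fb,
       phys = modulations$physiology,
       i_lamN4 = match("lamN4", vnames),
       i_muRTE4 = match("muRTE4", vnames))
}

.fast_effective_values <- function(age, cRTE, vbase, compiled) {
  v <- vbase
  for (e in compiled$plan) {
    b <- vbase[e$idx]
    v[e$idx] <- switch(e$form,
      hyperbolic = b * (1 + e$sgn * e$mc * age^e$h / (e$a50^e$h + age^e$h)),
      linear = max(b * (1 + e$sgn * e$slope * age), 0),
      exponential = b * (1 + e$sgn * e$mc * (1 - exp(-age / e$tau))),
      quadratic = max(b * (1 + e$sgn * (e$s1 * age + e$s2 * age^2)), 0))
  }
  if (compiled$variant == "AGE_PLUS_FEEDBACK") {
    fb <- compiled$fb
    hl <- cRTE^fb$Nh_lamN4 / (fb$C50_lamN4^fb$Nh_lamN4 + cRTE^fb$Nh_lamN4)
    hm <- cRTE^fb$Nh_muRTE4 / (fb$C50_muRTE4^fb$Nh_muRTE4 +
                                 cRTE^fb$Nh_muRTE4)
    if (cRTE == 0) { hl <- 0; hm <- 0 }
    v[compiled$i_lamN4] <- fb$lamN4base * (1 - fb$lamN4_fmax * hl)
    v[compiled$i_muRTE4] <- fb$muRTE4base * (1 + fb$muRTE4_fmax * hm)
  }
  v
}

.serialize_modulations <- function(mod) {
  list(variant = mod$variant,
       entries = lapply(unname(mod$entries), function(e) e),
       feedback = mod$feedback,
       physiology = mod$physiology)
}

.deserialize_modulations <- function(obj) {
  entries <- lapply(seq_len(if (is.data.frame(obj$entries)) nrow(obj$entries)
                            else length(obj$entries)),
                    function(i) {
    e <- if (is.data.frame(obj$entries)) as.list(obj$entries[i, ])
         else obj$entries[[i]]
    do.call(.mod_entry, e[c("target", "direction", "max_change", "age50",
                            "hill", "group", "form", "slope", "tau",
                            "s1", "s2")])
  })
  names(entries) <- vapply(entries, `[[`, "", "target")
  structure(list(variant = obj$variant, entries = entries,
                 feedback = lapply(obj$feedback, as.numeric),
                 physiology = lapply(obj$physiology, as.numeric)),
            class = "cd4_modulations")
}
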