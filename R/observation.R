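## Observation model ---------------------------------------------------------
##
## The calibration data are blood concentrations (cells/uL) of the six
## peripheral subpopulations and within-compartment percentages of the
## subpopulations present in lymphoid tissue (all six), the
## gastro-intestinal tract and lungs (naive, CM, EM, EFF), 20 observables in
## all. Blood counts are converted to concentrations through the
## age-dependent blood volume; percentages are computed from the sums of the
## state variables within each compartment.

.PERIPHERAL_SUBPOPS <- c("RTE", "N", "A", "CM", "EM", "EFF")

#' Identifiers of the 20 calibration observables
#'
#' @return Character vector: `BL_<S>_conc` for the six blood concentrations
#'   and `<C>_<S>_pct` for tissue percentages.
#' @export
observable_ids <- function() {
  c(paste0("BL_", .PERIPHERAL_SUBPOPS, "_conc"),
    paste0("LT_", .PERIPHERAL_SUBPOPS, "_pct"),
    paste0("GIT_", c("N", "CM", "EM", "EFF"), "_pct"),
    paste0("LUNG_", c("N", "CM", "EM", "EFF"), "_pct"))
}

#' Map a model state to the calibration observables and derived totals
#'
#' @param state Named 24-state vector (cells).
#' @param BV Blood volume in litres (`> 0`).
#' @return A list of class `cd4_observables` with `values` (named vector of
#'   the 20 calibration observables), `totals` (total and memory CD4+ blood
#'   concentrations, cells/uL, and total CD4+ counts per compartment,
#'   cells) and `degenerate` (names of all-zero compartments, whose
#'   percentages are reported as 0).
#' @examples
#' s <- state_vector(c(N_BL = 5e9))
#' observables_from_state(s, BV = 5)$values[["BL_N_conc"]]  # 1000
#' @export
observables_from_state <- function(state, BV) {
  if (BV <= 0) stop("blood volume must be positive", call. = FALSE)
  lab <- names(.IDX)
  S <- setNames(unname(state[seq_along(lab)]), lab)
  bv_uL <- BV * 1e6
  vals <- setNames(numeric(length(observable_ids())), observable_ids())
  for (sp in .PERIPHERAL_SUBPOPS) {
    vals[[paste0("BL_", sp, "_conc")]] <- S[[paste0(sp, "_BL")]] / bv_uL
  }
  degenerate <- character(0)
  for (comp in c("LT", "GIT", "LUNG")) {
    present <- intersect(paste0(.PERIPHERAL_SUBPOPS, "_", comp), lab)
    tot <- sum(S[present])
    for (nm in present) {
      sp <- sub(paste0("_", comp, "$"), "", nm)
      id <- paste0(comp, "_", sp, "_pct")
      if (!id %in% names(vals)) next
      vals[[id]] <- if (tot > 0) 100 * S[[nm]] / tot else 0
    }
    if (tot == 0) degenerate <- c(degenerate, comp)
  }
  comp_total <- vapply(c("BL", "LT", "GIT", "LUNG"), function(comp) {
    sum(S[intersect(paste0(.PERIPHERAL_SUBPOPS, "_", comp), lab)])
  }, numeric(1))
  totals <- c(
    BL_total_conc = unname(comp_total[["BL"]]) / bv_uL,
    BL_memory_conc = (S[["CM_BL"]] + S[["EM_BL"]]) / bv_uL,
    total_BL = unname(comp_total[["BL"]]),
    total_LT = unname(comp_total[["LT"]]),
    total_GIT = unname(comp_total[["GIT"]]),
    total_LUNG = unname(comp_total[["LUNG"]])
  )
  structure(list(values = vals, totals = totals, degenerate = degenerate),
            class = "cd4_observables")
}

#' Steady-state observables at a fixed age
#'
#' Convenience wrapper: solves the steady state at `age` and maps it to the
#' observable vector. Results are memoised per (age, parameters,
#' modulations) within a session.
#'
#' @inheritParams solve_steady_state
#' @param age Age in years.
#' @param cache Logical; reuse cached solutions for repeated calls.
#' @return A `cd4_observables` object (see [observables_from_state()]).
#' @export
predict_observables <- function(age, params = default_parameters(),
                                modulations = default_modulations(),
                                cache = TRUE) {
  key <- NULL
  if (cache) {
    key <- paste(format(age, digits = 15),
                 paste(format(as_parameters(params)$values, digits = 15),
                       collapse = ","),
                 modulations$variant,
                 paste(format(unlist(lapply(modulations$entries, function(e)
                   c(e$max_change, e$age50, e$hill))), digits = 15),
                   collapse = ","),
                 paste(format(unlist(modulations$feedback), digits = 15),
                       collapse = ","),
                 sep = "|")
    hit <- .ss_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ss <- solve_steady_state(params, modulations, age_fixed = age)
  obs <- observables_from_state(ss, BV = attr(ss, "effective")$BV)
  if (cache) .ss_cache[[key]] <- obs
  obs
}

.ss_cache <- new.env(parent = emptyenv())

#' Clear the steady-state prediction cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_prediction_cache <- function() {
  n <- length(ls(.ss_cache))
  rm(list = ls(.ss_cache), envir = .ss_cache)
  invisible(n)
}

## Validation arithmetic -----------------------------------------------------

#' CD4+ share of a total T-cell count
#'
#' Splits a total (CD4+ plus CD8+) T-cell count by the CD4/CD8 ratio:
#' `total * ratio / (1 + ratio)`.
#'
#' @param total_T Total T-cell count (`>= 0`).
#' @param cd4_cd8_ratio CD4/CD8 ratio (`> 0`).
#' @return CD4+ T-cell count.
#' @examples
#' reference_cd4_counts(8e9, 2)    # ~5.3e9
#' reference_cd4_counts(1.7e10, 1) # 8.5e9
#' @export
reference_cd4_counts <- function(total_T, cd4_cd8_ratio) {
  if (any(total_T < 0)) stop("total count must be non-negative",
                             call. = FALSE)
  if (any(cd4_cd8_ratio <= 0)) stop("CD4/CD8 ratio must be positive",
                                    call. = FALSE)
  total_T * cd4_cd8_ratio / (1 + cd4_cd8_ratio)
}

#' Absolute percentage difference between prediction and observation
#'
#' @param predicted Predicted value(s).
#' @param observed Observed value(s) (`> 0`).
#' @return `100 * |predicted - observed| / observed`.
#' @export
percent_difference <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed value must be positive",
                               call. = FALSE)
  100 * abs(predicted - observed) / observed
}

## Likelihood, information criteria, identifiability -------------------------

#' Proportional-error negative log-likelihood
#'
#' Gaussian likelihood with a proportional residual error model: each row's
#' standard deviation is `CV * |prediction|` with the CVs fixed (taken from
#' the dataset, not estimated). Rows whose prediction is zero against a
#' non-zero observation contribute a large flagged penalty instead of an
#' infinite term.
#'
#' @param predicted Numeric vector of predictions matched to `data` rows.
#' @param data A calibration dataset data.frame with columns `mean` and
#'   `cv` (see [generate_calibration_dataset()]).
#' @return Scalar negative log-likelihood with attribute `n_flagged` giving
#'   the number of degenerate rows.
#' @export
proportional_loglik <- function(predicted, data) {
  if (length(predicted) != nrow(data)) {
    stop("one prediction per data row is required", call. = FALSE)
  }
  obs <- data$mean
  cv <- data$cv
  if (any(cv <= 0)) stop("CVs must be positive", call. = FALSE)
  sd <- cv * abs(predicted)
  bad <- sd == 0 & obs != 0
  ok <- !bad
  nll <- sum(0.5 * log(2 * pi * sd[ok]^2) +
               (obs[ok] - predicted[ok])^2 / (2 * sd[ok]^2))
  if (any(bad)) nll <- nll + 1e10 * sum(bad)
  structure(nll, n_flagged = sum(bad))
}

#' Akaike information criterion
#' @param nll Negative log-likelihood.
#' @param k Number of estimated structural parameters (fixed CVs excluded).
#' @return `2 * k + 2 * nll`.
#' @export
aic <- function(nll, k) 2 * k + 2 * as.numeric(nll)

#' Select the best model fit by AIC
#'
#' Returns the fit with the lowest AIC; ties are broken by the smaller
#' number of estimated parameters, then by position in the list.
#'
#' @param fits A list of `cd4_fit` objects (see [fit_multistart()]) or any
#'   lists carrying `aic` and `k` fields.
#' @return The selected fit, with attribute `aic_table` summarising all
#'   candidates.
#' @export
aic_compare <- function(fits) {
  if (length(fits) < 1) stop("no fits to compare", call. = FALSE)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  if (any(!is.finite(aics))) stop("all fits must have finite AIC",
                                  call. = FALSE)
  ord <- order(aics, ks, seq_along(fits))
  sel <- fits[[ord[1]]]
  attr(sel, "aic_table") <- data.frame(fit = seq_along(fits), aic = aics,
                                       k = ks)
  sel
}

#' Relative standard errors from the curvature of the likelihood
#'
#' Estimates standard errors from the observed information (numerical
#' Hessian of the negative log-likelihood at the optimum) and reports the
#' relative standard error `100 * SE / |estimate|` per estimated parameter.
#' Parameters with RSE above 51% are flagged unidentifiable, as is every
#' parameter when the information matrix is numerically singular.
#'
#' @param nll_fn Function of the full estimate vector returning the NLL.
#' @param estimate Named numeric vector at the optimum.
#' @param rel_step Relative finite-difference step.
#' @param rse_threshold Identifiability cut-off in percent (default 51).
#' @return data.frame with columns `parameter`, `estimate`, `se`, `rse`,
#'   `identifiable`.
#' @export
rse_estimate <- function(nll_fn, estimate, rel_step = 1e-4,
                         rse_threshold = 51) {
  p <- length(estimate)
  h <- pmax(abs(estimate) * rel_step, 1e-10)
  H <- matrix(NA_real_, p, p)
  f0 <- nll_fn(estimate)
  for (a in seq_len(p)) {
    for (b in a:p) {
      ea <- eb <- numeric(p); ea[a] <- h[a]; eb[b] <- h[b]
      fpp <- nll_fn(estimate + ea + eb)
      fpm <- nll_fn(estimate + ea - eb)
      fmp <- nll_fn(estimate - ea + eb)
      fmm <- nll_fn(estimate - ea - eb)
      H[a, b] <- H[b, a] <- (fpp - fpm - fmp + fmm) / (4 * h[a] * h[b])
    }
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    return(data.frame(parameter = names(estimate), estimate = estimate,
                      se = NA_real_, rse = NA_real_, identifiable = FALSE,
                      row.names = NULL))
  }
  se <- sqrt(diag(cov))
  rse <- 100 * se / abs(estimate)
  data.frame(parameter = names(estimate), estimate = estimate, se = se,
             rse = rse, identifiable = rse <= rse_threshold,
             row.names = NULL)
}
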