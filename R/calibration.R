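## Calibration ---------------------------------------------------------------
##
## Proportional-error maximum likelihood against age-binned steady-state
## observables, with multi-start local optimisation on log-transformed
## parameters. Free parameters are addressed by path:
##   "<name>"                a kinetic rate in the parameter set
##   "mod:<target>:<field>"  a field of an age-function entry
##                           (max_change, age50, slope, tau, s1, s2)
##   "fb:<field>"            a feedback constant (lamN4base, C50, ...)

.free_get <- function(path, params, modulations) {
  if (grepl("^mod:", path)) {
    p <- strsplit(path, ":")[[1]]
    modulations$entries[[p[2]]][[p[3]]]
  } else if (grepl("^fb:", path)) {
    modulations$feedback[[sub("^fb:", "", path)]]
  } else {
    params$values[[path]]
  }
}

.free_set <- function(path, value, params, modulations) {
  if (grepl("^mod:", path)) {
    p <- strsplit(path, ":")[[1]]
    if (is.null(modulations$entries[[p[2]]])) {
      stop("no modulation entry for target ", p[2], call. = FALSE)
    }
    modulations$entries[[p[2]]][[p[3]]] <- value
    ## shared-age50 groups move together
    if (p[3] == "age50" && !is.na(modulations$entries[[p[2]]]$group)) {
      grp <- modulations$entries[[p[2]]]$group
      for (nm in names(modulations$entries)) {
        if (identical(modulations$entries[[nm]]$group, grp)) {
          modulations$entries[[nm]]$age50 <- value
        }
      }
    }
  } else if (grepl("^fb:", path)) {
    modulations$feedback[[sub("^fb:", "", path)]] <- value
  } else {
    if (!path %in% names(params$values)) {
      stop("unknown free parameter: ", path, call. = FALSE)
    }
    params$values[[path]] <- value
  }
  list(params = params, modulations = modulations)
}

.default_bounds <- function(free, params, modulations) {
  t(vapply(free, function(path) {
    v <- .free_get(path, params, modulations)
    if (is.null(v) || !is.finite(v) || v <= 0) v <- 1e-3
    c(lo = v * 0.01, hi = v * 100)
  }, numeric(2)))
}

.dataset_predictions <- function(data, params, modulations) {
  ages <- dataset_ages(data)
  ua <- unique(ages)
  preds <- lapply(ua, function(a) {
    tryCatch(predict_observables(a, params, modulations, cache = FALSE),
             error = function(e) NULL)
  })
  names(preds) <- vapply(ua, function(a) format(a, digits = 15), "")
  vapply(seq_len(nrow(data)), function(k) {
    p <- preds[[format(ages[k], digits = 15)]]
    if (is.null(p)) return(NA_real_)
    id <- data$observable_id[k]
    if (id %in% names(p$values)) p$values[[id]] else p$totals[[id]]
  }, numeric(1))
}

.make_objective <- function(data, params, modulations, free) {
  cal <- data[data$role == "calibration", , drop = FALSE]
  function(logtheta) {
    pm <- list(params = params, modulations = modulations)
    th <- exp(logtheta)
    for (j in seq_along(free)) {
      pm <- .free_set(free[j], th[j], pm$params, pm$modulations)
    }
    pred <- tryCatch(.dataset_predictions(cal, pm$params, pm$modulations),
                     error = function(e) rep(NA_real_, nrow(cal)))
    if (anyNA(pred)) return(1e12)
    as.numeric(proportional_loglik(pred, cal))
  }
}

#' Multi-start maximum-likelihood fit
#'
#' Minimises the proportional-error negative log-likelihood over the listed
#' free parameters using Nelder-Mead on log-transformed values, from
#' `n_starts` starting points (the nominal values plus log-uniform draws
#' within the bounds). Deterministic given `seed`.
#'
#' @param data A `cd4_dataset`; only `role == "calibration"` rows enter the
#'   likelihood, each evaluated at its age-bin midpoint.
#' @param params Base kinetic parameters (their current values are the
#'   nominal start).
#' @param modulations Modulation set defining the model variant.
#' @param free Character vector of free-parameter paths (see Details in
#'   the package vignette); all must be positive.
#' @param n_starts Number of optimisation starts (default 15).
#' @param seed Integer seed for the start draws.
#' @param bounds Optional matrix with columns `lo`, `hi` and one row per
#'   free parameter; defaults to nominal value x \[0.01, 100\].
#' @param maxit Nelder-Mead iteration cap per start.
#' @param compute_rse Logical; attach RSE-based identifiability.
#' @return An object of class `cd4_fit`: estimates, NLL, AIC (`2k + 2 NLL`
#'   with `k = length(free)`), per-start diagnostics, RSE table, and the
#'   updated parameter/modulation objects.
#' @export
fit_multistart <- function(data, params = default_parameters(),
                           modulations = default_modulations("STATIC"),
                           free, n_starts = 15, seed = 1L, bounds = NULL,
                           maxit = 300, compute_rse = TRUE) {
  if (length(free) < 1) stop("no free parameters", call. = FALSE)
  params <- validate_parameters(params)
  if (is.null(bounds)) bounds <- .default_bounds(free, params, modulations)
  obj <- .make_objective(data, params, modulations, free)
  nominal <- vapply(free, function(p) {
    v <- .free_get(p, params, modulations)
    if (is.null(v) || !is.finite(v) || v <= 0) {
      sqrt(bounds[match(p, free), 1] * bounds[match(p, free), 2])
    } else v
  }, numeric(1))
  set.seed(seed)
  starts <- matrix(stats::runif((n_starts - 1) * length(free)),
                   ncol = length(free))
  starts <- sweep(sweep(starts, 2, log(bounds[, 2] / bounds[, 1]), "*"),
                  2, log(bounds[, 1]), "+")
  starts <- rbind(log(nominal), starts)
  runs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    runs[[s]] <- tryCatch(
      if (length(free) == 1L) {
        stats::optim(starts[s, ], obj, method = "Brent",
                     lower = log(bounds[1, 1]), upper = log(bounds[1, 2]),
                     control = list(maxit = maxit))
      } else {
        stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10))
      },
      error = function(e) list(value = Inf, par = starts[s, ],
                               convergence = 99, message = conditionMessage(e)))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) {
    stop("all optimisation starts failed", call. = FALSE)
  }
  best <- runs[[which.min(vals)]]
  ## Nelder-Mead can stall near the optimum: one restart from the best
  ## vertex polishes the solution
  if (length(free) > 1L) {
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  est <- setNames(exp(best$par), free)
  pm <- list(params = params, modulations = modulations)
  for (j in seq_along(free)) {
    pm <- .free_set(free[j], est[[j]], pm$params, pm$modulations)
  }
  nll <- best$value
  k <- length(free)
  rse <- NULL
  if (compute_rse) {
    nat_obj <- function(theta) obj(log(pmax(theta, 1e-300)))
    rse <- rse_estimate(nat_obj, est)
  }
  structure(list(estimate = est, free = free, nll = nll, k = k,
                 aic = aic(nll, k), rse = rse,
                 variant = modulations$variant,
                 convergence = best$convergence,
                 start_values = vals, seed = seed, bounds = bounds,
                 params = pm$params, modulations = pm$modulations),
            class = "cd4_fit")
}

#' @export
print.cd4_fit <- function(x, ...) {
  cat("CD4+ homeostasis fit (variant ", x$variant, "): NLL = ",
      signif(x$nll, 8), ", AIC = ", signif(x$aic, 8), ", k = ", x$k, "\n",
      sep = "")
  print(signif(x$estimate, 4))
  invisible(x)
}

#' Profile likelihood for one fitted parameter
#'
#' Re-optimises the remaining free parameters with the profiled one fixed
#' across a grid, and reports the 95% confidence set (NLL within
#' `qchisq(0.95, 1)/2 = 1.92` of the minimum). A profile whose range is
#' below 0.01 likelihood units is flagged practically non-identifiable.
#'
#' @param fit A `cd4_fit`.
#' @param data The dataset used for the fit.
#' @param parameter Path of the parameter to profile (must be in
#'   `fit$free`).
#' @param grid Numeric grid of values; defaults to 11 log-spaced points
#'   over estimate x \[1/4, 4\].
#' @param maxit Iteration cap for each re-optimisation.
#' @return data.frame (class `cd4_profile`) with columns `value`, `nll`,
#'   `in_ci`; attributes `ci` (range of the confidence set), `flat`
#'   (logical) and `nll_min`.
#' @export
profile_likelihood <- function(fit, data, parameter, grid = NULL,
                               maxit = 200) {
  if (!parameter %in% fit$free) {
    stop("parameter was not free in this fit", call. = FALSE)
  }
  est <- fit$estimate[[parameter]]
  if (is.null(grid)) {
    grid <- exp(seq(log(est / 4), log(est * 4), length.out = 11))
  }
  if (min(grid) > est || max(grid) < est) {
    warning("profile grid does not bracket the estimate")
  }
  others <- setdiff(fit$free, parameter)
  prof <- vapply(grid, function(val) {
    pm <- .free_set(parameter, val, fit$params, fit$modulations)
    if (!length(others)) {
      obj <- .make_objective(data, pm$params, pm$modulations, parameter)
      return(obj(log(val)))
    }
    obj <- .make_objective(data, pm$params, pm$modulations, others)
    start <- log(unlist(fit$estimate[others]))
    r <- tryCatch(stats::optim(start, obj, method = "Nelder-Mead",
                               control = list(maxit = maxit,
                                              reltol = 1e-10)),
                  error = function(e) list(value = NA_real_))
    r$value
  }, numeric(1))
  nll_min <- min(c(prof, fit$nll), na.rm = TRUE)
  in_ci <- !is.na(prof) & prof <= nll_min + stats::qchisq(0.95, 1) / 2
  out <- data.frame(value = grid, nll = prof, in_ci = in_ci)
  attr(out, "ci") <- range(grid[in_ci])
  attr(out, "flat") <- diff(range(prof, na.rm = TRUE)) < 0.01
  attr(out, "nll_min") <- nll_min
  class(out) <- c("cd4_profile", "data.frame")
  out
}

## Stepwise selection of age functions ---------------------------------------

.form_free <- function(target, form) {
  switch(form,
         hyperbolic = paste0("mod:", target, c(":max_change", ":age50")),
         linear = paste0("mod:", target, ":slope"),
         exponential = paste0("mod:", target, c(":max_change", ":tau")),
         quadratic = paste0("mod:", target, c(":s1", ":s2")))
}

.form_init <- function(form) {
  switch(form,
         hyperbolic = c(max_change = 0.5, age50 = 20),
         linear = c(slope = 0.01),
         exponential = c(max_change = 0.5, tau = 20),
         quadratic = c(s1 = 0.005, s2 = 1e-4))
}

.form_bounds <- function(form, direction) {
  up_cap <- if (direction == "down") 1 else 20
  switch(form,
         hyperbolic = rbind(max_change = c(1e-3, up_cap),
                            age50 = c(0.5, 120)),
         linear = rbind(slope = c(1e-5, 1)),
         exponential = rbind(max_change = c(1e-3, up_cap),
                             tau = c(0.5, 120)),
         quadratic = rbind(s1 = c(1e-6, 0.1), s2 = c(1e-8, 0.01)))
}

#' Stepwise forward/backward selection of empirical age functions
#'
#' With the kinetic rates fixed, candidate (parameter, direction) pairs are
#' screened with four functional forms of age dependency. Forward step: the
#' candidate/form whose fit gives the lowest AIC, with all newly estimated
#' parameters identifiable (RSE at or below 51%), is added if it lowers the
#' current AIC; repeated until no candidate improves. Backward step:
#' accepted functions are removed one at a time and dropped for good if
#' removal lowers AIC. Previously accepted functions keep their estimates
#' while a new candidate is evaluated (stagewise approximation); `k` counts
#' all age-function parameters estimated so far.
#'
#' @param data A `cd4_dataset`.
#' @param candidates data.frame with columns `target` (kinetic rate name)
#'   and `direction` (`"up"`/`"down"`).
#' @param forms Functional forms to screen.
#' @param params Fixed kinetic parameters.
#' @param n_starts,maxit,seed Passed to the per-candidate fits (desk-scale
#'   defaults; raise `n_starts` for production runs).
#' @param rse_threshold Identifiability cut-off (%).
#' @return A list of class `cd4_selection`: `modulations` (selected set,
#'   variant `"AGE"`), `audit` (data.frame of all evaluated steps with
#'   AICs), `aic` (final), `nll` (final), `k`.
#' @export
stepwise_selection <- function(data, candidates,
                               forms = c("hyperbolic", "linear",
                                         "exponential", "quadratic"),
                               params = default_parameters(),
                               n_starts = 3, maxit = 150, seed = 1L,
                               rse_threshold = 51) {
  stopifnot(all(c("target", "direction") %in% names(candidates)))
  base_mod <- default_modulations("STATIC")
  base_mod$variant <- "AGE"
  base_mod$entries <- list()

  cal <- data[data$role == "calibration", , drop = FALSE]
  null_pred <- .dataset_predictions(cal, params, base_mod)
  cur_nll <- as.numeric(proportional_loglik(null_pred, cal))
  cur_k <- 0
  cur_aic <- aic(cur_nll, 0)
  cur_mod <- base_mod
  audit <- list()
  accepted <- character(0)
  remaining <- seq_len(nrow(candidates))

  repeat {
    best <- NULL
    for (ci in remaining) {
      tgt <- candidates$target[ci]
      dir <- candidates$direction[ci]
      for (fm in forms) {
        mod_try <- cur_mod
        init <- .form_init(fm)
        entry <- .mod_entry(tgt, dir,
                            max_change = unname(init["max_change"]) %||% 0.5,
                            age50 = unname(init["age50"]) %||% 20,
                            form = fm,
                            slope = unname(init["slope"]) %||% NA_real_,
                            tau = unname(init["tau"]) %||% NA_real_,
                            s1 = unname(init["s1"]) %||% NA_real_,
                            s2 = unname(init["s2"]) %||% NA_real_)
        mod_try$entries[[tgt]] <- entry
        free <- .form_free(tgt, fm)
        bb <- .form_bounds(fm, dir)
        fit <- tryCatch(
          fit_multistart(data, params, mod_try, free, n_starts = n_starts,
                         seed = seed + ci, bounds = bb, maxit = maxit,
                         compute_rse = TRUE),
          error = function(e) NULL)
        if (is.null(fit)) next
        k_new <- cur_k + length(free)
        cand_aic <- aic(fit$nll, k_new)
        identifiable <- !is.null(fit$rse) && all(fit$rse$identifiable)
        audit[[length(audit) + 1L]] <-
          data.frame(step = "forward", target = tgt, form = fm,
                     direction = dir, nll = fit$nll, k = k_new,
                     aic = cand_aic, identifiable = identifiable,
                     accepted = FALSE)
        if (identifiable && cand_aic < cur_aic &&
            (is.null(best) || cand_aic < best$aic)) {
          best <- list(fit = fit, aic = cand_aic, k = k_new, ci = ci,
                       target = tgt, form = fm,
                       audit_idx = length(audit))
        }
      }
    }
    if (is.null(best)) break
    cur_mod <- best$fit$modulations
    cur_nll <- best$fit$nll
    cur_k <- best$k
    cur_aic <- best$aic
    accepted <- c(accepted, best$target)
    remaining <- setdiff(remaining, best$ci)
    audit[[best$audit_idx]]$accepted <- TRUE
    if (!length(remaining)) break
  }

  ## backward elimination: drop any accepted function whose removal lowers
  ## AIC with the remaining functions kept at their estimates
  for (tgt in accepted) {
    mod_try <- cur_mod
    entry <- mod_try$entries[[tgt]]
    mod_try$entries[[tgt]] <- NULL
    pred <- .dataset_predictions(cal, params, mod_try)
    nll_wo <- as.numeric(proportional_loglik(pred, cal))
    k_wo <- cur_k - length(.form_free(tgt, entry$form))
    aic_wo <- aic(nll_wo, k_wo)
    audit[[length(audit) + 1L]] <-
      data.frame(step = "backward", target = tgt, form = entry$form,
                 direction = entry$direction, nll = nll_wo, k = k_wo,
                 aic = aic_wo, identifiable = NA, accepted = aic_wo < cur_aic)
    if (aic_wo < cur_aic) {
      cur_mod <- mod_try
      cur_nll <- nll_wo
      cur_k <- k_wo
      cur_aic <- aic_wo
      accepted <- setdiff(accepted, tgt)
    }
  }
  structure(list(modulations = cur_mod, accepted = accepted,
                 audit = if (length(audit)) do.call(rbind, audit)
                         else data.frame(),
                 aic = cur_aic, nll = cur_nll, k = cur_k),
            class = "cd4_selection")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
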