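## Synthetic calibration data ------------------------------------------------
##
## The calibration data the model is built against are age-binned weighted
## averages of subpopulation concentrations with proportional (CV-scale)
## uncertainty, 20 observables in all. The generator emulates that
## structure: steady-state model predictions at bin midpoints, multiplied by
## lognormal noise with a prescribed CV, with confidence intervals built
## from the CV and a synthetic number of contributing studies.

#' Specification for a synthetic calibration dataset
#'
#' @param params Generating kinetic parameters.
#' @param modulations Generating modulation set (its variant is the
#'   data-generating truth).
#' @param cv Proportional coefficient of variation per observation
#'   (default 0.1).
#' @param n_synth Synthetic number of studies per bin (drives CI width).
#' @param noise If `FALSE`, means equal model predictions exactly.
#' @param bins_blood Matrix-like list of age bins (years) for blood
#'   concentrations.
#' @param bins_tissue Age bins for tissue percentages (sparser, as tissue
#'   data are).
#' @param seed Integer seed; a fixed seed makes the dataset reproducible.
#' @return A list of class `cd4_synth_spec`.
#' @export
synthetic_spec <- function(params = default_parameters(),
                           modulations = default_modulations(),
                           cv = 0.1, n_synth = 5, noise = TRUE,
                           bins_blood = list(c(0, 0.25), c(0.25, 1),
                                             c(1, 5), c(5, 18), c(18, 40),
                                             c(40, 60), c(60, 80)),
                           bins_tissue = list(c(0, 18), c(18, 60)),
                           seed = 1L) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  ok_bins <- function(b) all(vapply(b, function(x) x[1] <= x[2], TRUE))
  if (!ok_bins(bins_blood) || !ok_bins(bins_tissue)) {
    stop("age bins must satisfy lo <= hi", call. = FALSE)
  }
  structure(list(params = params, modulations = modulations, cv = cv,
                 n_synth = n_synth, noise = noise, bins_blood = bins_blood,
                 bins_tissue = bins_tissue, seed = as.integer(seed)),
            class = "cd4_synth_spec")
}

.obs_meta <- function(id) {
  parts <- strsplit(id, "_")[[1]]
  list(compartment = parts[1], subpop = parts[2], kind = parts[3])
}

#' Generate an age-binned synthetic calibration dataset
#'
#' For each observable and age bin the "observed" mean is the generating
#' model's steady-state prediction at the bin midpoint, multiplied by
#' multiplicative lognormal noise with the specified CV (mean-preserving).
#' The 95% CI half-width is `1.96 * cv * mean / sqrt(n_synth)`. The dataset
#' carries the 20 calibration observables plus total and memory blood
#' concentrations in a validation role.
#'
#' @param spec A `cd4_synth_spec` from [synthetic_spec()].
#' @return A data.frame of class `cd4_dataset` with columns
#'   `observable_id`, `compartment`, `subpopulation`, `age_lo`, `age_hi`,
#'   `mean`, `ci_lo`, `ci_hi`, `cv`, `role`.
#' @export
generate_calibration_dataset <- function(spec) {
  if (!inherits(spec, "cd4_synth_spec")) {
    stop("spec must be a cd4_synth_spec", call. = FALSE)
  }
  set.seed(spec$seed)
  ids <- observable_ids()
  rows <- list()
  for (id in ids) {
    meta <- .obs_meta(id)
    bins <- if (meta$compartment == "BL") spec$bins_blood else
      spec$bins_tissue
    for (b in bins) {
      rows[[length(rows) + 1L]] <-
        data.frame(observable_id = id, compartment = meta$compartment,
                   subpopulation = meta$subpop, age_lo = b[1], age_hi = b[2],
                   role = "calibration", stringsAsFactors = FALSE)
    }
  }
  for (id in c("BL_total_conc", "BL_memory_conc")) {
    for (b in spec$bins_blood) {
      rows[[length(rows) + 1L]] <-
        data.frame(observable_id = id, compartment = "BL",
                   subpopulation = if (id == "BL_total_conc") "TOTAL"
                                   else "MEMORY",
                   age_lo = b[1], age_hi = b[2], role = "validation",
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$age_mid <- ifelse(df$age_lo == df$age_hi, df$age_lo,
                       (df$age_lo + df$age_hi) / 2)
  ages <- sort(unique(df$age_mid))
  preds <- lapply(ages, function(a)
    predict_observables(a, spec$params, spec$modulations, cache = FALSE))
  names(preds) <- vapply(ages, function(a) format(a, digits = 15), "")
  pred <- vapply(seq_len(nrow(df)), function(k) {
    p <- preds[[format(df$age_mid[k], digits = 15)]]
    id <- df$observable_id[k]
    if (id %in% names(p$values)) p$values[[id]] else p$totals[[id]]
  }, numeric(1))
  noise_mult <- if (spec$noise && spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    exp(stats::rnorm(nrow(df), -sdlog^2 / 2, sdlog))
  } else rep(1, nrow(df))
  df$mean <- pred * noise_mult
  hw <- 1.96 * spec$cv * df$mean / sqrt(spec$n_synth)
  df$ci_lo <- df$mean - hw
  df$ci_hi <- df$mean + hw
  df$cv <- if (spec$cv > 0) spec$cv else 0.1
  df$age_mid <- NULL
  class(df) <- c("cd4_dataset", "data.frame")
  df
}

#' Age regressor for a dataset row (bin midpoint)
#' @param data A `cd4_dataset`.
#' @return Numeric vector of ages (bin midpoints; degenerate bins use their
#'   single age).
#' @export
dataset_ages <- function(data) {
  ifelse(data$age_lo == data$age_hi, data$age_lo,
         (data$age_lo + data$age_hi) / 2)
}

#' Write / read a calibration dataset as CSV
#' @param data A `cd4_dataset`.
#' @param path CSV path.
#' @return `path` (write) or the dataset (read).
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable_id", "compartment", "subpopulation", "age_lo",
            "age_hi", "mean", "ci_lo", "ci_hi", "cv", "role")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("malformed dataset file, missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("cd4_dataset", "data.frame")
  df
}

#' Generate a synthetic thymectomy cohort
#'
#' Subjects are grouped by age at surgery into the six conventional groups
#' (0-1 mo, 1-2 mo, 2 mo-1 y, 1-1.5 y, 1.5-3 y, over 3 y); each subject's
#' surgery age is drawn uniformly within the group, the post-surgery
#' trajectory is simulated with [simulate_thymectomy()] and total blood
#' CD4+ concentration observations receive multiplicative lognormal noise.
#'
#' @param n_subjects Total number of subjects.
#' @param group_mix Integer vector of length 6 summing to `n_subjects`.
#' @param spec A `cd4_synth_spec` (noise CV and generating model).
#' @param observation_ages Ages (years) at which concentrations are
#'   recorded (ages before surgery are dropped per subject).
#' @return data.frame with columns `subject`, `group`, `age_at_surgery`,
#'   `age`, `total_blood_conc`.
#' @export
generate_thymectomy_cohort <- function(n_subjects, group_mix, spec,
                                       observation_ages = c(0.5, 1, 2, 3,
                                                            5, 10, 20)) {
  if (length(group_mix) != 6 || sum(group_mix) != n_subjects) {
    stop("group_mix must have 6 entries summing to n_subjects",
         call. = FALSE)
  }
  if (n_subjects < 1) stop("empty cohort", call. = FALSE)
  set.seed(spec$seed + 1L)
  bounds <- thymectomy_group_bounds()
  out <- list()
  subj <- 0L
  for (g in seq_len(6)) {
    if (group_mix[g] == 0) next
    for (r in seq_len(group_mix[g])) {
      subj <- subj + 1L
      a0 <- stats::runif(1, bounds$lo[g], bounds$hi[g])
      obs_ages <- observation_ages[observation_ages > a0]
      sim <- simulate_thymectomy(a0, spec$params, spec$modulations,
                                 until_age = max(obs_ages),
                                 observation_ages = obs_ages)
      keep <- sim$observed$age %in% obs_ages
      sim$observed <- sim$observed[keep, , drop = FALSE]
      conc <- sim$observed$total_blood_conc
      if (spec$noise && spec$cv > 0) {
        sdlog <- sqrt(log(1 + spec$cv^2))
        conc <- conc * exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog))
      }
      out[[subj]] <- data.frame(subject = subj, group = g,
                                age_at_surgery = a0,
                                age = sim$observed$age,
                                total_blood_conc = conc)
    }
  }
  do.call(rbind, out)
}

#' Printed anchor values shipped with the package
#'
#' Loads the small plain-text fixture of literature anchor values used by
#' the validation arithmetic: newborn total and memory CD4+ blood
#' concentrations (meta-analytic weighted averages with 95% CIs) and
#' whole-body total T-cell counts per compartment with their CD4/CD8
#' ratios.
#'
#' @return A list with data.frames `newborn_totals` and `body_counts`.
#' @export
reference_anchors <- function() {
  dir <- system.file("extdata", package = "cd4kinetics")
  list(newborn_totals = utils::read.csv(file.path(dir, "newborn_totals.csv"),
                                        stringsAsFactors = FALSE),
       body_counts = utils::read.csv(file.path(dir, "body_counts.csv"),
                                     stringsAsFactors = FALSE))
}
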