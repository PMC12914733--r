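## Pipeline ------------------------------------------------------------------
##
## Ties the stages together: (1) kinetic fit on the newborn-anchored
## dataset; (2) stepwise selection of age functions; (3) feedback
## replacement fit; (4) evaluation (sensitivity analysis, thymectomy).
## Configuration is a YAML file; one master seed is expanded into per-stage
## seeds; all outputs are plain CSV/JSON in the run directory.

.default_config <- function() {
  list(seed = 1L,
       stages = list(fit = TRUE, select_age = FALSE, feedback = FALSE,
                     evaluate = FALSE),
       dataset = list(path = NULL, cv = 0.1, noise = TRUE),
       fit = list(free = c("omRTE4bl_lt", "phiN4", "omA4lt_bl"),
                  n_starts = 5, maxit = 150),
       select_age = list(targets = c("lamA4", "phiCM4"),
                         directions = c("up", "down"),
                         forms = c("hyperbolic", "linear"),
                         n_starts = 2, maxit = 100),
       gsa = list(n = 200, ages = c(0, 20, 80)),
       thymectomy = list(ages_at_surgery = c(0.04, 1.2, 4),
                         until_age = 10))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      .merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

#' Run the staged analysis pipeline
#'
#' Executes the enabled stages in order on a calibration dataset (read from
#' `dataset$path` or generated synthetically), writing `fit.json`,
#' `selection_audit.csv`, `prcc.csv`, `trajectories.csv` and a `run_log.txt`
#' recording seeds and package version into `out_dir`. Later stages require
#' the outputs of earlier ones: enabling `evaluate` without `fit` is an
#' error before any computation starts.
#'
#' @param config Path to a YAML configuration file or a configuration list;
#'   unspecified fields take desk-scale defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or a YAML file path",
                          call. = FALSE)
  known <- names(.default_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg <- .merge_config(.default_config(), cfg)
  st <- cfg$stages
  if ((isTRUE(st$evaluate) || isTRUE(st$feedback) ||
       isTRUE(st$select_age)) && !isTRUE(st$fit)) {
    stop("stage dependency violated: later stages require stage 'fit'",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage_seed <- function(k) (seed * 97L + k * 1009L) %% 2147483647L
  log_lines <- c(paste("cd4kinetics", as.character(utils::packageVersion("cd4kinetics"))),
                 paste("master seed:", seed),
                 paste("started:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  params <- default_parameters()
  results <- list()

  dataset <- if (!is.null(cfg$dataset$path)) {
    read_dataset(cfg$dataset$path)
  } else {
    generate_calibration_dataset(synthetic_spec(
      params = params, modulations = default_modulations("AGE_PLUS_FEEDBACK"),
      cv = cfg$dataset$cv, noise = isTRUE(cfg$dataset$noise),
      seed = stage_seed(0L)))
  }
  write_dataset(dataset, file.path(out_dir, "dataset.csv"))
  log_lines <- c(log_lines, paste("dataset rows:", nrow(dataset)))

  if (isTRUE(st$fit)) {
    ## stage 1 calibrates the kinetics on the youngest age bin of each
    ## observable, before age-related processes shape the data
    youngest <- do.call(rbind, lapply(split(dataset, dataset$observable_id),
                                      function(d) d[which.min(d$age_lo), ]))
    class(youngest) <- class(dataset)
    fit <- fit_multistart(youngest, params, default_modulations("STATIC"),
                          free = cfg$fit$free,
                          n_starts = cfg$fit$n_starts,
                          seed = stage_seed(1L), maxit = cfg$fit$maxit)
    results$fit <- fit
    write_fit(fit, file.path(out_dir, "fit.json"))
    log_lines <- c(log_lines,
                   paste("stage 1 fit: NLL", signif(fit$nll, 8),
                         "AIC", signif(fit$aic, 8)))
    params <- fit$params
  }
  if (isTRUE(st$select_age)) {
    sel <- stepwise_selection(
      dataset,
      candidates = data.frame(target = cfg$select_age$targets,
                              direction = cfg$select_age$directions,
                              stringsAsFactors = FALSE),
      forms = cfg$select_age$forms, params = params,
      n_starts = cfg$select_age$n_starts, maxit = cfg$select_age$maxit,
      seed = stage_seed(2L))
    results$selection <- sel
    utils::write.csv(sel$audit, file.path(out_dir, "selection_audit.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines, paste("stage 2 selection: accepted",
                                    paste(sel$accepted, collapse = ",")))
  }
  if (isTRUE(st$feedback)) {
    mod_fb <- default_modulations("AGE_PLUS_FEEDBACK")
    fit_fb <- fit_multistart(dataset, params, mod_fb,
                             free = c("fb:C50_lamN4", "fb:lamN4base"),
                             n_starts = cfg$fit$n_starts,
                             seed = stage_seed(3L), maxit = cfg$fit$maxit)
    results$feedback_fit <- fit_fb
    write_fit(fit_fb, file.path(out_dir, "fit_feedback.json"))
    log_lines <- c(log_lines, paste("stage 3 feedback fit: AIC",
                                    signif(fit_fb$aic, 8)))
  }
  if (isTRUE(st$evaluate)) {
    mod <- default_modulations("AGE_PLUS_FEEDBACK")
    gsa <- run_gsa(params, mod, ages = cfg$gsa$ages,
                   outputs = observable_ids()[c(1, 2, 4)],
                   n = cfg$gsa$n, seed = stage_seed(4L))
    utils::write.csv(gsa$prcc, file.path(out_dir, "prcc.csv"),
                     row.names = FALSE)
    results$gsa <- gsa
    tr <- lapply(cfg$thymectomy$ages_at_surgery, function(a) {
      sim <- simulate_thymectomy(a, params, mod,
                                 until_age = cfg$thymectomy$until_age)
      cbind(age_at_surgery = a, sim$observed)
    })
    traj <- do.call(rbind, tr)
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    results$thymectomy <- traj
    log_lines <- c(log_lines, "stage 4 evaluation complete")
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

#' Write / read a fit result as JSON
#'
#' Full-precision round trip of the estimate vector, likelihood, AIC and
#' identifiability table.
#'
#' @param fit A `cd4_fit`.
#' @param path JSON path.
#' @return `path` (write); a list with the fit fields (read).
#' @export
write_fit <- function(fit, path) {
  obj <- list(variant = fit$variant,
              free = fit$free,
              estimate = as.list(fit$estimate),
              nll = fit$nll, aic = fit$aic, k = fit$k,
              convergence = fit$convergence,
              rse = if (!is.null(fit$rse)) fit$rse else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("estimate", "nll", "aic")) {
    if (is.null(obj[[f]])) {
      stop("malformed fit file: missing '", f, "'", call. = FALSE)
    }
  }
  obj$estimate <- unlist(obj$estimate)
  obj
}
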