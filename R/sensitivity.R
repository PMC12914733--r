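## Global sensitivity analysis -----------------------------------------------
##
## Latin-hypercube sampling of parameters within +/-25% of nominal, model
## steady-state outputs at representative ages, and partial rank
## correlation coefficients (PRCC) as the sensitivity measure; |PRCC| >= 0.5
## is flagged significant. Monotonicity is screened before PRCC is
## interpreted.

#' Latin-hypercube sample within parameter bounds
#'
#' Stratified uniform design: per dimension exactly one sample falls in each
#' of `n` equal-probability strata. Reproducible given `seed`.
#'
#' @param bounds data.frame with columns `name`, `lo`, `hi`.
#' @param n Number of samples (`>= 2`).
#' @param seed Integer seed.
#' @return A list of class `cd4_lhs`: `samples` (n x p matrix, named
#'   columns), `bounds`, `n`, `seed`.
#' @export
lhs_sample <- function(bounds, n, seed = 1L) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (any(!is.finite(bounds$lo)) || any(!is.finite(bounds$hi)) ||
      any(bounds$lo >= bounds$hi)) {
    stop("degenerate bounds (need finite lo < hi)", call. = FALSE)
  }
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(bounds))
  x <- sweep(sweep(u, 2, bounds$hi - bounds$lo, "*"), 2, bounds$lo, "+")
  colnames(x) <- bounds$name
  structure(list(samples = x, bounds = bounds, n = n, seed = seed),
            class = "cd4_lhs")
}

.rank_resid <- function(z, R_others) {
  stats::lm.fit(cbind(1, R_others), z)$residuals
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the design and output, then, for each parameter,
#' correlates the residuals of the parameter and of the output after linear
#' regression on the ranks of all other parameters. Rows with non-finite
#' output are dropped (at most 10% may fail); a constant output yields
#' PRCC 0 with a degenerate flag.
#'
#' @param design A `cd4_lhs` object or numeric matrix with named columns.
#' @param outputs Numeric vector of per-sample scalar outputs.
#' @return data.frame with columns `parameter`, `prcc`, `significant`
#'   (|PRCC| >= 0.5); attributes `n_effective` and `degenerate`.
#' @export
prcc <- function(design, outputs) {
  X <- if (inherits(design, "cd4_lhs")) design$samples else design
  if (nrow(X) != length(outputs)) {
    stop("one output per design row is required", call. = FALSE)
  }
  ok <- is.finite(outputs)
  if (mean(ok) < 0.9) {
    stop("more than 10% of the runs failed; aborting PRCC", call. = FALSE)
  }
  X <- X[ok, , drop = FALSE]
  y <- outputs[ok]
  p <- ncol(X)
  if (nrow(X) <= p + 2) {
    warning("PRCC needs more samples than parameters (n = ", nrow(X),
            ", p = ", p, "); coefficients are unreliable")
  }
  out <- data.frame(parameter = colnames(X), prcc = 0,
                    significant = FALSE, stringsAsFactors = FALSE)
  degenerate <- FALSE
  if (length(unique(y)) < 2) {
    degenerate <- TRUE
  } else {
    R <- apply(X, 2, rank, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    for (j in seq_len(p)) {
      ex <- .rank_resid(R[, j], R[, -j, drop = FALSE])
      ey <- .rank_resid(ry, R[, -j, drop = FALSE])
      r <- suppressWarnings(stats::cor(ex, ey))
      out$prcc[j] <- if (is.finite(r)) r else 0
    }
    out$significant <- abs(out$prcc) >= 0.5
  }
  attr(out, "n_effective") <- sum(ok)
  attr(out, "degenerate") <- degenerate
  out
}

#' Monotonicity screen before PRCC interpretation
#'
#' Per parameter: Spearman rank correlation with the output and a
#' binned-mean check (the sequence of output means across parameter bins
#' should be monotone up to a tolerance on direction changes).
#'
#' @inheritParams prcc
#' @param n_bins Number of equal-count bins for the binned-mean check.
#' @return data.frame with columns `parameter`, `spearman`, `monotone`.
#' @export
monotonicity_screen <- function(design, outputs, n_bins = 10) {
  X <- if (inherits(design, "cd4_lhs")) design$samples else design
  ok <- is.finite(outputs)
  X <- X[ok, , drop = FALSE]
  y <- outputs[ok]
  res <- lapply(colnames(X), function(nm) {
    x <- X[, nm]
    rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    if (!is.finite(rho)) rho <- 0
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(x, unique(qs), include.lowest = TRUE)
    bm <- tapply(y, bin, mean)
    bm <- bm[is.finite(bm)]
    dirs <- sign(diff(bm))
    dirs <- dirs[dirs != 0]
    frac_consistent <- if (length(dirs)) max(mean(dirs > 0), mean(dirs < 0))
                       else 1
    data.frame(parameter = nm, spearman = rho,
               monotone = frac_consistent >= 0.8 || abs(rho) < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## Parameter inventory for the GSA -------------------------------------------

#' Parameters entering the global sensitivity analysis
#'
#' The exported inventory: all kinetic rates of the thymocyte and
#' peripheral submodels plus the free constants of the age and feedback
#' functions of the supplied modulation set.
#'
#' @param params Kinetic parameters.
#' @param modulations Modulation set.
#' @param span Relative half-width of the sampling range (default 0.25).
#' @return data.frame with columns `name`, `lo`, `hi`, `nominal`.
#' @export
gsa_parameter_bounds <- function(params = default_parameters(),
                                 modulations = default_modulations(),
                                 span = 0.25) {
  v <- as_parameters(params)$values
  keep <- names(v)[v > 0]
  rows <- data.frame(name = keep, nominal = unname(v[keep]),
                     stringsAsFactors = FALSE)
  if (modulations$variant != "STATIC") {
    entries <- modulations$entries
    if (modulations$variant == "AGE_PLUS_FEEDBACK") {
      entries <- entries[setdiff(names(entries), c("lamN4", "muRTE4"))]
      fb <- modulations$feedback
      rows <- rbind(rows, data.frame(
        name = paste0("fb:", c("lamN4base", "lamN4_fmax", "muRTE4base",
                               "muRTE4_fmax", "C50_lamN4", "C50_muRTE4")),
        nominal = c(fb$lamN4base, fb$lamN4_fmax, fb$muRTE4base,
                    fb$muRTE4_fmax, fb$C50_lamN4, fb$C50_muRTE4),
        stringsAsFactors = FALSE))
    }
    for (e in entries) {
      rows <- rbind(rows, data.frame(
        name = paste0("mod:", e$target, c(":max_change", ":age50")),
        nominal = c(e$max_change, e$age50), stringsAsFactors = FALSE))
    }
  }
  rows$lo <- rows$nominal * (1 - span)
  rows$hi <- rows$nominal * (1 + span)
  ## fractions stay within [0, 1]
  down_targets <- names(Filter(function(e) e$direction == "down",
                               modulations$entries))
  frac <- rows$name %in% c("f4", "alphaSP4", "fb:lamN4_fmax",
                           paste0("mod:", down_targets, ":max_change"))
  rows$hi[frac] <- pmin(rows$hi[frac], 1)
  rows[, c("name", "lo", "hi", "nominal")]
}

.apply_gsa_sample <- function(row_values, names, params, modulations) {
  for (j in seq_along(names)) {
    nm <- names[j]
    if (grepl("^(mod|fb):", nm)) {
      pm <- .free_set(nm, row_values[j], params, modulations)
      params <- pm$params; modulations <- pm$modulations
    } else {
      params$values[[nm]] <- row_values[j]
    }
  }
  list(params = params, modulations = modulations)
}

#' Latin-hypercube / PRCC global sensitivity analysis
#'
#' Samples the parameter inventory within +/-`span` of nominal, simulates
#' each sampled model over the life course (from its newborn steady state
#' to the oldest requested age), reads all observables at the requested
#' ages, and computes PRCC of every parameter against every observable.
#' Outputs are taken from the simulated trajectory rather than frozen-age
#' fixed points because the aged system is only marginally stable at the
#' calibrated rates: under wide parameter perturbation many draws have no
#' old-age fixed point at all, while their life-course trajectories remain
#' perfectly well defined. A convergence report compares PRCC at `n` and
#' `n/2` samples for the strongest parameters.
#'
#' @param params,modulations Calibrated model.
#' @param ages Ages (years) at which outputs are evaluated.
#' @param outputs Observable ids (default all 20).
#' @param n Number of LHS samples (desk-scale default 2000; the
#'   full-scale analysis uses 10000).
#' @param seed Integer seed.
#' @param span Relative sampling half-width.
#' @return A list of class `cd4_gsa`: `prcc` (data.frame `parameter`,
#'   `output`, `age`, `prcc`, `significant`, `monotone`), `design`,
#'   `failed_fraction`, `convergence` (max |drift| between n and n/2 for
#'   the five largest-|PRCC| parameters per output/age), `parameters`.
#' @export
run_gsa <- function(params = default_parameters(),
                    modulations = default_modulations(),
                    ages = c(0, 1, 20, 50, 80),
                    outputs = observable_ids(), n = 2000, seed = 1L,
                    span = 0.25) {
  bounds <- gsa_parameter_bounds(params, modulations, span)
  des <- lhs_sample(bounds[, c("name", "lo", "hi")], n, seed)
  X <- des$samples
  fail <- 0L
  ages <- sort(ages)
  t_out <- unique(c(0, ages * 365.25))
  ## per-sample life-course simulation; observables read at the requested
  ## ages (one array n x outputs per age)
  Ys <- lapply(ages, function(a)
    matrix(NA_real_, n, length(outputs), dimnames = list(NULL, outputs)))
  names(Ys) <- format(ages)
  for (s in seq_len(n)) {
    pm <- .apply_gsa_sample(X[s, ], colnames(X), params, modulations)
    obs_by_age <- tryCatch({
      init <- solve_steady_state(pm$params, pm$modulations, age_fixed = 0)
      tr <- simulate_trajectory(init, pm$params, pm$modulations,
                                t_grid = t_out, age0 = 0, rtol = 1e-6)
      lapply(ages, function(a) {
        k <- which.min(abs(tr$age_years - a))
        st <- as.numeric(tr[k, names(.IDX)])
        bv <- blood_volume(a, pm$modulations$physiology)
        observables_from_state(st, bv)
      })
    }, error = function(e) NULL)
    if (is.null(obs_by_age)) { fail <- fail + 1L; next }
    for (ai in seq_along(ages)) {
      Ys[[ai]][s, ] <- obs_by_age[[ai]]$values[outputs]
    }
  }
  if (fail / n > 0.1) {
    stop("more than 10% of simulations failed (", fail, " of ", n, ")",
         call. = FALSE)
  }
  res <- vector("list", length(ages))
  for (ai in seq_along(ages)) {
    age <- ages[ai]
    Y <- Ys[[ai]]
    tabs <- lapply(outputs, function(o) {
      pr <- prcc(X, Y[, o])
      mono <- monotonicity_screen(X, Y[, o])
      top <- order(abs(pr$prcc), decreasing = TRUE)[seq_len(min(5,
                                                                nrow(pr)))]
      drift <- if (floor(n / 2) > ncol(X) + 2) {
        half <- prcc(X[seq_len(floor(n / 2)), , drop = FALSE],
                     Y[seq_len(floor(n / 2)), o])
        max(abs(pr$prcc[top] - half$prcc[top]))
      } else NA_real_
      cbind(pr, output = o, age = age, monotone = mono$monotone,
            drift_top5 = drift)
    })
    res[[ai]] <- do.call(rbind, tabs)
  }
  tab <- do.call(rbind, res)
  conv <- unique(tab[, c("output", "age", "drift_top5")])
  rownames(conv) <- NULL
  structure(list(prcc = tab, design = des,
                 failed_fraction = fail / n,
                 convergence = conv,
                 parameters = bounds),
            class = "cd4_gsa")
}

#' Two-parameter iso-output response surface
#'
#' Steady-state output on a 2-D grid over +/-`span` of the nominal values
#' of a parameter pair, all other parameters held at nominal; used to
#' visualise compensatory (diagonal iso-line) parameter interactions.
#'
#' @param pair Character vector of two distinct parameter names.
#' @param params,modulations Calibrated model.
#' @param grid_size Grid points per axis.
#' @param age Age (years).
#' @param output Observable id or `"total_LT"`-style total.
#' @param span Relative half-width.
#' @return data.frame (class `cd4_contour`) with columns `p1`, `p2`,
#'   `value`; attributes `pair`, `age`, `output`.
#' @export
contour_grid <- function(pair, params = default_parameters(),
                         modulations = default_modulations(),
                         grid_size = 11, age = 20,
                         output = "total_LT", span = 0.25) {
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("pair must name two distinct parameters", call. = FALSE)
  }
  v <- as_parameters(params)$values
  g1 <- seq(v[[pair[1]]] * (1 - span), v[[pair[1]]] * (1 + span),
            length.out = grid_size)
  g2 <- seq(v[[pair[2]]] * (1 - span), v[[pair[2]]] * (1 + span),
            length.out = grid_size)
  grid <- expand.grid(p1 = g1, p2 = g2)
  grid$value <- vapply(seq_len(nrow(grid)), function(k) {
    p <- params
    p$values[[pair[1]]] <- grid$p1[k]
    p$values[[pair[2]]] <- grid$p2[k]
    obs <- tryCatch({
      ss <- solve_steady_state(p, modulations, age_fixed = age)
      ob <- observables_from_state(ss, attr(ss, "effective")$BV)
      if (output %in% names(ob$values)) ob$values[[output]]
      else ob$totals[[output]]
    }, error = function(e) NA_real_)
    obs
  }, numeric(1))
  attr(grid, "pair") <- pair
  attr(grid, "age") <- age
  attr(grid, "output") <- output
  class(grid) <- c("cd4_contour", "data.frame")
  grid
}
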