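## Kinetic parameter set -----------------------------------------------------
##
## Peripheral rates are the published calibration values for the newborn
## (age-0) homeostatic model; each carries an `estimated` flag distinguishing
## rates estimated from the age-binned concentration data from rates fixed on
## physiological ranges. Thymocyte-submodel constants are a reconstruction
## (flagged "reconstructed"): DN cells proliferate under a cortical carrying
## capacity, differentiate to DP; DP proliferate under the same capacity and
## are routed at selection to SP4/SP8 under a medullary capacity; SP4 cells
## egress into blood as recent thymic emigrants.

.PERIPHERAL_DEFAULTS <- c(
  muRTE4      = 0.0076,   # death rate of RTE cells, 1/d
  omRTE4bl_lt = 0.217,    # RTE blood -> lymphoid tissue, 1/d
  phiRTE4     = 0.0012,   # RTE -> naive differentiation (in LT), 1/d
  muN4        = 0.000457, # naive death rate, 1/d
  lamN4       = 0.0007,   # naive homeostatic proliferation, 1/d
  phiN4       = 0.0012,   # naive -> activated differentiation (in LT), 1/d
  omN4lt_bl   = 1.64,     # naive LT -> blood, 1/d
  omN4bl_lt   = 40,       # naive blood -> LT, 1/d
  omN4bl_git  = 0.0003,   # naive blood -> gut, 1/d
  omN4bl_lung = 0.0003,   # naive blood -> lung, 1/d
  omN4bl_tis  = 0.0003,   # naive blood -> unmodelled tissues (loss), 1/d
  omA4bl_tis  = 0.0003,   # activated blood -> unmodelled tissues (loss), 1/d
  omN4git_bl  = 0.00075,  # naive gut -> blood, 1/d
  omN4lung_bl = 0.00075,  # naive lung -> blood, 1/d
  lamA4       = 1.725,    # activated (clonal-expansion) proliferation, 1/d
  phiA4       = 1.727,    # activated -> memory/effector differentiation, 1/d
  muA4        = 0.04,     # activated death rate, 1/d
  omA4lt_bl   = 4.06,     # activated LT -> blood, 1/d
  omA4bl_lt   = 40,       # activated blood -> LT, 1/d
  f4          = 0.4,      # fraction of differentiating activated cells -> CM
  TA4max      = 1e13,     # whole-body carrying capacity of activated cells
  lamCM4      = 0.0391,   # central-memory proliferation, 1/d
  muCM4       = 0.041,    # central-memory death rate, 1/d
  phiCM4      = 0.111,    # CM -> EM differentiation, 1/d
  omCM4lt_bl  = 0.334,    # CM LT -> blood, 1/d
  omCM4bl_lt  = 10,       # CM blood -> LT, 1/d
  omCM4bl_git = 0.12,     # CM blood -> gut, 1/d
  omCM4bl_lung= 0.12,     # CM blood -> lung, 1/d
  omCM4bl_tis = 0.12,     # CM blood -> unmodelled tissues (loss), 1/d
  omCM4git_bl = 0.09,     # CM gut -> blood, 1/d
  omCM4lung_bl= 0.09,     # CM lung -> blood, 1/d
  lamEM4      = 0.042,    # effector-memory proliferation, 1/d
  muEM4       = 0.11,     # effector-memory death rate, 1/d
  phiEM4      = 0.035,    # EM -> effector differentiation, 1/d
  omEM4lt_bl  = 0.035,    # EM LT -> blood (no return to LT), 1/d
  omEM4bl_git = 0.882,    # EM blood -> gut, 1/d
  omEM4bl_lung= 0.882,    # EM blood -> lung, 1/d
  omEM4bl_tis = 0.882,    # EM blood -> unmodelled tissues (loss), 1/d
  omEM4git_bl = 0.04,     # EM gut -> blood, 1/d
  omEM4lung_bl= 0.04,     # EM lung -> blood, 1/d
  muEFF4      = 0.87,     # effector death rate, 1/d
  omEFF4lt_bl = 0.253,    # effector LT -> blood, 1/d
  omEFF4bl_git= 0.087,    # effector blood -> gut (no return), 1/d
  omEFF4bl_lung = 0.087,  # effector blood -> lung (no return), 1/d
  omEFF4bl_tis  = 0.087   # effector blood -> unmodelled tissues (loss), 1/d
)

.PERIPHERAL_ESTIMATED <- c(
  "omRTE4bl_lt", "phiN4", "omN4lt_bl", "omN4git_bl", "omN4lung_bl",
  "phiA4", "omA4lt_bl", "omCM4lt_bl", "omCM4git_bl", "omCM4lung_bl",
  "phiEM4", "omEM4bl_git", "omEM4bl_lung", "omEM4bl_tis",
  "muEFF4", "omEFF4lt_bl", "omEFF4bl_git", "omEFF4bl_lung", "omEFF4bl_tis"
)

.THYMUS_DEFAULTS <- c(
  pDN      = 0.9,     # DN proliferation under cortical capacity, 1/d
  dltDN    = 0.3,     # DN -> DP differentiation, 1/d
  muDN     = 0.05,    # DN death, 1/d
  pDP      = 0.5,     # DP proliferation under cortical capacity, 1/d
  dltDP    = 0.05,    # DP -> SP selection/differentiation, 1/d
  muDP     = 0.25,    # DP death (failed selection), 1/d
  pSP      = 1.0,     # SP proliferation under medullary capacity, 1/d
  muSP     = 0.05,    # SP death, 1/d
  sigmaSP4 = 0.25,    # SP egress to periphery, 1/d (SP8 egress leaves model)
  alphaSP4 = 0.75    # fraction of selected DP routed to the SP4 lineage
)

#' Default kinetic parameter set
#'
#' Returns the full kinetic parameter set of the homeostasis model: the 45
#' peripheral CD4+ rate constants (newborn calibration values) plus the ten
#' reconstructed thymocyte-submodel constants. Units are 1/day except `f4`
#' and `alphaSP4` (dimensionless fractions) and `TA4max` (cells).
#'
#' @return A named list of class `cd4_parameters` with elements `values`
#'   (named numeric vector) and `estimated` (named logical vector marking
#'   which peripheral rates were estimated rather than fixed).
#' @examples
#' p <- default_parameters()
#' p$values[["muEFF4"]]
#' @export
default_parameters <- function() {
  values <- c(.PERIPHERAL_DEFAULTS, .THYMUS_DEFAULTS)
  estimated <- setNames(names(values) %in% .PERIPHERAL_ESTIMATED, names(values))
  structure(list(values = values, estimated = estimated),
            class = "cd4_parameters")
}

#' Validate a kinetic parameter set
#'
#' Checks completeness, non-negativity of all rates, `f4` and `alphaSP4`
#' within \[0, 1\] and `TA4max > 0`.
#'
#' @param params A `cd4_parameters` object or named numeric vector.
#' @return The validated `cd4_parameters` object, invisibly usable downstream.
#' @export
validate_parameters <- function(params) {
  params <- as_parameters(params)
  v <- params$values
  need <- names(c(.PERIPHERAL_DEFAULTS, .THYMUS_DEFAULTS))
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(v))) stop("non-finite parameter value", call. = FALSE)
  if (any(v < 0)) {
    stop("negative rate(s): ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  }
  for (fr in c("f4", "alphaSP4")) {
    if (v[[fr]] > 1) stop(fr, " must lie in [0, 1]", call. = FALSE)
  }
  if (v[["TA4max"]] <= 0) stop("TA4max must be positive", call. = FALSE)
  params
}

#' Coerce to a `cd4_parameters` object
#' @param x Named numeric vector or `cd4_parameters`.
#' @return A `cd4_parameters` object.
#' @export
as_parameters <- function(x) {
  if (inherits(x, "cd4_parameters")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    base <- default_parameters()
    bad <- setdiff(names(x), names(base$values))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    base$values[names(x)] <- x
    return(base)
  }
  stop("cannot interpret `x` as a parameter set", call. = FALSE)
}

#' Update selected parameter values
#' @param params A `cd4_parameters` object.
#' @param ... Named scalar replacements, e.g. `lamA4 = 2`.
#' @return Updated `cd4_parameters` object.
#' @export
set_parameters <- function(params, ...) {
  repl <- unlist(list(...))
  params <- as_parameters(params)
  bad <- setdiff(names(repl), names(params$values))
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  params$values[names(repl)] <- repl
  params
}

#' @export
print.cd4_parameters <- function(x, ...) {
  cat("CD4+ homeostasis kinetic parameter set:",
      length(x$values), "parameters (",
      sum(x$estimated), "estimated )\n")
  invisible(x)
}

#' Write a parameter set (with optional modulations) to JSON
#'
#' @param params `cd4_parameters` object.
#' @param path Output file path.
#' @param modulations Optional `cd4_modulations` object serialised under a
#'   `"modulations"` field.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, modulations = NULL) {
  params <- validate_parameters(params)
  obj <- list(values = as.list(params$values),
              estimated = as.list(params$estimated))
  if (!is.null(modulations)) obj$modulations <- .serialize_modulations(modulations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set written by [write_parameters()]
#'
#' @param path JSON file path.
#' @return A list with elements `params` (`cd4_parameters`) and `modulations`
#'   (`cd4_modulations` or `NULL`).
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$values)) stop("malformed parameter file: missing 'values'",
                                call. = FALSE)
  vals <- unlist(obj$values)
  params <- validate_parameters(as_parameters(vals))
  if (!is.null(obj$estimated)) {
    params$estimated[names(obj$estimated)] <- unlist(obj$estimated)
  }
  mods <- if (!is.null(obj$modulations)) .deserialize_modulations(obj$modulations)
  list(params = params, modulations = mods)
}
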