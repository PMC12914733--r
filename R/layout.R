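#' @keywords internal
"_PACKAGE"

## Subpopulation and compartment vocabularies. The thymocyte stages (DN, DP,
## SP4, SP8) live only in the thymus; SP4 cells egress into the blood as
## recent thymic emigrants (RTE). Peripheral subsets: RTE, naive (N),
## activated (A), central-memory (CM), effector-memory (EM), effector (EFF).
.SUBPOPS <- c("DN", "DP", "SP4", "SP8", "RTE", "N", "A", "CM", "EM", "EFF")
.COMPARTMENTS <- c("THY", "BL", "LT", "GIT", "LUNG")

#' Compartment layout of the 24-state homeostasis model
#'
#' Defines the ordered list of model states, each a (subpopulation,
#' compartment) pair: four thymocyte stages in the thymus, recent thymic
#' emigrants and activated cells in blood and lymphoid tissue, and naive,
#' central-memory, effector-memory and effector cells in blood, lymphoid
#' tissue, gastro-intestinal tract and lungs.
#'
#' @return A data.frame with columns `label`, `subpop`, `compartment` and
#'   `index`; the row order defines the state-vector order used everywhere
#'   in the package.
#' @examples
#' lay <- compartment_layout()
#' nrow(lay)  # 24
#' @export
compartment_layout <- function() {
  def <- list(
    DN   = "THY", DP = "THY", SP4 = "THY", SP8 = "THY",
    RTE  = c("BL", "LT"),
    N    = c("BL", "LT", "GIT", "LUNG"),
    A    = c("BL", "LT"),
    CM   = c("BL", "LT", "GIT", "LUNG"),
    EM   = c("BL", "LT", "GIT", "LUNG"),
    EFF  = c("BL", "LT", "GIT", "LUNG")
  )
  subpop <- rep(names(def), lengths(def))
  compartment <- unlist(def, use.names = FALSE)
  lab <- paste(subpop, compartment, sep = "_")
  data.frame(label = lab, subpop = subpop, compartment = compartment,
             index = seq_along(lab), stringsAsFactors = FALSE)
}

.LAYOUT <- NULL  # filled at load time

.layout <- function() {
  if (is.null(.LAYOUT)) compartment_layout() else .LAYOUT
}

#' Index of a state in the model state vector
#'
#' @param subpop Subpopulation code (e.g. `"N"`, `"CM"`).
#' @param compartment Compartment code (e.g. `"BL"`, `"LT"`).
#' @return Integer position in the 24-long state vector.
#' @export
state_index <- function(subpop, compartment) {
  lay <- .layout()
  i <- match(paste(subpop, compartment, sep = "_"), lay$label)
  if (anyNA(i)) {
    stop("unknown state: ", paste(subpop, compartment, sep = "_"),
         call. = FALSE)
  }
  i
}

#' State labels in canonical order
#' @return Character vector of 24 labels such as `"RTE_BL"`.
#' @export
state_labels <- function() .layout()$label

#' Construct a named state vector
#'
#' @param counts Numeric vector of cell counts, either length 24 in layout
#'   order or named by state labels (missing states are 0).
#' @param age Age in years attached as an attribute (default 0).
#' @return Named numeric vector of length 24 with an `age` attribute.
#' @export
state_vector <- function(counts = 0, age = 0) {
  lab <- state_labels()
  x <- setNames(numeric(length(lab)), lab)
  if (!is.null(names(counts))) {
    bad <- setdiff(names(counts), lab)
    if (length(bad)) stop("unknown state label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x[names(counts)] <- counts
  } else if (length(counts) %in% c(1L, length(lab))) {
    x[] <- counts
  } else {
    stop("`counts` must be length 1, length 24, or named", call. = FALSE)
  }
  if (any(x < 0)) stop("cell counts must be non-negative", call. = FALSE)
  attr(x, "age") <- age
  x
}

.onLoad <- function(libname, pkgname) {
  ns <- topenv()
  assign(".LAYOUT", compartment_layout(), envir = ns)
  invisible()
}
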