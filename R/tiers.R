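#' Five-tier pathogenicity classes
#'
#' Variant classifications throughout the package use the standard 5-tier
#' scheme: 1 = benign (BV), 2 = likely benign (LBV), 3 = variant of unknown
#' significance (VUS), 4 = likely pathogenic (LPV), 5 = pathogenic (PV).
#' Increasing integer value reflects increasing pathogenicity.
#'
#' @format Named integer vector of length 5.
#' @export
TIER_LEVELS <- c(BV = 1L, LBV = 2L, VUS = 3L, LPV = 4L, PV = 5L)

#' Convert a class code or label to a tier integer
#'
#' @param x integer 1-5, or a label among "BV","LBV","VUS","LPV","PV".
#' @return integer vector with values in 1..5.
#' @examples
#' as_tier("LPV")  # 4
#' as_tier(1:5)
#' @export
as_tier <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x) | x < 1L | x > 5L)) {
      stop("tier values must be integers in 1..5", call. = FALSE)
    }
    return(x)
  }
  if (is.character(x)) {
    out <- TIER_LEVELS[toupper(trimws(x))]
    if (any(is.na(out))) {
      stop("unknown tier label(s): ",
           paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
    }
    return(unname(out))
  }
  stop("cannot interpret tier of class ", class(x)[1], call. = FALSE)
}

#' Label for a tier integer
#'
#' @param x integer vector with values in 1..5.
#' @return character vector among "BV","LBV","VUS","LPV","PV".
#' @export
tier_label <- function(x) {
  x <- as_tier(x)
  names(TIER_LEVELS)[x]
}
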