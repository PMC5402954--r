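#' Snellen to logMAR acuity conversion
#'
#' Converts a Snellen fraction to the logarithm of the minimum angle of
#' resolution: `logMAR = log10(denominator / numerator)`, so 20/20 is 0.0
#' and 20/200 is 1.0. Low-vision categories that have no Snellen fraction
#' (counting fingers, hand motion) map through a configurable table.
#'
#' @param numerator,denominator Snellen fraction components (e.g. 20 and 86
#'   for 20/86); vectors are accepted.
#' @param category optional character vector of low-vision categories; when
#'   supplied, the fraction arguments are ignored for those entries.
#' @param category_map named numeric vector of logMAR values for
#'   categories; the defaults assign counting fingers 2.0 and hand motion
#'   3.0.
#' @return Numeric logMAR value(s).
#' @examples
#' snellen_to_logmar(20, 200)      # 1.0
#' snellen_to_logmar(20, 86)       # ~0.63
#' snellen_to_logmar(category = "CF")
#' @export
snellen_to_logmar <- function(numerator = NULL, denominator = NULL,
                              category = NULL,
                              category_map = c(CF = 2.0, HM = 3.0)) {
  if (!is.null(category)) {
    unknown <- setdiff(category, names(category_map))
    if (length(unknown))
      stop("unknown acuity category: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    return(unname(category_map[category]))
  }
  if (is.null(numerator) || is.null(denominator))
    stop("supply a Snellen fraction or a category", call. = FALSE)
  if (any(numerator <= 0) || any(denominator <= 0))
    stop("Snellen fraction components must be positive", call. = FALSE)
  log10(denominator / numerator)
}

#' @rdname snellen_to_logmar
#' @param logmar logMAR value(s) to convert back to a 20-ft Snellen string.
#' @export
logmar_to_snellen <- function(logmar) {
  sprintf("20/%d", round(20 * 10^logmar))
}
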