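#' Point-biserial correlation
#'
#' Correlation between a dichotomous label and a continuous variable,
#' computed as `(mean1 - mean0) / s_n * sqrt(p * q)` with `s_n` the
#' population (divide-by-n) standard deviation of the pooled values and
#' `p`, `q` the label proportions. This equals the Pearson correlation of
#' the values with 0/1-coded labels.
#'
#' @param group vector with exactly two distinct values (logical, factor or
#'   character); the higher level is coded 1.
#' @param values numeric vector of the same length.
#' @return List of class `correlation_result` with `r_pb` and `n`.
#' @examples
#' point_biserial(rep(c(0, 1), each = 5), c(rnorm(5), rnorm(5, 2)))
#' @export
point_biserial <- function(group, values) {
  if (length(group) != length(values))
    stop("group and values lengths differ", call. = FALSE)
  ok <- !is.na(group) & !is.na(values)
  group <- group[ok]; values <- values[ok]
  if (length(values) < 3) stop("need at least 3 observations", call. = FALSE)
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2)
    stop("group must contain exactly two distinct labels", call. = FALSE)
  g <- as.numeric(as.character(group) == lev[2])
  n <- length(values)
  p <- mean(g); q <- 1 - p
  s_n <- sqrt(sum((values - mean(values))^2) / n)
  if (s_n == 0) stop("values are constant; correlation undefined", call. = FALSE)
  r <- (mean(values[g == 1]) - mean(values[g == 0])) / s_n * sqrt(p * q)
  structure(list(r_pb = r, n = n, levels = lev), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<point-biserial> r_pb = %.4f (n = %d; %s -> 0, %s -> 1)\n",
              x$r_pb, x$n, x$levels[1], x$levels[2]))
  invisible(x)
}
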