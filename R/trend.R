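#' Jonckheere-Terpstra ordered trend test
#'
#' Tests for a monotone trend of a continuous outcome across k >= 3 ordered
#' groups (e.g. control -> branch occlusion -> central occlusion). The
#' statistic is the sum over ordered group pairs (i < j) of Mann-Whitney
#' counts `#\{x in group i, y in group j : y > x\} + 0.5 * #ties`. The
#' asymptotic null uses the tie-corrected normal approximation; an optional
#' seeded Monte-Carlo permutation p-value is computed by shuffling group
#' labels.
#'
#' @param groups list of numeric vectors in increasing hypothesized order.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param n_permutations number of label permutations for the Monte-Carlo
#'   p-value (0 = skip).
#' @param seed integer seed for the permutations.
#' @return List of class `trend_test_result` with `j_statistic`,
#'   `expected_j`, `variance_j`, `z_score`, `p_asymptotic`,
#'   `p_permutation` (NA when not requested), `alternative`, `group_sizes`.
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))$j_statistic  # 12
#' @export
jonckheere_terpstra <- function(groups, alternative = c("two.sided",
                                                        "increasing",
                                                        "decreasing"),
                                n_permutations = 0, seed = 1L) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 3)
    stop("need at least 3 ordered groups", call. = FALSE)
  if (any(!vapply(groups, length, 1L)))
    stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(groups)
  if (anyNA(x)) stop("missing values in groups", call. = FALSE)
  n_i <- vapply(groups, length, 1L)
  g <- rep(seq_along(groups), n_i)

  jt_stat <- function(x, g) {
    # ranks within each pooled pair of groups; vectorized over pairs
    j <- 0
    k <- max(g)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      xa <- x[g == a]; xb <- x[g == b]
      # Mann-Whitney count of (xa, xb) pairs with xb > xa, ties half,
      # via the rank-sum identity U = R_b - n_b (n_b + 1) / 2
      r <- rank(c(xa, xb))
      u <- sum(r[(length(xa) + 1):(length(xa) + length(xb))]) -
        length(xb) * (length(xb) + 1) / 2
      j <- j + u
    }
    j
  }
  J <- jt_stat(x, g)

  N <- length(x)
  EJ <- (N^2 - sum(n_i^2)) / 4
  # tie-corrected null variance
  t_j <- as.numeric(table(x))
  s1 <- N * (N - 1) * (2 * N + 5) - sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  s2 <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  s3 <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1))
  VJ <- s1 / 72 +
    s2 / (36 * N * (N - 1) * (N - 2)) +
    s3 / (8 * N * (N - 1))

  if (VJ <= 0) {
    warning("degenerate data (all values tied); z = 0, p = 1")
    z <- 0; p_asym <- 1
  } else {
    z <- (J - EJ) / sqrt(VJ)
    p_asym <- switch(alternative,
                     two.sided = 2 * stats::pnorm(-abs(z)),
                     increasing = stats::pnorm(z, lower.tail = FALSE),
                     decreasing = stats::pnorm(z))
  }

  p_perm <- NA_real_
  if (n_permutations > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    obs <- switch(alternative,
                  two.sided = abs(J - EJ),
                  increasing = J - EJ,
                  decreasing = EJ - J)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      Jp <- jt_stat(x, sample(g))
      stat <- switch(alternative,
                     two.sided = abs(Jp - EJ),
                     increasing = Jp - EJ,
                     decreasing = EJ - Jp)
      if (stat >= obs - 1e-12) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (n_permutations + 1)
  }

  structure(list(j_statistic = J, expected_j = EJ, variance_j = max(VJ, 0),
                 z_score = z, p_asymptotic = p_asym, p_permutation = p_perm,
                 alternative = alternative, group_sizes = n_i),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("<Jonckheere-Terpstra> J = %.1f (E = %.1f, var = %.2f), z = %.3f, p[%s] = %.4g\n",
              x$j_statistic, x$expected_j, x$variance_j, x$z_score,
              x$alternative, x$p_asymptotic))
  if (!is.na(x$p_permutation))
    cat(sprintf("  permutation p = %.4g\n", x$p_permutation))
  invisible(x)
}
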