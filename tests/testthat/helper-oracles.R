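# Independent oracles and fixture generators used across the suite.

# brute-force box counter: loop over every box and test occupancy directly
brute_box_count <- function(mask, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (r0 in seq(1, nr, by = s)) for (c0 in seq(1, nc, by = s)) {
    if (any(mask[r0:min(r0 + s - 1, nr), c0:min(c0 + s - 1, nc)]))
      cnt <- cnt + 1L
  }
  cnt
}

# exact Jonckheere-Terpstra null distribution by enumerating every
# assignment of the pooled values to the ordered groups
jt_exact_tail <- function(groups) {
  x <- unlist(groups)
  sizes <- vapply(groups, length, 1L)
  jt_of <- function(vals, sizes) {
    j <- 0
    idx <- split(seq_along(vals), rep(seq_along(sizes), sizes))
    k <- length(sizes)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      xa <- vals[idx[[a]]]; xb <- vals[idx[[b]]]
      for (u in xa) j <- j + sum(xb > u) + 0.5 * sum(xb == u)
    }
    j
  }
  j_obs <- jt_of(x, sizes)
  n <- length(x)
  # enumerate distinct assignments: choose positions of group 1, then 2, ...
  stats_all <- c()
  enumerate <- function(remaining, chosen) {
    if (length(chosen) == length(sizes) - 1L) {
      perm <- c(unlist(chosen), remaining)
      stats_all <<- c(stats_all, jt_of(x[perm], sizes))
      return(invisible(NULL))
    }
    g <- length(chosen) + 1L
    for (pick in utils::combn(remaining, sizes[g], simplify = FALSE))
      enumerate(setdiff(remaining, pick), c(chosen, list(pick)))
  }
  enumerate(seq_len(n), list())
  list(j_obs = j_obs, stats = stats_all,
       p_upper = mean(stats_all >= j_obs - 1e-12))
}

# small random vessel-like network mask: a few random thick strokes
random_network_mask <- function(seed, size = 96, n_strokes = 6) {
  set.seed(seed)
  segs <- lapply(seq_len(n_strokes), function(i) {
    x0 <- runif(1, 0.2, 2.8); y0 <- runif(1, 0.2, 2.8)
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 0.5, 1.8)
    t <- seq(0, 1, length.out = 20)
    list(x = pmin(pmax(x0 + len * t * cos(ang) + 0.05 * sin(8 * t), 0.01), 2.99),
         y = pmin(pmax(y0 + len * t * sin(ang) + 0.05 * cos(7 * t), 0.01), 2.99),
         width_um = runif(1, 40, 120), generation = 0L, type = "branch")
  })
  octaquant:::rasterize_segments(segs, 3, size)
}

has_full_2x2 <- function(m) {
  any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
}

sierpinski_carpet <- function(levels = 6) {
  n <- 3^levels
  idx <- 0:(n - 1)
  digit_is_one <- sapply(seq_len(levels) - 1L, function(k) (idx %/% 3^k) %% 3 == 1)
  carpet <- matrix(TRUE, n, n)
  for (k in seq_len(levels))
    carpet <- carpet & !outer(digit_is_one[, k], digit_is_one[, k], "&")
  carpet
}

# quick healthy synthetic angiogram for image tests
quick_angiogram <- function(seed, coverage = 0.4, size = 256) {
  net <- grow_network(vascular_network_spec(coverage = coverage,
                                            coverage_check_px = size),
                      seed = seed)
  suppressWarnings(render_angiogram(net, size, seed = seed + 1L))
}
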