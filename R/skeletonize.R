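# Morphological thinning of binary vessel maps.
#
# Guo-Hall two-subiteration parallel thinning (1989) reduces each vessel to a
# one-pixel-wide 8-connected centerline while preserving connectivity. A
# sequential cleanup pass removes simple pixels from any residual fully-set
# 2x2 block, and the (thin + cleanup) cycle repeats until a fixed point, which
# makes the operation idempotent by construction.

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

guo_hall_pass <- function(p, odd) {
  # neighbors: p2 = N, then clockwise. Matrix rows grow downward.
  p2 <- shift_mask(p, 1, 0);  p3 <- shift_mask(p, 1, -1)
  p4 <- shift_mask(p, 0, -1); p5 <- shift_mask(p, -1, -1)
  p6 <- shift_mask(p, -1, 0); p7 <- shift_mask(p, -1, 1)
  p8 <- shift_mask(p, 0, 1);  p9 <- shift_mask(p, 1, 1)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  nm <- pmin(n1, n2)
  m <- if (odd) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
  p & !(C == 1 & nm >= 2 & nm <= 3 & !m)
}

# Hilditch crossing number and neighbor count at one pixel of a padded mask
pixel_simple <- function(pad, r, c) {
  nb <- c(pad[r - 1, c], pad[r - 1, c + 1], pad[r, c + 1], pad[r + 1, c + 1],
          pad[r + 1, c], pad[r + 1, c - 1], pad[r, c - 1], pad[r - 1, c - 1])
  b <- sum(nb)
  a <- sum(!nb & c(nb[-1], nb[1]))  # 0 -> 1 transitions around the ring
  a == 1 && b >= 2
}

# remove simple pixels until no fully-set 2x2 block remains (sequential, so
# connectivity is preserved at every deletion)
clear_2x2 <- function(p) {
  repeat {
    blk <- p & shift_mask(p, -1, 0) & shift_mask(p, 0, -1) & shift_mask(p, -1, -1)
    if (!any(blk)) return(p)
    pad <- matrix(FALSE, nrow(p) + 2L, ncol(p) + 2L)
    pad[2:(nrow(p) + 1L), 2:(ncol(p) + 1L)] <- p
    changed <- FALSE
    for (i in which(blk)) {
      r <- (i - 1L) %% nrow(p) + 1L
      c <- (i - 1L) %/% nrow(p) + 1L
      # try the four pixels of this block, delete the first simple one
      for (d in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (pad[rr + 1L, cc + 1L] && pixel_simple(pad, rr + 1L, cc + 1L)) {
          pad[rr + 1L, cc + 1L] <- FALSE
          p[rr, cc] <- FALSE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(p)  # no simple pixel in any block; give up
  }
}

#' Skeletonize a binary vessel map
#'
#' Reduces each vessel to a one-pixel-wide centerline by homotopic thinning,
#' so that skeleton pixel count proxies total vessel length independent of
#' caliber. The result contains no fully-set 2x2 block, is a subset of the
#' input mask, preserves the number of 8-connected components, and is a fixed
#' point of the operation (skeletonizing a skeleton returns it unchanged).
#'
#' @param vessels a [binary_vessel_map()] or logical matrix.
#' @return A [skeleton_map()].
#' @examples
#' m <- matrix(FALSE, 20, 60); m[8:12, 5:55] <- TRUE
#' sk <- skeletonize(m)
#' sum(sk$mask)  # approximately the bar length
#' @export
skeletonize <- function(vessels) {
  p <- as_mask(vessels, "vessels")
  repeat {
    before <- p
    repeat {
      q <- guo_hall_pass(p, odd = TRUE)
      q <- guo_hall_pass(q, odd = FALSE)
      if (identical(q, p)) break
      p <- q
    }
    p <- clear_2x2(p)
    if (identical(p, before)) break
  }
  skeleton_map(p)
}

#' Count 8-connected components of a binary mask
#'
#' @param mask logical matrix or mask object.
#' @return Integer component count (0 for an empty mask).
#' @export
count_components <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m)
  if (length(idx) == 0L) return(0L)
  nr <- nrow(m); nc <- ncol(m)
  id <- integer(length(m)); id[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  from <- integer(0); to <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- m[nidx]
    from <- c(from, id[idx[ok]][hit])
    to <- c(to, id[nidx[hit]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  igraph::count_components(g)
}
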