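# Morphological skeletonization (Zhang-Suen thinning), vectorized over
# the whole mask with shifted copies. No installed image package exposes
# thinning, and the fiber tracer needs a 1-px-wide centerline.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighborhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# with x = column and y = row increasing downward ("N" = row - 1).
zs_neighbors <- function(m) {
  list(
    p2 = shift_mat(m, -1,  0), p3 = shift_mat(m, -1,  1),
    p4 = shift_mat(m,  0,  1), p5 = shift_mat(m,  1,  1),
    p6 = shift_mat(m,  1,  0), p7 = shift_mat(m,  1, -1),
    p8 = shift_mat(m,  0, -1), p9 = shift_mat(m, -1, -1)
  )
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Guo-Hall iterative thinning (two sub-iterations per pass), vectorized
#' over the whole mask. Chosen over the older Zhang-Suen scheme because
#' the latter deletes 2x2 blocks outright, which destroys the staircase
#' runs that near-diagonal fibers thin down to. Used by [trace_fibers()]
#' to reduce the thresholded fiber mask to centerlines.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param max_iter Safety cap on thinning iterations.
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(mask, max_iter = 500L) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbors(m)
      C <- ((1L - nb$p2) & (nb$p3 | nb$p4)) +
        ((1L - nb$p4) & (nb$p5 | nb$p6)) +
        ((1L - nb$p6) & (nb$p7 | nb$p8)) +
        ((1L - nb$p8) & (nb$p9 | nb$p2))
      n1 <- (nb$p9 | nb$p2) + (nb$p3 | nb$p4) + (nb$p5 | nb$p6) + (nb$p7 | nb$p8)
      n2 <- (nb$p2 | nb$p3) + (nb$p4 | nb$p5) + (nb$p6 | nb$p7) + (nb$p8 | nb$p9)
      nmin <- pmin(n1, n2)
      g3 <- if (step == 1) {
        (nb$p6 | nb$p7 | (1L - nb$p9)) & nb$p8
      } else {
        (nb$p2 | nb$p3 | (1L - nb$p5)) & nb$p4
      }
      del <- m == 1L & C == 1L & nmin >= 2L & nmin <= 3L & g3 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# count of 8-neighbors for each skeleton pixel
neighbor_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  nb <- zs_neighbors(m)
  Reduce(`+`, nb)
}

# Rutovitz crossing number: 0->1 transitions around the 8-neighborhood.
# Simple path pixels have 2 (1 at endpoints); true junctions >= 3. Plain
# neighbor counts over-call junctions on the staircase patterns oblique
# skeleton lines are made of.
crossing_number <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  nb <- zs_neighbors(m)
  seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) a <- a + (seqs[[k]] == 0L & seqs[[k + 1]] == 1L)
  a
}
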