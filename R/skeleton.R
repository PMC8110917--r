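# Morphological skeletonization (topological thinning) and skeleton length.

# Shift a logical/numeric matrix by (dr, dc), padding with 0.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels while preserving
#' connectivity and line ends, until the foreground is one pixel wide. The
#' result is the morphological centerline whose weighted pixel count
#' estimates object length.
#'
#' @param mask logical or 0/1 numeric matrix; non-zero is foreground.
#' @return Logical matrix of the same shape marking skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- (as.matrix(mask) != 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # 8-neighborhood in the order P2..P9 = N, NE, E, SE, S, SW, W, NW
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1L) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

#' Length of a skeleton in pixels
#'
#' Weighted pixel count of the skeleton: walking along the centerline, an
#' orthogonal step to the next pixel counts 1 and a diagonal step counts
#' sqrt(2) (raw pixel counts would understate diagonal runs by up to 41%).
#' A diagonal link is skipped when the two pixels are already joined
#' through a shared orthogonal skeleton neighbor, which avoids double
#' counting at corners; each connected skeleton piece contributes its
#' first pixel, so a straight k-pixel run measures k.
#'
#' @param skeleton logical matrix from [skeletonize()].
#' @return Total skeleton length in pixel units.
#' @export
skeleton_length <- function(skeleton) {
  s <- (as.matrix(skeleton) != 0) * 1
  n_px <- sum(s)
  if (n_px == 0) return(0)
  e <- shift_mat(s, 0, -1)   # right neighbor, aligned onto current pixel
  so <- shift_mat(s, -1, 0)  # below neighbor
  se <- shift_mat(s, -1, -1) # below-right
  sw <- shift_mat(s, -1, 1)  # below-left
  n_orth <- sum(s * e) + sum(s * so)
  # diagonal p->SE redundant if right or below neighbor of p is skeleton and
  # also orthogonally adjacent to the SE pixel (both are, by construction)
  diag_se <- s * se * (1 - pmax(s * e, s * so))
  w <- shift_mat(s, 0, 1)
  diag_sw <- s * sw * (1 - pmax(s * w, s * so))
  n_diag <- sum(diag_se) + sum(diag_sw)
  n_orth + sqrt(2) * n_diag + skeleton_component_count(s)
}

# Number of 8-connected components among skeleton pixels (union-find).
skeleton_component_count <- function(s) {
  idx <- which(s == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  key <- matrix(0L, nrow(s), ncol(s))
  key[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (k in 1:4) {
    r2 <- idx[, 1] + offs[k, 1]; c2 <- idx[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(s) & c2 >= 1 & c2 <= ncol(s)
    j <- integer(n); j[ok] <- key[cbind(r2[ok], c2[ok])]
    for (a in which(j > 0)) {
      ra <- find(a); rb <- find(j[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
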