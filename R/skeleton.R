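#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels of a binary mask until a one-pixel-wide,
#' 8-connected skeleton remains.
#'
#' @param mask binary matrix or `pixel_grid` (non-zero = foreground).
#' @return Binary matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- grid_values(mask) != 0
  storage.mode(m) <- "integer"
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north (rows grow downward, so north = -1 row)
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Number of 8-connected foreground neighbours of every pixel.
neighbor_count8 <- function(m) {
  m <- (grid_values(m) != 0) * 1
  conv2_replicate_zero <- function(x) {
    p <- matrix(0, nrow(x) + 2, ncol(x) + 2)
    p[2:(nrow(x) + 1), 2:(ncol(x) + 1)] <- x
    out <- matrix(0, nrow(x), ncol(x))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out + p[(2 + dr):(nrow(x) + 1 + dr), (2 + dc):(ncol(x) + 1 + dc)]
    }
    out
  }
  conv2_replicate_zero(m)
}

# Branch points of a skeleton: foreground pixels with >= 3 neighbours.
branch_points <- function(skel) {
  (grid_values(skel) != 0) & (neighbor_count8(skel) >= 3)
}

# 8-connected component labeling (breadth-first), returning an integer label
# matrix with 0 = background. EBImage::bwlabel is 4-connected, which splits
# diagonal skeleton steps; skeleton morphometrics need 8-connectivity.
label8 <- function(mask) {
  m <- grid_values(mask) != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  idx_fg <- which(m)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (o in seq_len(nrow(offsets))) {
        rr <- r + offsets$dr[o]; cc <- cl + offsets$dc[o]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        ii <- (cc - 1L) * nr + rr
        if (m[ii] && lab[ii] == 0L) {
          lab[ii] <- nxt
          queue <- c(queue, ii)
        }
      }
    }
  }
  lab
}

# Endpoints of a skeleton component: exactly one 8-connected neighbour.
endpoints_of <- function(skel) {
  which((grid_values(skel) != 0) & (neighbor_count8(skel) == 1))
}

# Walk a simple 8-connected path from `start` (linear index) to its other
# endpoint, returning ordered (row, col) coordinates. 4-neighbours are
# preferred over diagonals when both touch, which keeps steps minimal.
walk_path <- function(m, start) {
  nr <- nrow(m)
  visited <- matrix(FALSE, nr, ncol(m))
  path_r <- integer(0); path_c <- integer(0)
  cur <- start
  ord4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  ord8 <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    r <- ((cur - 1L) %% nr) + 1L
    cl <- ((cur - 1L) %/% nr) + 1L
    visited[cur] <- TRUE
    path_r <- c(path_r, r); path_c <- c(path_c, cl)
    nxt <- 0L
    for (o in seq_len(4)) {
      rr <- r + ord4[o, 1]; cc <- cl + ord4[o, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
      ii <- (cc - 1L) * nr + rr
      if (m[ii] != 0 && !visited[ii]) { nxt <- ii; break }
    }
    if (nxt == 0L) for (o in seq_len(4)) {
      rr <- r + ord8[o, 1]; cc <- cl + ord8[o, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
      ii <- (cc - 1L) * nr + rr
      if (m[ii] != 0 && !visited[ii]) { nxt <- ii; break }
    }
    if (nxt == 0L) break
    cur <- nxt
  }
  cbind(row = path_r, col = path_c)
}
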