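#' Global Shannon entropy of an image
#'
#' Entropy in bits of the 256-bin intensity histogram after min-max scaling
#' of the image to the 0-255 range (`0 * log 0 := 0`). Periderm slices of a
#' confocal stack have markedly lower entropy than the speckled basal
#' epidermis, which is what slice filtering exploits.
#'
#' @param img `pixel_grid` or numeric matrix.
#' @return Entropy in bits (0 for a constant image).
#' @export
shannon_entropy <- function(img) {
  m <- grid_values(img)
  if (length(m) == 0) stop("empty image")
  q <- quantize256(m)
  p <- tabulate(q + 1L, nbins = 256L) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Min-max scale to integers 0..255 (constant image maps to all zeros).
quantize256 <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) {
    q <- round((m - rng[1]) / (rng[2] - rng[1]) * 255)
    storage.mode(q) <- "integer"
    q
  } else {
    matrix(0L, nrow(m), ncol(m))
  }
}

#' Local entropy map
#'
#' Per-pixel Shannon entropy (bits) of the intensity multiset in a square
#' window around each pixel, computed on the globally 256-level quantized
#' image with replicate-padded borders. Used to mask pixels where basal
#' speckle bleeds into a periderm slice.
#'
#' @param img `pixel_grid` or matrix (at least window x window).
#' @param window odd window size in pixels (default 3).
#' @return Matrix of entropies, same shape as `img`.
#' @export
local_entropy_map <- function(img, window = 3) {
  m <- grid_values(img)
  if (nrow(m) < window || ncol(m) < window)
    stop("image smaller than the entropy window")
  q <- quantize256(m)
  h <- (window - 1L) %/% 2L
  p <- pad_replicate(q, h)
  nr <- nrow(m); nc <- ncol(m)
  npx <- window * window
  # gather the window multiset of every pixel as rows of an n x window^2 array
  neigh <- matrix(0L, nr * nc, npx)
  k <- 0L
  for (dj in -h:h) for (di in -h:h) {
    k <- k + 1L
    neigh[, k] <- as.vector(p[(h + 1 + di):(h + nr + di),
                              (h + 1 + dj):(h + nc + dj)])
  }
  ent <- apply(neigh, 1L, function(v) {
    cnt <- tabulate(match(v, unique(v)))
    pr <- cnt / npx
    -sum(pr * log2(pr))
  })
  matrix(ent, nr, nc)
}

#' Entropy-based slice selection and mean projection
#'
#' Reduces an XYZT stack to one 2D frame per time point: z-slices whose
#' global entropy is at or below `global_threshold` are kept (the periderm),
#' pixels whose local entropy exceeds `local_threshold` are zeroed, and the
#' per-pixel mean over the kept slices is returned. Thresholds are fixed per
#' movie and applied identically at every time point.
#'
#' @param stack 4D numeric array `[row, col, z, t]` (a 3D `[row, col, z]`
#'   array is treated as a single time point).
#' @param global_threshold slice-level entropy threshold in bits.
#' @param local_threshold pixel-level entropy threshold in bits (`Inf`
#'   disables pixel masking).
#' @param window local entropy window (default 3).
#' @param pixel_size micrometres per pixel for the returned grids.
#' @return List with `frames` (list of `pixel_grid`, one per time point),
#'   `kept_indices` (list of kept z indices per time point) and the
#'   thresholds used.
#' @export
select_and_project <- function(stack, global_threshold, local_threshold = Inf,
                               window = 3, pixel_size = 1) {
  if (length(dim(stack)) == 3) dim(stack) <- c(dim(stack), 1)
  if (length(dim(stack)) != 4) stop("stack must be a 3D or 4D array")
  nz <- dim(stack)[3]; nt <- dim(stack)[4]
  frames <- vector("list", nt)
  kept <- vector("list", nt)
  for (t in seq_len(nt)) {
    ent <- vapply(seq_len(nz), function(z) shannon_entropy(stack[, , z, t]),
                  numeric(1))
    keep <- which(ent <= global_threshold)
    if (length(keep) == 0)
      stop("no z-slice passes the global entropy threshold at time point ", t)
    kept[[t]] <- keep
    acc <- matrix(0, dim(stack)[1], dim(stack)[2])
    for (z in keep) {
      sl <- stack[, , z, t]
      if (is.finite(local_threshold)) {
        le <- local_entropy_map(sl, window = window)
        sl[le > local_threshold] <- 0
      }
      acc <- acc + sl
    }
    frames[[t]] <- pixel_grid(acc / length(keep), pixel_size, pixel_size)
  }
  list(frames = frames, kept_indices = kept,
       global_threshold = global_threshold,
       local_threshold = local_threshold, window = window)
}
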