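#' Read an image stack from a multi-page TIFF
#'
#' Pages are stacked along z; when `n_z` is given, pages are folded into a
#' 4D `[row, col, z, t]` array (page order: z fastest, then t).
#'
#' @param path TIFF file.
#' @param n_z slices per time point (default: all pages are one time point).
#' @return 4D numeric array `[row, col, z, t]`.
#' @export
read_stack_tiff <- function(path, n_z = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  np <- length(pages)
  if (is.null(n_z)) n_z <- np
  if (np %% n_z != 0) stop("page count is not a multiple of n_z")
  nt <- np %/% n_z
  arr <- array(0, c(dim(pages[[1]]), n_z, nt))
  k <- 0L
  for (t in seq_len(nt)) for (z in seq_len(n_z)) {
    k <- k + 1L
    arr[, , z, t] <- pages[[k]]
  }
  arr
}

#' Write one or more grids to a (multi-page) TIFF
#'
#' Values are min-max scaled to \[0, 1\] per file unless already in range.
#'
#' @param grids a matrix/`pixel_grid` or a list of them.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_grid_tiff <- function(grids, path) {
  if (!is.list(grids) || inherits(grids, "pixel_grid")) grids <- list(grids)
  ms <- lapply(grids, grid_values)
  lo <- min(vapply(ms, min, numeric(1)))
  hi <- max(vapply(ms, max, numeric(1)))
  if (lo < 0 || hi > 1) {
    rng <- max(hi - lo, .Machine$double.eps)
    ms <- lapply(ms, function(m) (m - lo) / rng)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(ms, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' @param mask binary matrix.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG((grid_values(mask) != 0) * 1, path)
  invisible(path)
}

#' Write worm-like chains to CSV
#'
#' @param wlc `wlc_set` from [make_wormlike_chains()].
#' @param path output CSV with columns `chain`, `point`, `x_um`, `y_um`.
#' @return The path, invisibly.
#' @export
write_chains_csv <- function(wlc, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- do.call(rbind, lapply(seq_along(wlc$chains), function(i) {
    ch <- wlc$chains[[i]]
    data.frame(chain = i, point = seq_len(nrow(ch)),
               x_um = ch[, 1], y_um = ch[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
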