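#' Track cells across frames by nearest centroid distance
#'
#' Links detections between consecutive frames by minimum-total-cost
#' bipartite assignment on the Euclidean centroid distance matrix, with
#' pairings beyond `cutoff` forbidden: such detections terminate their track
#' and start a new one. This coincides with greedy nearest-neighbour linking
#' whenever that is unambiguous, and resolves conflicts globally otherwise.
#'
#' @param frames list (one element per frame) of n x 2 matrices of centroid
#'   coordinates in micrometres (columns x, y).
#' @param cutoff maximum linking distance in micrometres (default 2.5).
#' @return List of `cell_track` objects; each has `track_id` and a
#'   data.frame `points` with columns `t` (frame index), `cell_id`
#'   (detection index within its frame), `x_um`, `y_um`.
#' @export
track_cells <- function(frames, cutoff = 2.5) {
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (length(f) == 0) f <- matrix(numeric(0), 0, 2)
    f
  })
  nt <- length(frames)
  # track index currently attached to each detection of the previous frame
  tracks <- list()
  open_track <- function(t, i) {
    tracks[[length(tracks) + 1]] <<- data.frame(
      t = t, cell_id = i, x_um = frames[[t]][i, 1], y_um = frames[[t]][i, 2])
    length(tracks)
  }
  if (nt == 0) return(list())
  prev_track <- vapply(seq_len(nrow(frames[[1]])), function(i)
    open_track(1L, i), integer(1))
  if (nt >= 2) for (t in seq_len(nt - 1)) {
    a <- frames[[t]]; b <- frames[[t + 1]]
    cur_track <- integer(nrow(b))
    if (nrow(a) > 0 && nrow(b) > 0) {
      d <- sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
      d[d > cutoff] <- Inf
      assign <- solve_lap(d)
      for (i in seq_len(nrow(a))) {
        j <- assign[i]
        if (!is.na(j)) {
          tr <- prev_track[i]
          tracks[[tr]] <- rbind(tracks[[tr]], data.frame(
            t = t + 1L, cell_id = j, x_um = b[j, 1], y_um = b[j, 2]))
          cur_track[j] <- tr
        }
      }
    }
    for (j in seq_len(nrow(b))) if (cur_track[j] == 0L)
      cur_track[j] <- open_track(t + 1L, j)
    prev_track <- cur_track
  }
  lapply(seq_along(tracks), function(k)
    structure(list(track_id = k, points = tracks[[k]]), class = "cell_track"))
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> id %d, %d frame(s), t = %d..%d\n", x$track_id,
              nrow(x$points), min(x$points$t), max(x$points$t)))
  invisible(x)
}

#' Tracks as a tidy table
#'
#' @param tracks list of `cell_track` objects from [track_cells()] or
#'   [track_ridges()].
#' @return data.frame with columns `track_id`, `t`, `cell_id`, `x_um`,
#'   `y_um`.
#' @export
tracks_table <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr)
    cbind(track_id = tr$track_id, tr$points)))
}
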