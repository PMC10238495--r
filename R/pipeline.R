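#' Default pipeline configuration
#'
#' Returns the full stage-block configuration with every tunable parameter
#' at its default. Unknown keys passed to [run_pipeline()] are rejected.
#'
#' @return Nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "ridgemetrics_out",
    stages = c("preprocess", "segment_cells", "track_cells", "label_ridges",
               "metrics"),
    preprocess = list(global_threshold = 5, local_threshold = Inf, window = 3),
    segment_cells = list(sigma = 0.7, bhp_n = 1, bhp_D0 = 3, close_radius = 2,
                         min_area = 0, min_solidity = 0),
    track_cells = list(cutoff = 2.5),
    label_ridges = list(sigma = 0.7, sigma_g = 0.7),
    metrics = list(temperature = 300, spline_factor = 10, min_points = 10)
  )
}

# deep-merge user config into defaults, rejecting unknown keys
merge_config <- function(user, defaults = default_config(), path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the processing pipeline end to end
#'
#' Orchestrates preprocess (entropy slice filtering + projection), cell
#' segmentation and extraction, cell tracking, conventional ridge labeling
#' and per-cell pattern metrics (wavelength, branch lengths, persistence
#' length) on an XYZT stack, writing every artifact plus a manifest with
#' checksums under `config$out_dir`.
#'
#' @param stack 4D array `[row, col, z, t]` or path to a multi-page TIFF
#'   (then `n_z` is required via `config$n_z` handled by the CLI).
#' @param config nested list overriding [default_config()]; may also be a
#'   path to a YAML file.
#' @param pixel_size micrometres per pixel.
#' @return The run manifest (named list of artifact paths and md5 sums),
#'   invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(stack, config = list(), pixel_size = 0.1977) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)
  stage <- "init"
  result <- try({
    stage <- "preprocess"
    frames <- if ("preprocess" %in% cfg$stages) {
      sel <- select_and_project(stack, cfg$preprocess$global_threshold,
                                cfg$preprocess$local_threshold,
                                window = cfg$preprocess$window,
                                pixel_size = pixel_size)
      add(write_grid_tiff(sel$frames, file.path(out_dir, "projected.tif")))
      kept <- data.frame(
        t = rep(seq_along(sel$kept_indices),
                lengths(sel$kept_indices)),
        z = unlist(sel$kept_indices))
      p <- file.path(out_dir, "kept_slices.csv")
      utils::write.csv(kept, p, row.names = FALSE)
      add(p)
      sel$frames
    } else {
      nt <- dim(stack)[4]
      lapply(seq_len(nt), function(t)
        pixel_grid(apply(stack[, , , t, drop = FALSE], c(1, 2), mean),
                   pixel_size, pixel_size))
    }

    cells_by_t <- NULL
    if ("segment_cells" %in% cfg$stages) {
      stage <- "segment_cells"
      sc <- cfg$segment_cells
      cells_by_t <- lapply(seq_along(frames), function(t) {
        sm <- gaussian_smooth(frames[[t]], sigma = sc$sigma)
        hp <- butterworth_highpass(sm, n = sc$bhp_n, D0 = sc$bhp_D0)
        mm <- close_membranes(hp, close_radius = sc$close_radius)
        extract_cells(mm, sm, min_area = sc$min_area,
                      min_solidity = sc$min_solidity)
      })
      props <- do.call(rbind, lapply(seq_along(cells_by_t), function(t) {
        cells <- cells_by_t[[t]]
        if (length(cells) == 0) return(NULL)
        do.call(rbind, lapply(seq_along(cells), function(i) {
          cl <- cells[[i]]
          data.frame(t = t, cell = i, area_px2 = cl$area,
                     solidity = cl$solidity,
                     centroid_x_px = cl$centroid[1],
                     centroid_y_px = cl$centroid[2])
        }))
      }))
      p <- file.path(out_dir, "cells.csv")
      utils::write.csv(props, p, row.names = FALSE)
      add(p)
      for (t in seq_along(cells_by_t)) for (i in seq_along(cells_by_t[[t]])) {
        add(write_grid_tiff(cells_by_t[[t]][[i]]$patterned_image,
                            file.path(out_dir,
                                      sprintf("cell_%04d_%04d.tif", t, i))))
      }
    }

    if ("track_cells" %in% cfg$stages) {
      stage <- "track_cells"
      if (is.null(cells_by_t))
        stop("track_cells requires the segment_cells stage")
      cent <- lapply(cells_by_t, function(cells) {
        if (length(cells) == 0) return(matrix(numeric(0), 0, 2))
        do.call(rbind, lapply(cells, function(cl)
          cl$centroid * c(pixel_size, pixel_size)))
      })
      tracks <- track_cells(cent, cutoff = cfg$track_cells$cutoff)
      p <- file.path(out_dir, "tracks.csv")
      utils::write.csv(tracks_table(tracks), p, row.names = FALSE)
      add(p)
    }

    labels <- NULL
    if ("label_ridges" %in% cfg$stages) {
      stage <- "label_ridges"
      if (is.null(cells_by_t))
        stop("label_ridges requires the segment_cells stage")
      lr <- cfg$label_ridges
      labels <- lapply(cells_by_t, function(cells) lapply(cells, function(cl)
        label_cell(cl$patterned_image, sigma = lr$sigma,
                   sigma_g = lr$sigma_g)))
      for (t in seq_along(labels)) for (i in seq_along(labels[[t]])) {
        add(write_mask_png(labels[[t]][[i]]$label,
                           file.path(out_dir,
                                     sprintf("label_%04d_%04d.png", t, i))))
      }
    }

    if ("metrics" %in% cfg$stages) {
      stage <- "metrics"
      if (is.null(labels)) stop("metrics requires the label_ridges stage")
      mt <- cfg$metrics
      rows <- list()
      pool <- numeric(0)
      for (t in seq_along(labels)) for (i in seq_along(labels[[t]])) {
        B <- labels[[t]][[i]]$label
        if (sum(B) == 0) next
        sw <- try(pattern_wavelength(B, ds_edge = pixel_size), silent = TRUE)
        bs <- branch_stats(B, ds_edge = pixel_size)
        rows[[length(rows) + 1]] <- data.frame(
          t = t, cell = i,
          lambda_um = if (inherits(sw, "try-error")) NA_real_ else sw$lambda,
          mean_branch_len_um = bs$mean_branch_length,
          n_branches = bs$n_branches)
        traces <- trace_branches(B, dx = pixel_size, dy = pixel_size,
                                 min_points = mt$min_points)
        pool <- c(pool, unlist(lapply(traces, function(tr) {
          sm <- orient_and_smooth(tr$coords)
          dn <- try(spline_interpolate(sm, factor = mt$spline_factor),
                    silent = TRUE)
          if (inherits(dn, "try-error")) return(numeric(0))
          curvature_series(dn)$kappa_s
        })))
      }
      p <- file.path(out_dir, "pattern_metrics.csv")
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
      add(p)
      summary <- list(n_kappa_s = length(pool))
      if (length(pool) >= 100) {
        est <- fit_lp(pool, temperature = mt$temperature)
        summary$lp_um <- est$lp
        summary$ei_Nm2 <- est$ei
        summary$fc_pN_L1um <- critical_force(est$lp, 1, mt$temperature)
      }
      p <- file.path(out_dir, "summary.json")
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
      add(p)
    }
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    manifest <- list(status = "failed", failed_stage = stage,
                     error = attr(result, "condition")$message,
                     artifacts = as.list(tools::md5sum(artifacts)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         attr(result, "condition")$message)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  add(cfg_path)
  manifest <- list(status = "ok", seed = cfg$seed,
                   artifacts = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
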