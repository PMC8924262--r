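# Plain-text and TIFF interchange.
#
# Sweeps are persisted as a long CSV (sweep_id, time_s, current_pa, stimulus)
# plus a JSON sidecar holding the acquisition metadata and, for synthetic
# sweeps, the generative ground truth. TIRF movies go to multi-page 16-bit
# TIFF; tracks to CSV with fixed column names (track_id, frame, x_um, y_um).

#' Write a list of sweeps to CSV with a JSON metadata sidecar
#'
#' @param sweeps Named or unnamed list of sweeps.
#' @param path Path of the CSV file; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  ids <- names(sweeps) %||% as.character(seq_along(sweeps))
  if (is.null(names(sweeps))) ids <- sprintf("sweep_%03d", seq_along(sweeps))
  long <- purrr::map2_dfr(sweeps, ids, function(sw, id) {
    tibble(sweep_id = id, time_s = sw$time_s, current_pa = sw$current_pa,
           stimulus = sw$stimulus)
  })
  utils::write.csv(long, path, row.names = FALSE)
  meta <- purrr::map2(sweeps, ids, function(sw, id) {
    m <- sweep_meta(sw)
    if (!is.null(m$truth$events)) m$truth$events <- as.data.frame(m$truth$events)
    list(sweep_id = id,
         sampling_khz = sweep_attr(sw, "sampling_khz"),
         holding_mv = sweep_attr(sw, "holding_mv"),
         onset_index = sweep_attr(sw, "onset_index"),
         end_index = sweep_attr(sw, "end_index"),
         meta = m)
  })
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read sweeps written by [write_sweeps_csv()]
#'
#' @param path Path of the CSV file (the `<path>.meta.json` sidecar must
#'   exist alongside).
#' @return Named list of sweeps.
#' @export
read_sweeps_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- lapply(meta, function(m) {
    rows <- long[long$sweep_id == m$sweep_id, ]
    mm <- m$meta %||% list()
    if (!is.null(mm$truth$events)) {
      mm$truth$events <- as_tibble(as.data.frame(
        lapply(mm$truth$events, unlist)))
    }
    new_sweep(rows$time_s, rows$current_pa, rows$stimulus,
              sampling_khz = m$sampling_khz, holding_mv = m$holding_mv,
              onset_index = m$onset_index, end_index = m$end_index,
              meta = mm)
  })
  names(out) <- vapply(meta, `[[`, character(1), "sweep_id")
  out
}

#' Write a TIRF movie as a multi-page 16-bit TIFF
#'
#' Pixel values are clamped at 0 and scaled by `scale_max` to the 16-bit
#' range.
#'
#' @param movie A `pq_tirf_movie` or a numeric array `ny x nx x n_frames`.
#' @param path Output TIFF path.
#' @param scale_max Intensity mapped to the top of the 16-bit range; defaults
#'   to the movie maximum.
#' @return `path`, invisibly.
#' @export
write_tirf_tiff <- function(movie, path, scale_max = NULL) {
  frames <- if (inherits(movie, "pq_tirf_movie")) movie$frames else movie
  scale_max <- scale_max %||% max(frames)
  pages <- lapply(seq_len(dim(frames)[3]), function(f) {
    pmin(pmax(frames[, , f] / scale_max, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a movie array
#'
#' @param path TIFF path.
#' @return Numeric array `ny x nx x n_frames` with values in `[0, 1]`.
#' @export
read_tirf_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Write a track table to CSV
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks[c("track_id", "frame", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}
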