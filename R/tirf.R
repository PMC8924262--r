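# TIRF cluster detection, tracking and motility analysis.
#
# Spots are detected per frame with a difference-of-Gaussians (DoG) blob
# filter and refined to sub-pixel precision by a local quadratic fit. The
# detector's quality is the DoG response normalized by a robust noise
# estimate of the DoG image, so the quality threshold has a reproducible
# meaning across movies. Linking is nearest-neighbour per adjacent frame
# pair (greedy on squared distance under a hard cap) with gap closing, which
# is adequate at the spot densities simulated here.

#' Detect spots in one frame
#'
#' @param frame Numeric matrix (one image, rows = y, cols = x).
#' @param pixel_size_um Pixel size (um).
#' @param blob_diameter_um Expected spot diameter (um); sets the DoG scales.
#' @param quality_min Minimum quality (DoG response / robust noise of the DoG
#'   image) for a maximum to count as a spot.
#' @return Tibble with columns `x_um`, `y_um`, `quality`, `intensity`.
#'   Coordinates have their origin at the top-left pixel center, x rightward,
#'   y downward.
#' @export
detect_spots <- function(frame, pixel_size_um = 0.11, blob_diameter_um = 0.7,
                         quality_min = 10) {
  d_px <- blob_diameter_um / pixel_size_um
  if (d_px < 2) abort("`blob_diameter_um` must be at least 2 pixels.")
  s1 <- d_px / (2 * sqrt(2))
  s2 <- 1.6 * s1
  img <- EBImage::Image(frame)
  dog <- EBImage::gblur(img, s1) - EBImage::gblur(img, s2)
  dog <- EBImage::imageData(dog)
  noise <- mad(dog)
  if (noise <= 0) noise <- sd(dog)
  if (noise <= 0) return(tibble(x_um = numeric(), y_um = numeric(),
                                quality = numeric(), intensity = numeric()))
  q <- dog / noise

  ny <- nrow(q); nx <- ncol(q)
  margin <- max(2L, ceiling(s2))
  # 8-neighbour local maxima
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- q
  nb_max <- pmax(pad[1:ny, 1:nx], pad[1:ny, 2:(nx + 1)], pad[1:ny, 3:(nx + 2)],
                 pad[2:(ny + 1), 1:nx], pad[2:(ny + 1), 3:(nx + 2)],
                 pad[3:(ny + 2), 1:nx], pad[3:(ny + 2), 2:(nx + 1)],
                 pad[3:(ny + 2), 3:(nx + 2)])
  is_max <- q > nb_max & q >= quality_min
  is_max[c(seq_len(margin), ny - seq_len(margin) + 1L), ] <- FALSE
  is_max[, c(seq_len(margin), nx - seq_len(margin) + 1L)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble(x_um = numeric(), y_um = numeric(),
                  quality = numeric(), intensity = numeric()))
  }
  refine <- function(v_m, v_0, v_p) {
    den <- v_m - 2 * v_0 + v_p
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (v_m - v_p) / den))
  }
  out <- apply(idx, 1, function(rc) {
    r <- rc[[1]]; c <- rc[[2]]
    dyy <- refine(q[r - 1, c], q[r, c], q[r + 1, c])
    dxx <- refine(q[r, c - 1], q[r, c], q[r, c + 1])
    c(x = (c - 1 + dxx) * pixel_size_um,
      y = (r - 1 + dyy) * pixel_size_um,
      quality = q[r, c], intensity = frame[r, c])
  })
  out <- t(out)
  tibble(x_um = out[, "x"], y_um = out[, "y"],
         quality = out[, "quality"], intensity = out[, "intensity"])
}

#' Detect spots in every frame of a movie
#'
#' @param movie A `pq_tirf_movie` (from [simulate_tirf_movie()]) or a numeric
#'   array `ny x nx x n_frames`.
#' @inheritParams detect_spots
#' @return Tibble with columns `frame`, `x_um`, `y_um`, `quality`,
#'   `intensity`.
#' @export
detect_spots_movie <- function(movie, pixel_size_um = 0.11,
                               blob_diameter_um = 0.7, quality_min = 10) {
  if (inherits(movie, "pq_tirf_movie")) {
    pixel_size_um <- movie$cfg$pixel_size_um
    movie <- movie$frames
  }
  purrr::map_dfr(seq_len(dim(movie)[3]), function(f) {
    sp <- detect_spots(movie[, , f], pixel_size_um, blob_diameter_um,
                       quality_min)
    if (nrow(sp)) sp$frame <- f
    sp
  }) |> dplyr::relocate("frame")
}

# greedy assignment between two point sets under a distance cap; returns an
# integer vector over rows of `a` giving the matched row of `b` (NA if none)
greedy_match <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax); nb <- length(bx)
  match_ab <- rep(NA_integer_, na)
  if (!na || !nb) return(match_ab)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  cap <- max_dist^2
  cand <- which(d2 <= cap, arr.ind = TRUE)
  if (!nrow(cand)) return(match_ab)
  ord <- order(d2[cand])
  used_a <- logical(na); used_b <- logical(nb)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      match_ab[i] <- j
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  match_ab
}

#' Link detected spots into tracks
#'
#' Frame-to-frame nearest-neighbour assignment (greedy on squared distance,
#' capped at `link_distance_um`), followed by gap closing: a track end is
#' joined to a later track start when the spatial distance is at most
#' `gap_distance_um` and the frame gap is at most `max_gap`. Gap frames are
#' linearly interpolated and flagged. Tracks spanning fewer than
#' `min_duration` frames are discarded.
#'
#' @param spots Tibble with columns `frame`, `x_um`, `y_um` (e.g. from
#'   [detect_spots_movie()]).
#' @param link_distance_um Maximum frame-to-frame link distance (um).
#' @param gap_distance_um Maximum gap-closing distance (um).
#' @param max_gap Maximum number of missed frames to close over.
#' @param min_duration Minimum track duration in frames (first to last).
#' @return Tibble with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `interpolated`.
#' @export
link_tracks <- function(spots, link_distance_um = 0.5, gap_distance_um = 0.7,
                        max_gap = 2, min_duration = 40) {
  if (!nrow(spots)) {
    return(tibble(track_id = integer(), frame = integer(), x_um = numeric(),
                  y_um = numeric(), interpolated = logical()))
  }
  spots <- dplyr::arrange(spots, .data$frame)
  frames <- sort(unique(spots$frame))
  by_frame <- split(spots, spots$frame)

  # active track bookkeeping
  tracks <- list()          # each: tibble(frame, x_um, y_um)
  last_pos <- list()        # c(x, y, frame)
  open <- integer()         # track ids active in the previous frame

  for (f in frames) {
    cur <- by_frame[[as.character(f)]]
    prev_ids <- open[vapply(open, function(id) last_pos[[id]][3] == f - 1, logical(1))]
    if (length(prev_ids)) {
      ax <- vapply(prev_ids, function(id) last_pos[[id]][1], numeric(1))
      ay <- vapply(prev_ids, function(id) last_pos[[id]][2], numeric(1))
      m <- greedy_match(ax, ay, cur$x_um, cur$y_um, link_distance_um)
    } else {
      m <- integer()
    }
    used_spots <- logical(nrow(cur))
    for (k in seq_along(prev_ids)) {
      j <- m[k]
      if (!is.na(j)) {
        id <- prev_ids[k]
        tracks[[id]] <- rbind(tracks[[id]], c(f, cur$x_um[j], cur$y_um[j]))
        last_pos[[id]] <- c(cur$x_um[j], cur$y_um[j], f)
        used_spots[j] <- TRUE
      }
    }
    for (j in which(!used_spots)) {
      id <- length(tracks) + 1L
      tracks[[id]] <- matrix(c(f, cur$x_um[j], cur$y_um[j]), nrow = 1)
      last_pos[[id]] <- c(cur$x_um[j], cur$y_um[j], f)
    }
    open <- seq_along(tracks)
  }

  # gap closing: join ends to starts within gap_distance and <= max_gap
  # missed frames, greedily by spatial distance
  starts <- t(vapply(tracks, function(m) m[1, ], numeric(3)))
  ends <- t(vapply(tracks, function(m) m[nrow(m), ], numeric(3)))
  merged_into <- seq_along(tracks)
  repeat {
    cand <- NULL
    for (i in seq_along(tracks)) {
      if (merged_into[i] != i) next
      gap_ok <- which(merged_into == seq_along(tracks) &
                        starts[, 1] > ends[i, 1] + 1 &
                        starts[, 1] <= ends[i, 1] + 1 + max_gap)
      if (!length(gap_ok)) next
      d <- sqrt((starts[gap_ok, 2] - ends[i, 2])^2 +
                  (starts[gap_ok, 3] - ends[i, 3])^2)
      ok <- which(d <= gap_distance_um)
      if (!length(ok)) next
      j <- gap_ok[ok[which.min(d[ok])]]
      if (is.null(cand) || min(d[ok]) < cand$d) {
        cand <- list(i = i, j = j, d = min(d[ok]))
      }
    }
    if (is.null(cand)) break
    i <- cand$i; j <- cand$j
    tracks[[i]] <- rbind(tracks[[i]], tracks[[j]])
    ends[i, ] <- ends[j, ]
    merged_into[j] <- i
    starts[j, 1] <- Inf    # retire j
  }

  keep <- which(merged_into == seq_along(tracks))
  out <- purrr::imap_dfr(tracks[keep], function(m, k) {
    dur <- m[nrow(m), 1] - m[1, 1] + 1
    if (dur < min_duration) return(NULL)
    fr <- m[, 1]
    full <- seq(fr[1], fr[length(fr)])
    x <- approx(fr, m[, 2], xout = full)$y
    y <- approx(fr, m[, 3], xout = full)$y
    tibble(track_id = k, frame = as.integer(full), x_um = x, y_um = y,
           interpolated = !(full %in% fr))
  })
  if (!nrow(out)) {
    return(tibble(track_id = integer(), frame = integer(), x_um = numeric(),
                  y_um = numeric(), interpolated = logical()))
  }
  out$track_id <- match(out$track_id, unique(out$track_id))
  out
}

#' Time-averaged mean squared displacement of one track
#'
#' MSD at lag `L` is averaged over all overlapping position pairs `L` frames
#' apart; lags run up to `max_lag_fraction` of the track duration.
#'
#' @param track Tibble with columns `frame`, `x_um`, `y_um` (one track,
#'   consecutive frames).
#' @param frame_rate_hz Frames per second (sets the lag time axis).
#' @param max_lag_fraction Longest lag as a fraction of track duration.
#' @return Tibble of class `pq_msd` with columns `lag_s`, `msd_um2`,
#'   `n_pairs`.
#' @export
compute_msd <- function(track, frame_rate_hz = 10, max_lag_fraction = 0.25) {
  n <- nrow(track)
  if (n < 4) abort("track must have at least 4 positions.")
  max_lag <- max(1L, floor(n * max_lag_fraction))
  x <- track$x_um; y <- track$y_um
  msd <- vapply(seq_len(max_lag), function(L) {
    dx <- x[(1 + L):n] - x[1:(n - L)]
    dy <- y[(1 + L):n] - y[1:(n - L)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  out <- tibble(lag_s = seq_len(max_lag) / frame_rate_hz,
                msd_um2 = msd,
                n_pairs = n - seq_len(max_lag))
  class(out) <- c("pq_msd", class(out))
  out
}

#' Classify the motility of one track
#'
#' The anomalous exponent `alpha` is the slope of `log(msd)` vs `log(lag)`
#' over the first five lags; tracks are `"directed"` when `alpha >= 1.5` or
#' the net/total path straightness is >= 0.6, `"confined"` when `alpha < 0.3`
#' or the normalized long/short-lag MSD ratio is < 0.3, `"subdiffusion"` for
#' `0.3 <= alpha < 0.85`, else `"normal diffusion"`. `D_fit` is
#' `msd(lag1) / (4 lag1)`.
#'
#' @param msd A [compute_msd()] result with at least 5 usable lags.
#' @param track The corresponding track (for the straightness feature).
#' @return One-row tibble: `category`, `alpha`, `d_fit_um2_s`,
#'   `straightness`, `confinement_ratio`, `flagged`.
#' @export
classify_track <- function(msd, track) {
  if (nrow(msd) < 5) abort("need at least 5 usable MSD lags.")
  m5 <- msd[1:5, ]
  if (all(m5$msd_um2 == 0)) {
    return(tibble(category = "confined", alpha = 0, d_fit_um2_s = 0,
                  straightness = 0, confinement_ratio = 0, flagged = TRUE))
  }
  a <- unname(coef(lm(log(m5$msd_um2) ~ log(m5$lag_s)))[2])
  d_fit <- m5$msd_um2[1] / (4 * m5$lag_s[1])
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                (track$y_um[nrow(track)] - track$y_um[1])^2)
  straightness <- if (sum(steps) > 0) net / sum(steps) else 0
  # long/short-lag ratio normalized so normal diffusion gives ~1
  cr <- (m5$msd_um2[5] / m5$msd_um2[1]) * (m5$lag_s[1] / m5$lag_s[5])
  category <- if (a >= 1.5 || straightness >= 0.6) {
    "directed"
  } else if (a < 0.3 || cr < 0.3) {
    "confined"
  } else if (a < 0.85) {
    "subdiffusion"
  } else {
    "normal diffusion"
  }
  tibble(category = category, alpha = a, d_fit_um2_s = d_fit,
         straightness = straightness, confinement_ratio = cr, flagged = FALSE)
}

#' Classify every track in a track table
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @inheritParams compute_msd
#' @return Tibble with one row per track: `track_id`, the [classify_track()]
#'   columns and `duration_frames`.
#' @export
classify_tracks <- function(tracks, frame_rate_hz = 10,
                            max_lag_fraction = 0.25) {
  purrr::map_dfr(split(tracks, tracks$track_id), function(tr) {
    cl <- classify_track(compute_msd(tr, frame_rate_hz, max_lag_fraction), tr)
    cl$track_id <- tr$track_id[1]
    cl$duration_frames <- nrow(tr)
    cl
  }) |> dplyr::relocate("track_id")
}

#' Cluster diameter from a 2D Gaussian fit
#'
#' Least-squares fit of an elliptical 2D Gaussian (amplitude, centroid,
#' sigma_x, sigma_y, background) to an image patch containing one dominant
#' spot. The diameter is `2 * mean(sigma_x, sigma_y)` in um.
#'
#' @param patch Numeric matrix around one spot (rows = y, cols = x).
#' @param pixel_size_um Pixel size (um).
#' @return One-row tibble: `x_um`, `y_um`, `sigma_x_um`, `sigma_y_um`,
#'   `diameter_um`, `amplitude`, `background`, `rss`, `converged`.
#' @export
cluster_diameter <- function(patch, pixel_size_um = 0.11) {
  ny <- nrow(patch); nx <- ncol(patch)
  xs <- rep(seq_len(nx), each = ny)
  ys <- rep(seq_len(ny), times = nx)
  z <- as.numeric(patch)
  bg0 <- median(z)
  a0 <- max(z) - bg0
  # moment initialisation on pixels clearly above background
  w <- pmax(z - bg0 - 2 * mad(z), 0)
  if (sum(w) == 0) w <- pmax(z - bg0, 0)
  cx0 <- sum(xs * w) / sum(w)
  cy0 <- sum(ys * w) / sum(w)
  s0 <- max(0.8, sqrt(sum(w * ((xs - cx0)^2 + (ys - cy0)^2)) / (2 * sum(w))))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + a * exp(-((xs - cx)^2 / (2 * sx^2) + (ys - cy)^2 / (2 * sy^2))),
      start = list(bg = bg0, a = a0, cx = cx0, cy = cy0, sx = s0, sy = s0),
      lower = c(-Inf, 0, 1, 1, 0.2, 0.2),
      upper = c(Inf, Inf, nx, ny, nx, ny),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(x_um = NA_real_, y_um = NA_real_, sigma_x_um = NA_real_,
                  sigma_y_um = NA_real_, diameter_um = NA_real_,
                  amplitude = NA_real_, background = NA_real_,
                  rss = NA_real_, converged = FALSE))
  }
  cf <- coef(fit)
  sx_um <- unname(cf["sx"]) * pixel_size_um
  sy_um <- unname(cf["sy"]) * pixel_size_um
  tibble(x_um = (unname(cf["cx"]) - 1) * pixel_size_um,
         y_um = (unname(cf["cy"]) - 1) * pixel_size_um,
         sigma_x_um = sx_um, sigma_y_um = sy_um,
         diameter_um = sx_um + sy_um,
         amplitude = unname(cf["a"]), background = unname(cf["bg"]),
         rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Cluster density on the first frame
#'
#' @param spots Tibble of first-frame detections (or an integer count).
#' @param cell_area_um2 Manually determined cell area (um^2), > 0.
#' @return Density in spots per um^2.
#' @export
cluster_density <- function(spots, cell_area_um2) {
  if (cell_area_um2 <= 0) abort("`cell_area_um2` must be > 0.")
  n <- if (is.data.frame(spots)) nrow(spots) else as.numeric(spots)
  n / cell_area_um2
}
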