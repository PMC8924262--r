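# Synthetic TIRF movies of diffusing channel clusters.
#
# Trajectories follow one of four motion regimes -- normal diffusion,
# subdiffusion (fractional-Gaussian-noise increments), confined motion
# (Brownian steps reflected in a disc) and directed motion (Brownian plus
# constant drift). Each spot is rendered per frame as an isotropic 2D
# Gaussian of width `psf_sigma_um` on a noisy background, and the ground
# truth trajectory table is returned with the pixel data.

#' Motion model for a tracked cluster
#'
#' @param category One of `"diffusion"`, `"subdiffusion"`, `"confined"`,
#'   `"directed"`.
#' @param d_um2_s Diffusion coefficient D (um^2/s).
#' @param alpha Anomalous exponent for subdiffusion (0 < alpha < 1): the
#'   per-axis MSD grows as `2 D t^alpha`.
#' @param corral_radius_um Radius of the reflecting disc (confined motion).
#' @param drift_um_s Drift speed (directed motion), along a random direction.
#' @return A list of class `pq_motion_model`.
#' @export
motion_model <- function(category = c("diffusion", "subdiffusion",
                                      "confined", "directed"),
                         d_um2_s = 0.05, alpha = NULL,
                         corral_radius_um = NULL, drift_um_s = NULL) {
  category <- match.arg(category)
  if (d_um2_s < 0) abort("`d_um2_s` must be >= 0.")
  if (category == "subdiffusion") {
    if (is.null(alpha)) alpha <- 0.5
    if (alpha <= 0 || alpha >= 1) abort("subdiffusion needs 0 < alpha < 1.")
  }
  if (category == "confined") {
    if (is.null(corral_radius_um)) corral_radius_um <- 0.2
    if (corral_radius_um <= 0) abort("`corral_radius_um` must be > 0.")
  }
  if (category == "directed") {
    if (is.null(drift_um_s)) drift_um_s <- 0.5
    if (drift_um_s < 0) abort("`drift_um_s` must be >= 0.")
  }
  structure(list(category = category, d_um2_s = d_um2_s, alpha = alpha,
                 corral_radius_um = corral_radius_um,
                 drift_um_s = drift_um_s),
            class = "pq_motion_model")
}

# cache of fGn Cholesky factors keyed by "n|H"
.fgn_cache <- new.env(parent = emptyenv())

# fractional Gaussian noise of unit variance, Hurst H, length n
fgn <- function(n, H) {
  key <- paste(n, signif(H, 10), sep = "|")
  L <- .fgn_cache[[key]]
  if (is.null(L)) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j))
    cov <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
    L <- t(chol(cov))
    .fgn_cache[[key]] <- L
  }
  as.numeric(L %*% rnorm(n))
}

#' Simulate one ground-truth trajectory
#'
#' @param model A [motion_model()].
#' @param n_frames Number of frames (>= 2).
#' @param dt_s Frame interval (s).
#' @param x0_um,y0_um Initial position (um).
#' @return Tibble with columns `frame`, `x_um`, `y_um`.
#' @export
simulate_trajectory <- function(model, n_frames, dt_s, x0_um = 0, y0_um = 0) {
  stopifnot(inherits(model, "pq_motion_model"), n_frames >= 2)
  n <- n_frames - 1L
  D <- model$d_um2_s
  pos <- switch(
    model$category,
    diffusion = {
      sdd <- sqrt(2 * D * dt_s)
      cbind(cumsum(c(0, rnorm(n, 0, sdd))), cumsum(c(0, rnorm(n, 0, sdd))))
    },
    subdiffusion = {
      # per-axis MSD(t) = 2 D t^alpha: fBm with Hurst H = alpha/2, scaled
      H <- model$alpha / 2
      scale <- sqrt(2 * D * dt_s^model$alpha)
      cbind(c(0, scale * cumsum(fgn(n, H))),
            c(0, scale * cumsum(fgn(n, H))))
    },
    confined = {
      sdd <- sqrt(2 * D * dt_s)
      R <- model$corral_radius_um
      x <- numeric(n_frames); y <- numeric(n_frames)
      for (k in seq_len(n)) {
        px <- x[k] + rnorm(1, 0, sdd)
        py <- y[k] + rnorm(1, 0, sdd)
        r <- sqrt(px^2 + py^2)
        if (r > R) {       # reflect radially back into the disc
          rr <- max(1e-12, 2 * R - r)
          px <- px * rr / r; py <- py * rr / r
          r2 <- sqrt(px^2 + py^2)
          if (r2 > R) { px <- px * R / r2; py <- py * R / r2 }
        }
        x[k + 1] <- px; y[k + 1] <- py
      }
      cbind(x, y)
    },
    directed = {
      sdd <- sqrt(2 * D * dt_s)
      theta <- runif(1, 0, 2 * pi)
      v <- model$drift_um_s
      tt <- (seq_len(n_frames) - 1) * dt_s
      cbind(v * cos(theta) * tt + cumsum(c(0, rnorm(n, 0, sdd))),
            v * sin(theta) * tt + cumsum(c(0, rnorm(n, 0, sdd))))
    })
  tibble(frame = seq_len(n_frames),
         x_um = pos[, 1] + x0_um, y_um = pos[, 2] + y0_um)
}

#' TIRF movie configuration
#'
#' Defaults emulate the live-imaging conditions: ~10 Hz frame rate and a
#' final pixel size of 0.11 um.
#'
#' @param frame_rate_hz Frames per second.
#' @param n_frames Number of frames (>= 2).
#' @param pixel_size_um Pixel size (um).
#' @param frame_shape Image height/width in pixels, `c(ny, nx)`.
#' @param psf_sigma_um Gaussian PSF standard deviation (um).
#' @param spot_amplitude,background Intensity units.
#' @param noise_sd Gaussian photon-noise SD (intensity units).
#' @return A list of class `pq_tirf_config`.
#' @export
tirf_config <- function(frame_rate_hz = 10, n_frames = 100,
                        pixel_size_um = 0.11, frame_shape = c(64, 64),
                        psf_sigma_um = 0.15, spot_amplitude = 400,
                        background = 100, noise_sd = 10) {
  check_finite(frame_rate_hz = frame_rate_hz, n_frames = n_frames,
               pixel_size_um = pixel_size_um, frame_shape = frame_shape,
               psf_sigma_um = psf_sigma_um, spot_amplitude = spot_amplitude,
               background = background, noise_sd = noise_sd)
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  if (psf_sigma_um <= 0) abort("`psf_sigma_um` must be > 0.")
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  structure(list(frame_rate_hz = frame_rate_hz, n_frames = as.integer(n_frames),
                 pixel_size_um = pixel_size_um,
                 frame_shape = as.integer(frame_shape),
                 psf_sigma_um = psf_sigma_um, spot_amplitude = spot_amplitude,
                 background = background, noise_sd = noise_sd),
            class = "pq_tirf_config")
}

# add one Gaussian spot to a frame (in place value-return); coordinates in
# um, origin at the top-left pixel center, x rightward, y downward
render_spot <- function(frame, x_um, y_um, cfg) {
  px <- cfg$pixel_size_um
  sx <- cfg$psf_sigma_um / px
  cx <- x_um / px + 1      # pixel coordinates, 1-based centers
  cy <- y_um / px + 1
  r <- ceiling(4 * sx)
  xs <- max(1, floor(cx - r)):min(ncol(frame), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(nrow(frame), ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(frame)
  gx <- exp(-((xs - cx)^2) / (2 * sx^2))
  gy <- exp(-((ys - cy)^2) / (2 * sx^2))
  frame[ys, xs] <- frame[ys, xs] + cfg$spot_amplitude * outer(gy, gx)
  frame
}

#' Simulate a TIRF movie with ground-truth tracks
#'
#' @param cfg A [tirf_config()].
#' @param motions List of motion specs, each a list with elements `model` (a
#'   [motion_model()]) and `x0_um`, `y0_um` (initial position, inside the
#'   frame).
#' @param seed Integer seed for bit-reproducibility.
#' @return A list of class `pq_tirf_movie`: `frames` (array ny x nx x
#'   n_frames), `truth` (tibble `track_id`, `frame`, `x_um`, `y_um`,
#'   `category`), and `cfg`.
#' @export
simulate_tirf_movie <- function(cfg, motions = list(), seed = NULL) {
  stopifnot(inherits(cfg, "pq_tirf_config"))
  local_seed(seed)
  ny <- cfg$frame_shape[1]; nx <- cfg$frame_shape[2]
  wx <- (nx - 1) * cfg$pixel_size_um
  wy <- (ny - 1) * cfg$pixel_size_um
  dt <- 1 / cfg$frame_rate_hz

  truth <- purrr::imap_dfr(motions, function(m, i) {
    x0 <- m$x0_um %||% (wx / 2)
    y0 <- m$y0_um %||% (wy / 2)
    if (x0 < 0 || x0 > wx || y0 < 0 || y0 > wy) {
      abort(sprintf("initial position of spot %d lies outside the frame.", i))
    }
    tr <- simulate_trajectory(m$model, cfg$n_frames, dt, x0, y0)
    tr$track_id <- i
    tr$category <- m$model$category
    tr
  })

  frames <- array(cfg$background, dim = c(ny, nx, cfg$n_frames))
  if (nrow(truth)) {
    for (f in seq_len(cfg$n_frames)) {
      rows <- truth[truth$frame == f, ]
      fr <- frames[, , f]
      for (k in seq_len(nrow(rows))) {
        fr <- render_spot(fr, rows$x_um[k], rows$y_um[k], cfg)
      }
      frames[, , f] <- fr
    }
  }
  if (cfg$noise_sd > 0) {
    frames <- frames + array(rnorm(length(frames), 0, cfg$noise_sd), dim = dim(frames))
  }
  truth <- if (nrow(truth)) {
    dplyr::select(truth, "track_id", "frame", "x_um", "y_um", "category")
  } else {
    tibble(track_id = integer(), frame = integer(), x_um = numeric(),
           y_um = numeric(), category = character())
  }
  structure(list(frames = frames, truth = truth, cfg = cfg),
            class = "pq_tirf_movie")
}
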