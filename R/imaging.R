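#' Imaging configuration for the synthetic stack renderer
#'
#' Parameters of the fluorescence-microscopy emulation: a single
#' fluorescently stained molecule appears as one diffuse elliptical
#' Gaussian blob whose major-axis extent tracks the instantaneous
#' long-axis length, imaged through a Gaussian PSF onto a pixel grid with
#' Poisson shot noise and Gaussian read noise (16-bit camera counts).
#'
#' `peak_photons` is the expected peak signal count when the molecule is
#' at the reference length of 3 um; per-frame amplitudes are rescaled so
#' the total expected photon count per frame is independent of the
#' instantaneous length (the dye load does not change as the coil
#' elongates).
#'
#' `sigma_scale` maps the long-axis length R to the blob's major-axis
#' Gaussian width, `sigma_major = R / sigma_scale`. Its default is
#' calibrated once so that rendering a noiseless frame and extracting the
#' length with the default settings (Otsu threshold, maximum Feret
#' diameter) returns R: the renderer and extractor share one
#' operationalization of "long-axis length".
#'
#' @param pixel_size_um Pixel size in um/px (> 0, default 0.1).
#' @param frame_shape Frame size in px, `c(ny, nx)` (default 128 x 128).
#' @param psf_sigma_um PSF Gaussian sigma in um (>= 0, default 0.15).
#' @param peak_photons Expected peak signal count at the 3 um reference
#'   length (>= 0, default 150).
#' @param background_photons Expected background count per pixel
#'   (>= 0, default 20).
#' @param read_noise_sd Read-noise standard deviation in counts
#'   (>= 0, default 2).
#' @param aspect_ratio Short-axis / long-axis width of the blob,
#'   in (0, 1] (default 0.35).
#' @param sigma_scale Length-to-sigma mapping (see Details).
#' @param fluctuate_orientation If `TRUE` (default) the blob orientation
#'   is redrawn uniformly every frame; `FALSE` freezes it along x.
#' @param noise If `FALSE`, render noiseless expected counts (rounded).
#' @param seed Integer seed for orientation and noise.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 0.1, frame_shape = c(128, 128),
                           psf_sigma_um = 0.15, peak_photons = 150,
                           background_photons = 20, read_noise_sd = 2,
                           aspect_ratio = 0.35, sigma_scale = NULL,
                           fluctuate_orientation = TRUE, noise = TRUE,
                           seed = 1) {
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  if (length(frame_shape) != 2 || any(frame_shape < 16)) {
    abort("`frame_shape` must be two pixel counts >= 16.")
  }
  if (psf_sigma_um < 0) abort("`psf_sigma_um` must be >= 0.")
  if (peak_photons < 0 || background_photons < 0 || read_noise_sd < 0) {
    abort("photon counts and read noise must be >= 0.")
  }
  if (aspect_ratio <= 0 || aspect_ratio > 1) abort("`aspect_ratio` must be in (0, 1].")
  if (is.null(sigma_scale)) sigma_scale <- .default_sigma_scale
  if (sigma_scale <= 0) abort("`sigma_scale` must be positive.")
  structure(
    list(
      pixel_size_um = pixel_size_um, frame_shape = as.integer(frame_shape),
      psf_sigma_um = psf_sigma_um, peak_photons = peak_photons,
      background_photons = background_photons, read_noise_sd = read_noise_sd,
      aspect_ratio = aspect_ratio, sigma_scale = sigma_scale,
      fluctuate_orientation = isTRUE(fluctuate_orientation),
      noise = isTRUE(noise), seed = as.integer(seed)
    ),
    class = "imaging_config"
  )
}

# Calibrated so that noiseless render + default extraction (Otsu,
# max-Feret) is the identity on R to within ~1 px over 1.5-4.5 um at the
# default imaging configuration.
.default_sigma_scale <- 3.2

.ref_length_um <- 3

#' Render a long-axis-length series into a synthetic image stack
#'
#' One elliptical Gaussian blob per frame, centred mid-frame, with
#' major-axis extent tracking `R_um` (via `sigma_scale`, see
#' [imaging_config()]), optional per-frame random in-plane orientation,
#' analytic Gaussian-PSF blurring, and camera noise (Poisson shot noise
#' on signal + background, then Gaussian read noise), quantized to 16-bit
#' counts.
#'
#' @param series A single-molecule series tibble (`time_s`, `R_um`).
#' @param config An [imaging_config()].
#' @return An object of class `frame_stack`: a list with `frames` (list
#'   of integer count matrices), `pixel_size_um`, `frame_interval_s`.
#' @examples
#' p <- oscillator_params()
#' s <- simulate_gp(p, sampling_spec(n_frames = 5, n_molecules = 1, seed = 1))
#' st <- render_stack(s, imaging_config(noise = FALSE))
#' @export
render_stack <- function(series, config = imaging_config()) {
  stopifnot(is.data.frame(series), inherits(config, "imaging_config"))
  if (!all(c("time_s", "R_um") %in% names(series))) {
    abort("`series` needs columns `time_s` and `R_um`.")
  }
  if ("molecule_id" %in% names(series) &&
      length(unique(series$molecule_id)) > 1L) {
    abort("render one molecule per stack.")
  }
  ny <- config$frame_shape[1]; nx <- config$frame_shape[2]
  px <- config$pixel_size_um
  half_extent <- min(nx, ny) * px / 2
  margin_bad <- which(series$R_um / 2 + 3 * config$psf_sigma_um > half_extent)
  if (length(margin_bad) > 0) {
    abort(sprintf(
      "blob exceeds the frame at frame %d (R = %.3g um does not fit in a %g um half-extent with a 3-sigma PSF margin).",
      margin_bad[1], series$R_um[margin_bad[1]], half_extent
    ))
  }
  # pixel-centre coordinates (um), origin mid-frame
  xs <- (seq_len(nx) - (nx + 1) / 2) * px
  ys <- (seq_len(ny) - (ny + 1) / 2) * px
  X <- matrix(rep(xs, each = ny), nrow = ny)
  Y <- matrix(rep(ys, times = nx), nrow = ny)

  # total expected signal photons, set by the peak at the reference length
  s_maj0 <- .ref_length_um / config$sigma_scale
  su0 <- sqrt(s_maj0^2 + config$psf_sigma_um^2)
  sv0 <- sqrt((config$aspect_ratio * s_maj0)^2 + config$psf_sigma_um^2)
  n_total <- config$peak_photons * 2 * pi * su0 * sv0 / px^2

  set.seed(config$seed)
  n_frames <- nrow(series)
  thetas <- if (config$fluctuate_orientation) runif(n_frames, 0, 2 * pi) else rep(0, n_frames)
  npx <- nx * ny
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    s_maj <- series$R_um[f] / config$sigma_scale
    su <- sqrt(s_maj^2 + config$psf_sigma_um^2)
    sv <- sqrt((config$aspect_ratio * s_maj)^2 + config$psf_sigma_um^2)
    amp <- n_total * px^2 / (2 * pi * su * sv)
    th <- thetas[f]
    U <- X * cos(th) + Y * sin(th)
    V <- -X * sin(th) + Y * cos(th)
    expected <- amp * exp(-0.5 * ((U / su)^2 + (V / sv)^2)) + config$background_photons
    counts <- if (config$noise) {
      rpois(npx, expected) + round(rnorm(npx, 0, config$read_noise_sd))
    } else {
      round(expected)
    }
    counts <- pmin(pmax(counts, 0), 65535)
    frames[[f]] <- matrix(as.integer(counts), nrow = ny)
  }
  structure(
    list(
      frames = frames,
      pixel_size_um = px,
      frame_interval_s = if (n_frames > 1) median(diff(series$time_s)) else NA_real_,
      seed = config$seed
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.3g um/px, %.4g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Write / read an image stack as multi-page 16-bit TIFF with JSON sidecar
#'
#' The TIFF stores one grayscale 16-bit page per frame; calibration
#' (pixel size, frame interval) and any ground-truth metadata go to a
#' `<path>.json` sidecar. `read_stack(write_stack(x))` reproduces the
#' counts bit-exactly. Reading refuses a stack without its sidecar, since
#' an uncalibrated stack cannot be converted to physical lengths.
#'
#' @param stack A `frame_stack`.
#' @param path TIFF output path.
#' @param ground_truth Optional list recorded verbatim in the sidecar
#'   (e.g. simulation parameters).
#' @return `write_stack()`: `path`, invisibly. `read_stack()`: a
#'   `frame_stack` with sidecar metadata in `$meta`.
#' @export
write_stack <- function(stack, path, ground_truth = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(
    lapply(stack$frames, function(m) m / 65535),
    path, bits.per.sample = 16, compression = "none"
  )
  meta <- list(
    format = "dnafluct-stack-v1",
    pixel_size_um = stack$pixel_size_um,
    frame_interval_s = stack$frame_interval_s,
    n_frames = length(stack$frames),
    seed = stack$seed
  )
  if (!is.null(ground_truth)) meta$ground_truth <- ground_truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0(
      "no sidecar found at ", sidecar,
      ": the pixel size and frame interval are required to calibrate the stack."
    ))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um) || !is.finite(meta$pixel_size_um)) {
    abort("sidecar lacks a finite `pixel_size_um`.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(m) {
    if (length(dim(m)) != 2) abort("expected single-channel grayscale pages.")
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  })
  d1 <- dim(frames[[1]])
  if (!all(vapply(frames, function(m) identical(dim(m), d1), logical(1)))) {
    abort("pages of the stack differ in shape.")
  }
  structure(
    list(
      frames = frames,
      pixel_size_um = meta$pixel_size_um,
      frame_interval_s = meta$frame_interval_s,
      seed = meta$seed,
      meta = meta
    ),
    class = "frame_stack"
  )
}
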