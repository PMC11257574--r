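#' Calibrated multichannel z-stack
#'
#' @param intensities numeric array `[y, x, z, channel]`, non-negative.
#' @param pixel_size lateral calibration, micrometres per pixel.
#' @param z_step axial spacing between z-sections, micrometres.
#' @param channels character vector of channel labels.
#' @return An `image_stack` object.
#' @export
image_stack <- function(intensities, pixel_size, z_step,
                        channels = NULL) {
  if (length(dim(intensities)) == 2L) {
    dim(intensities) <- c(dim(intensities), 1L, 1L)
  }
  if (length(dim(intensities)) == 3L) {
    dim(intensities) <- c(dim(intensities), 1L)
  }
  if (length(dim(intensities)) != 4L) {
    stop("intensities must be a [y, x, z, channel] array")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be > 0")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(intensities)[4]))
  if (length(channels) != dim(intensities)[4]) {
    stop("channel labels do not match the channel dimension")
  }
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 z_step = z_step, channels = channels),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat("image_stack ", d[2], " x ", d[1], " px, ", d[3], " z-sections, ",
      d[4], " channel(s) [", paste(x$channels, collapse = ", "), "]\n",
      "  pixel size ", x$pixel_size, " um, z step ", x$z_step, " um\n",
      sep = "")
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus sidecar
#'
#' Pages are ordered z-fastest within channel. Because baseline TIFF
#' clamps values outside [0, 1], intensities are stored scaled by their
#' maximum into 32-bit float pages; the scale and the calibration
#' (pixel size, z step, channel labels) live in a JSON sidecar at
#' `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$intensities)
  scale <- max(stack$intensities, 1e-12)
  pages <- list()
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[length(pages) + 1L]] <- stack$intensities[, , z, ch] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, z_step = stack$z_step,
         channels = stack$channels, ny = d[1], nx = d[2], nz = d[3],
         nchannel = d[4], scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(meta$ny, meta$nx, meta$nz, meta$nchannel))
  k <- 0L
  for (ch in seq_len(meta$nchannel)) for (z in seq_len(meta$nz)) {
    k <- k + 1L
    arr[, , z, ch] <- pages[[k]] * meta$scale
  }
  image_stack(arr, meta$pixel_size, meta$z_step, meta$channels)
}

#' Project a stack along z
#'
#' @param stack an [image_stack()].
#' @param channel channel label or index.
#' @param mode `"sum"` (for intensity quantification) or `"max"` (for
#'   display-style projections).
#' @param z_range integer vector of z-section indices (default: all).
#' @return 2-D numeric matrix `[y, x]`.
#' @export
project <- function(stack, channel = 1L, mode = c("sum", "max"),
                    z_range = NULL) {
  mode <- match.arg(mode)
  if (is.character(channel)) channel <- match(channel, stack$channels)
  if (is.na(channel) || channel < 1 || channel > dim(stack$intensities)[4]) {
    stop("unknown channel")
  }
  if (is.null(z_range)) z_range <- seq_len(dim(stack$intensities)[3])
  if (length(z_range) == 0L) stop("empty z_range")
  sub <- stack$intensities[, , z_range, channel, drop = FALSE]
  apply(sub, c(1L, 2L), if (mode == "sum") sum else max)
}

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with the origin at the top-left
#' corner, x rightwards and y downwards; bounds are half-open, so a ROI
#' at `x0 = 0` with `width = 3` covers pixel columns 0, 1, 2.
#'
#' @param x0,y0 top-left corner (pixels, 0-based).
#' @param width,height extent in pixels (>= 1).
#' @return A `rect_roi` object with an `area` field (pixels).
#' @export
rect_roi <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop("ROI must cover at least one pixel")
  if (x0 < 0 || y0 < 0) stop("ROI origin must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 area = as.integer(width) * as.integer(height)),
            class = "rect_roi")
}

roi_pixels <- function(image, roi) {
  if (roi$y0 + roi$height > nrow(image) || roi$x0 + roi$width > ncol(image)) {
    stop("ROI exceeds image bounds")
  }
  image[roi$y0 + seq_len(roi$height), roi$x0 + seq_len(roi$width),
        drop = FALSE]
}

roi_contains <- function(outer, inner) {
  inner$x0 >= outer$x0 && inner$y0 >= outer$y0 &&
    inner$x0 + inner$width <= outer$x0 + outer$width &&
    inner$y0 + inner$height <= outer$y0 + outer$height
}

#' Background-subtracted total ROI intensity
#'
#' The division-site signal ROI1 sits inside a larger ROI2 (about twice
#' its area); the ROI2-minus-ROI1 annulus estimates the local
#' per-pixel cytoplasmic background, which is scaled to ROI1's area and
#' subtracted:
#' `corrected = I1 - A1 * (I2 - I1) / (A2 - A1)`.
#'
#' @param image 2-D matrix (typically a sum projection).
#' @param roi1 signal [rect_roi()].
#' @param roi2 background [rect_roi()] containing `roi1`, strictly
#'   larger in area.
#' @return corrected total intensity (numeric scalar).
#' @export
roi_background_subtracted_intensity <- function(image, roi1, roi2) {
  if (!roi_contains(roi2, roi1)) stop("roi1 must lie inside roi2")
  if (roi2$area <= roi1$area) stop("roi2 must be larger than roi1")
  i1 <- sum(roi_pixels(image, roi1))
  i2 <- sum(roi_pixels(image, roi2))
  i1 - roi1$area * (i2 - i1) / (roi2$area - roi1$area)
}

#' Width-averaged intensity profile
#'
#' @param positions positions in micrometres (strictly increasing).
#' @param values mean intensity per position.
#' @param width_pixels averaging width used to produce the profile.
#' @param alignment list with `strategy` and `origin` (um).
#' @return A `line_profile` object.
#' @export
line_profile <- function(positions, values, width_pixels = 1L,
                         alignment = list(strategy = "none", origin = 0)) {
  if (length(positions) != length(values)) {
    stop("positions and values must have equal length")
  }
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 width_pixels = as.integer(width_pixels),
                 alignment = alignment),
            class = "line_profile")
}

#' Axial colocalization profile across the division plane
#'
#' Reproduces the 1.5 um x 3.5 um rectangular-ROI measurement: within
#' the ROI, the mean intensity of all pixels along the short axis is
#' taken at each position along the long axis.
#'
#' @param image 2-D matrix (typically a max projection).
#' @param roi a [rect_roi()] across the division plane.
#' @param pixel_size micrometres per pixel.
#' @param long_axis `"x"` (default) or `"y"`: the axis along which the
#'   profile runs.
#' @return A [line_profile()] with positions in micrometres (pixel
#'   centres, absolute image coordinates).
#' @export
axial_colocalization_profile <- function(image, roi, pixel_size,
                                         long_axis = c("x", "y")) {
  long_axis <- match.arg(long_axis)
  px <- roi_pixels(image, roi)
  if (long_axis == "x") {
    values <- colMeans(px)
    positions <- (roi$x0 + seq_len(roi$width) - 0.5) * pixel_size
  } else {
    values <- rowMeans(px)
    positions <- (roi$y0 + seq_len(roi$height) - 0.5) * pixel_size
  }
  line_profile(positions, values, width_pixels = if (long_axis == "x")
    roi$height else roi$width)
}

# Bilinear interpolation at 0-based pixel-centre coordinates.
bilinear <- function(image, x, y) {
  nx <- ncol(image); ny <- nrow(image)
  x <- pmin(pmax(x, 0), nx - 1); y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]; i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]; i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Line scan across the division plane
#'
#' Mean intensity along a line of a given pixel width (default 3, to
#' damp single-plane signal variation), sampled at unit-pixel spacing.
#' Axis-aligned lines at integer coordinates reduce to exact pixel
#' means; oblique lines are sampled by bilinear interpolation.
#'
#' @param image 2-D matrix (a middle focal plane).
#' @param p0,p1 numeric `c(x, y)` endpoints, 0-based pixel coordinates.
#' @param width_pixels averaging width perpendicular to the line
#'   (odd integer, default 3).
#' @param pixel_size micrometres per pixel (default 1: positions in
#'   pixels).
#' @return A [line_profile()]; positions are distances from `p0`.
#' @export
line_scan <- function(image, p0, p1, width_pixels = 3L, pixel_size = 1) {
  dvec <- p1 - p0
  len <- sqrt(sum(dvec^2))
  if (len == 0) stop("zero-length line")
  if (width_pixels < 1L || width_pixels %% 2L == 0L) {
    stop("width_pixels must be a positive odd integer")
  }
  u <- dvec / len
  nvec <- c(-u[2], u[1])
  t <- seq(0, floor(len))
  offsets <- seq_len(width_pixels) - (width_pixels + 1) / 2
  vals <- rowMeans(vapply(offsets, function(o) {
    xs <- p0[1] + t * u[1] + o * nvec[1]
    ys <- p0[2] + t * u[2] + o * nvec[2]
    if (any(xs < 0 | xs > ncol(image) - 1 | ys < 0 | ys > nrow(image) - 1)) {
      stop("line (with width) exceeds image bounds")
    }
    bilinear(image, xs, ys)
  }, numeric(length(t))))
  line_profile(t * pixel_size, vals, width_pixels = width_pixels)
}

# Centered 3-point smoothing with shrink-to-available edge windows;
# used only for peak detection during alignment.
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[1] <- mean(v[1:2]); out[n] <- mean(v[(n - 1):n])
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

peak_position <- function(profile) {
  s <- smooth3(profile$values)
  profile$positions[which.max(s)]
}

two_peak_positions <- function(profile, min_separation = 3L) {
  s <- smooth3(profile$values)
  n <- length(s)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) s[i] >= s[i - 1L] else TRUE
    right <- if (i < n) s[i] >= s[i + 1L] else TRUE
    left && right
  }, logical(1))
  cand <- which(is_max)
  cand <- cand[order(-s[cand])]
  if (length(cand) >= 1L) {
    first <- cand[1L]
    rest <- cand[abs(cand - first) >= min_separation]
    if (length(rest) >= 1L) {
      return(sort(profile$positions[c(first, rest[1L])]))
    }
  }
  stop("profile has fewer than two separated local maxima")
}

#' Align intensity profiles
#'
#' Shifts each profile's positions so its alignment origin sits at 0;
#' values are untouched. Strategies mirror the measurement designs:
#' `reference_peak` (align everything on the peak of one reference
#' channel, e.g. a contractile-ring marker), `brightest_pixel` (each
#' profile on its own brightest position), `two_peak_midpoint` (on the
#' midpoint of the two highest separated local maxima, for symmetric
#' double-peaked rim signals), and `external_center` (origins supplied
#' externally, e.g. the septum centre read from DIC images). Peak
#' detection uses a 3-point smoothed profile; `two_peak_midpoint`
#' requires two local maxima at least 3 positions apart.
#'
#' @param profiles list of [line_profile()] objects.
#' @param strategy one of `"reference_peak"`, `"brightest_pixel"`,
#'   `"two_peak_midpoint"`, `"external_center"`.
#' @param reference for `reference_peak`: a [line_profile()]; for
#'   `external_center`: numeric origins (um), recycled.
#' @return list of aligned profiles.
#' @export
align_profiles <- function(profiles,
                           strategy = c("reference_peak", "brightest_pixel",
                                        "two_peak_midpoint",
                                        "external_center"),
                           reference = NULL) {
  strategy <- match.arg(strategy)
  origins <- switch(
    strategy,
    reference_peak = {
      if (is.null(reference)) stop("reference_peak needs a reference profile")
      rep(peak_position(reference), length(profiles))
    },
    brightest_pixel = vapply(profiles, peak_position, numeric(1)),
    two_peak_midpoint = vapply(profiles, function(p) {
      mean(two_peak_positions(p))
    }, numeric(1)),
    external_center = {
      if (is.null(reference)) stop("external_center needs numeric origins")
      rep_len(as.numeric(reference), length(profiles))
    }
  )
  mapply(function(p, o) {
    line_profile(p$positions - o, p$values, p$width_pixels,
                 alignment = list(strategy = strategy, origin = o))
  }, profiles, origins, SIMPLIFY = FALSE)
}

#' Rim-spread index of a division-plane profile
#'
#' Quantitative surrogate for visual "intact ring vs mislocalized"
#' scoring: on a cross-section profile spanning the full cell diameter,
#' the mean of the centre third of positions divided by the sum of the
#' centre-third mean and the mean over the two rim thirds. Near 0 for a
#' pure rim ring (no signal at the centre), towards 1 for signal
#' concentrated at the centre of the division plane.
#'
#' @param profile a [line_profile()] spanning the full cell diameter.
#' @return numeric scalar in [0, 1].
#' @export
rim_spread_index <- function(profile) {
  v <- profile$values
  if (all(v == 0)) stop("all-zero profile: rim-spread index undefined")
  p <- profile$positions
  lo <- min(p) + diff(range(p)) / 3
  hi <- min(p) + 2 * diff(range(p)) / 3
  centre <- v[p >= lo & p <= hi]
  rim <- v[p < lo | p > hi]
  if (length(centre) == 0L || length(rim) == 0L) {
    stop("profile too short to split into thirds")
  }
  mean(centre) / (mean(centre) + mean(rim))
}
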