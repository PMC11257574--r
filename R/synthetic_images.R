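# Separable Gaussian blur (kernel truncated at 3 sigma); sigma in
# pixels. Used as a crude point-spread-function stand-in.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  mat <- apply(mat, 2L, pad_conv)
  t(apply(mat, 1L, pad_conv))
}

#' Synthetic end-on division-plane image stack
#'
#' Emulates the end-on view of the division plane: a rim ring (annulus
#' at the cell radius), a centre disk (signal spread over the septum
#' interior, concentrated toward the centre of the division plane), or
#' both. Slices carry a Gaussian z-envelope centred on the middle
#' section; an optional second channel repeats the pattern displaced
#' along x by a planted offset (for colocalization-profile tests).
#' Optional Gaussian-PSF blur and Poisson shot noise.
#'
#' @param pattern `"ring"`, `"disk"` or `"ring_plus_disk"`.
#' @param cell_radius_um cell radius (default 1.8 um).
#' @param pixel_size um/pixel (default 0.1).
#' @param z_step um between sections (default 0.5).
#' @param nz number of z-sections (default 7).
#' @param peak_intensity photon-scale peak of the clean mask
#'   (default 200).
#' @param ring_thickness_um radial thickness of the rim ring
#'   (default 0.3).
#' @param disk_radius_frac disk radius as a fraction of the cell radius
#'   (default 0.6: the septum interior without the rim).
#' @param psf_sigma_um Gaussian blur sigma (0 disables; default 0.15).
#' @param margin_um field-of-view margin beyond the cell radius
#'   (default 0.7 um); widen it when a background annulus around the
#'   whole cell is needed.
#' @param poisson_noise add Poisson shot noise (default FALSE).
#' @param second_channel_offset_um if non-NULL, add a second channel
#'   with its pattern centre shifted by this many um along x.
#' @param seed RNG seed (noise only).
#' @return list with `stack` (an [image_stack()]) and `truth` (pattern
#'   geometry, centre in um, planted offset, the clean noiseless
#'   array).
#' @export
make_division_stack <- function(pattern = c("ring", "disk", "ring_plus_disk"),
                                cell_radius_um = 1.8, pixel_size = 0.1,
                                z_step = 0.5, nz = 7L,
                                peak_intensity = 200,
                                ring_thickness_um = 0.3,
                                disk_radius_frac = 0.6,
                                psf_sigma_um = 0.15,
                                margin_um = 0.7,
                                poisson_noise = FALSE,
                                second_channel_offset_um = NULL,
                                seed = 1L) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  n <- 2L * ceiling((cell_radius_um + margin_um) / pixel_size) + 1L
  centre <- (n / 2) * pixel_size   # um, image centre
  xs <- (seq_len(n) - 0.5) * pixel_size
  mask_at <- function(cx) {
    dx2 <- outer(rep(1, n), (xs - cx)^2)
    dy2 <- outer((xs - centre)^2, rep(1, n))
    r <- sqrt(dx2 + dy2)
    m <- matrix(0, n, n)
    if (pattern %in% c("ring", "ring_plus_disk")) {
      m <- m + (r >= cell_radius_um - ring_thickness_um & r <= cell_radius_um)
    }
    if (pattern %in% c("disk", "ring_plus_disk")) {
      m <- m + (r <= disk_radius_frac * cell_radius_um)
    }
    m * peak_intensity
  }
  zc <- (nz + 1) / 2
  z_env <- exp(-((seq_len(nz) - zc) / 1.5)^2)
  nch <- if (is.null(second_channel_offset_um)) 1L else 2L
  clean <- array(0, dim = c(n, n, nz, nch))
  for (ch in seq_len(nch)) {
    cx <- centre + if (ch == 2L) second_channel_offset_um else 0
    m <- mask_at(cx)
    if (psf_sigma_um > 0) m <- gaussian_blur(m, psf_sigma_um / pixel_size)
    for (z in seq_len(nz)) clean[, , z, ch] <- m * z_env[z]
  }
  noisy <- clean
  if (poisson_noise) {
    noisy[] <- stats::rpois(length(clean), lambda = clean)
  }
  list(
    stack = image_stack(noisy, pixel_size, z_step,
                        channels = paste0("ch", seq_len(nch))),
    truth = list(pattern = pattern, cell_radius_um = cell_radius_um,
                 centre_um = centre,
                 ring_thickness_um = ring_thickness_um,
                 disk_radius_um = disk_radius_frac * cell_radius_um,
                 second_channel_offset_um = second_channel_offset_um,
                 peak_intensity = peak_intensity, z_envelope = z_env,
                 clean = clean, seed = seed)
  )
}
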