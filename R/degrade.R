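#' Degradation specification for high-speed low-dosage acquisition
#'
#' Bundles the forward-model parameters: per-pulse energy fraction `f`
#' (relative to the ANSI-limit pulse energy of the ground truth),
#' per-axis undersampling factor `s`, additive detector noise SD, and the
#' seed for the noise field.
#'
#' @param f Energy fraction in (0, 1].
#' @param s Integer undersampling factor (1, 2 or 4 supported).
#' @param noise_sigma Noise standard deviation on the normalized amplitude
#'   scale (>= 0).
#' @param seed Integer seed for the noise field.
#' @return A `DegradationSpec` list.
#' @export
degradation_spec <- function(f = 0.5, s = 2L, noise_sigma = 0.05, seed = 1L) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop("energy fraction f must be in (0, 1]")
  s <- as.integer(s)
  if (!s %in% c(1L, 2L, 4L)) stop("undersample factor s must be 1, 2 or 4")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(f = f, s = s, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "DegradationSpec")
}

#' Simulate reduced per-pulse energy with detector noise
#'
#' Low per-pulse energy scales the photoacoustic amplitude linearly while
#' the detector noise floor stays fixed, so the image becomes
#' `f * image + N(0, noise_sigma^2)`, clipped back to the normalized
#' \[0, 1\] range. Deterministic for a fixed seed.
#'
#' @param image 2-D numeric matrix on the \[0, 1\] scale.
#' @param f Energy fraction in (0, 1].
#' @param noise_sigma Additive Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return Degraded matrix, same shape, clipped to \[0, 1\].
#' @export
apply_energy_scaling <- function(image, f, noise_sigma = 0, seed = 1L) {
  if (f <= 0 || f > 1) stop("energy fraction f must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  out <- f * image
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(image), 0, noise_sigma),
                        nrow(image), ncol(image))
  }
  pmin(pmax(out, 0), 1)
}

#' Spatially undersample an image by decimation
#'
#' Keeps rows and columns at indices 1, 1+s, 1+2s, ... (every s-th scan
#' position along each axis, no interpolation), emulating sparse scanning.
#' Output shape is `ceiling(dim / s)`.
#'
#' @param image 2-D numeric matrix.
#' @param s Integer factor >= 1, at most the smaller image dimension.
#' @return Decimated matrix.
#' @export
undersample <- function(image, s) {
  s <- as.integer(s)
  if (s < 1) stop("undersample factor s must be >= 1")
  if (s > min(dim(image))) stop("undersample factor exceeds image size")
  image[seq(1, nrow(image), by = s), seq(1, ncol(image), by = s), drop = FALSE]
}

#' Laser dosage reduction factor
#'
#' Undersampling by `s` per axis cuts the pulse count `s^2`-fold and each
#' remaining pulse carries a fraction `f` of the ANSI-limit energy, so the
#' total dosage drops by `s^2 / f`: 16-fold at (f = 1/4, s = 2) and 32-fold
#' at (f = 1/2, s = 4).
#'
#' @param f Energy fraction in (0, 1].
#' @param s Integer undersampling factor >= 1.
#' @return The dimensionless dosage reduction factor `s^2 / f`.
#' @export
compute_dosage_reduction <- function(f, s) {
  if (f <= 0 || f > 1) stop("energy fraction f must be in (0, 1]")
  if (s < 1) stop("undersample factor s must be >= 1")
  s^2 / f
}

#' Optical fiber delay time
#'
#' Propagation delay of a pulse through a multimode delay fiber:
#' `length * group_index / c`. A ~150 m fiber with group index 1.5 delays
#' by 750 ns, which is how a delay line separates high- and low-energy
#' pulse returns at the detector.
#'
#' @param length_m Fiber length in meters.
#' @param group_index Group refractive index (default 1.5 for silica).
#' @return Delay in seconds.
#' @export
fiber_delay <- function(length_m, group_index = 1.5) {
  if (length_m < 0) stop("fiber length must be non-negative")
  length_m * group_index / 3e8 # c = 3e8 m/s, the usual delay-sizing figure
}

#' Degrade a phantom scene into a dual-wavelength acquisition pair
#'
#' Applies [apply_energy_scaling()] then [undersample()] to both channels.
#' The two channels receive independent noise fields (seeds `seed` and
#' `seed + 1`), as two different lasers have uncorrelated detector noise.
#'
#' @param scene A `PhantomScene`.
#' @param spec A `DegradationSpec`.
#' @param provenance Optional scene identifier stored with the pair.
#' @return An `AcquisitionPair`: list with `input1` (532 nm), `input2`
#'   (560 nm), `spec`, `provenance`.
#' @export
degrade_scene <- function(scene, spec, provenance = NA_character_) {
  stopifnot(inherits(scene, "PhantomScene"), inherits(spec, "DegradationSpec"))
  in1 <- undersample(
    apply_energy_scaling(scene$gt532, spec$f, spec$noise_sigma, spec$seed),
    spec$s)
  in2 <- undersample(
    apply_energy_scaling(scene$gt560, spec$f, spec$noise_sigma, spec$seed + 1L),
    spec$s)
  structure(list(input1 = in1, input2 = in2, spec = spec,
                 provenance = provenance),
            class = "AcquisitionPair")
}
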