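#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10( max(ref) * sqrt(N) / ||ref - rec||_2 )`, i.e.
#' `20 log10( max(ref) / sqrt(MSE) )` with N the pixel count, in decibels.
#' The peak is taken from the reference image.
#'
#' @param ref Reference image matrix (max > 0).
#' @param rec Reconstructed image matrix, same shape, not identical to
#'   `ref`.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, rec) {
  if (!all(dim(ref) == dim(rec))) stop("ref and rec must have the same shape")
  peak <- max(ref)
  if (peak <= 0) stop("reference image has non-positive maximum")
  mse <- mean((ref - rec)^2)
  if (mse == 0) {
    stop(errorCondition("identical images: PSNR is infinite",
                        class = c("psnr_infinite", "error", "condition")))
  }
  20 * log10(peak / sqrt(mse))
}

#' SSIM regularization constants
#'
#' Defaults follow the usual convention for data on a \[0, L\] scale with
#' L = 1: `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, `c3 = c2 / 2`.
#'
#' @param c1,c2,c3 Non-negative constants, not all zero.
#' @return An `SSIMConstants` list.
#' @export
ssim_constants <- function(c1 = 1e-4, c2 = 9e-4, c3 = 4.5e-4) {
  if (any(c(c1, c2, c3) < 0) || all(c(c1, c2, c3) == 0)) {
    stop("SSIM constants must be non-negative and not all zero")
  }
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "SSIMConstants")
}

#' Structural similarity index (global form)
#'
#' The product of the luminance, contrast and structure terms
#' \deqn{\frac{2\mu_r\mu_c + c_1}{\mu_r^2+\mu_c^2+c_1}\cdot
#'       \frac{2\sigma_r\sigma_c + c_2}{\sigma_r^2+\sigma_c^2+c_2}\cdot
#'       \frac{\sigma_{rc} + c_3}{\sigma_r\sigma_c + c_3}}
#' computed from GLOBAL image statistics (population moments, 1/N), not a
#' sliding window; a windowed mean-of-local-SSIM variant is available via
#' `window`. With `c3 = 0` and both variances zero the structure term is
#' defined as 1.
#'
#' @param ref,rec Image matrices of identical shape.
#' @param consts An `SSIMConstants` object.
#' @param window Optional odd window size for the local (sliding, uniform
#'   window) variant; `NULL` (default) gives the canonical global form.
#' @return SSIM index (<= 1; 1 iff the images are identical when the
#'   constants are positive).
#' @export
ssim <- function(ref, rec, consts = ssim_constants(), window = NULL) {
  if (!all(dim(ref) == dim(rec))) stop("ref and rec must have the same shape")
  stopifnot(inherits(consts, "SSIMConstants"))
  if (is.null(window)) {
    return(.ssim_terms(ref, rec, consts))
  }
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  r <- (window - 1) / 2
  nr <- nrow(ref); nc <- ncol(ref)
  if (window > min(nr, nc)) stop("window larger than image")
  total <- 0; count <- 0
  for (i in seq(1 + r, nr - r)) {
    for (j in seq(1 + r, nc - r)) {
      ri <- (i - r):(i + r); ci <- (j - r):(j + r)
      total <- total + .ssim_terms(ref[ri, ci], rec[ri, ci], consts)
      count <- count + 1
    }
  }
  total / count
}

.ssim_terms <- function(ref, rec, consts) {
  n <- length(ref)
  mu_r <- mean(ref); mu_c <- mean(rec)
  var_r <- mean((ref - mu_r)^2); var_c <- mean((rec - mu_c)^2)
  sd_r <- sqrt(var_r); sd_c <- sqrt(var_c)
  cov_rc <- mean((ref - mu_r) * (rec - mu_c))
  lum <- (2 * mu_r * mu_c + consts$c1) / (mu_r^2 + mu_c^2 + consts$c1)
  con <- (2 * sd_r * sd_c + consts$c2) / (var_r + var_c + consts$c2)
  str_den <- sd_r * sd_c + consts$c3
  str <- if (str_den == 0) 1 else (cov_rc + consts$c3) / str_den
  lum * con * str
}

#' Signal-to-noise ratio along a line profile
#'
#' Interpolates the image intensity along a straight line (bilinear, about
#' two samples per pixel of line length) and divides the profile maximum by
#' the standard deviation of a vessel-free background box.
#'
#' @param image 2-D numeric matrix.
#' @param line Numeric `c(r0, c0, r1, c1)`: line endpoints in pixel
#'   coordinates (1-based), inside the image.
#' @param background_region Integer `c(r0, r1, c0, c1)`: inclusive box used
#'   as background, disjoint from the line.
#' @return Dimensionless SNR (profile peak / background SD).
#' @export
line_profile_snr <- function(image, line, background_region) {
  stopifnot(length(line) == 4, length(background_region) == 4)
  if (any(line[c(1, 3)] < 1) || any(line[c(1, 3)] > nrow(image)) ||
      any(line[c(2, 4)] < 1) || any(line[c(2, 4)] > ncol(image))) {
    stop("line endpoints must lie inside the image")
  }
  b <- as.integer(background_region)
  bg <- image[b[1]:b[2], b[3]:b[4]]
  bg_sd <- stats::sd(as.numeric(bg))
  if (!is.finite(bg_sd) || bg_sd == 0) {
    stop(errorCondition("background SD is zero: SNR is infinite",
                        class = c("snr_infinite", "error", "condition")))
  }
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  # half-pixel sampling inclusive of both endpoints, so profiles along
  # grid-aligned lines hit pixel centers exactly
  nsamp <- max(3L, 2L * ceiling(len) + 1L)
  t <- seq(0, 1, length.out = nsamp)
  rr <- line[1] + t * (line[3] - line[1])
  cc <- line[2] + t * (line[4] - line[2])
  prof <- .bilinear(image, rr, cc)
  max(prof) / bg_sd
}

.bilinear <- function(image, rr, cc) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- pmin(pmax(floor(rr), 1), nr - 1); c0 <- pmin(pmax(floor(cc), 1), nc - 1)
  fr <- rr - r0; fc <- cc - c0
  i00 <- image[cbind(r0, c0)]; i10 <- image[cbind(r0 + 1, c0)]
  i01 <- image[cbind(r0, c0 + 1)]; i11 <- image[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

#' Pixelwise absolute error map
#'
#' The residuals map `|ref - rec|`, the standard visualization of
#' reconstruction distortion.
#'
#' @param ref,rec Image matrices of identical shape.
#' @return Non-negative matrix of the same shape.
#' @export
error_map <- function(ref, rec) {
  if (!all(dim(ref) == dim(rec))) stop("ref and rec must have the same shape")
  abs(ref - rec)
}

#' Mean, SD and histogram of a metric distribution
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' fixed-width histogram bins, as used to summarize PSNR/SSIM over a test
#' set.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_bins Number of fixed-width histogram bins.
#' @return List with `mean`, `sd`, `breaks`, `counts`, `n`.
#' @export
summarize_distribution <- function(values, n_bins = 20L) {
  if (length(values) < 2) stop("need at least 2 values")
  breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
  if (breaks[1] == breaks[length(breaks)]) {
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = n_bins + 1L)
  }
  counts <- as.integer(table(cut(values, breaks, include.lowest = TRUE)))
  list(mean = mean(values), sd = stats::sd(values), breaks = breaks,
       counts = counts, n = length(values))
}

#' PSNR/SSIM report over a set of image pairs
#'
#' @param refs,recs Lists of matched reference/reconstruction matrices.
#' @param consts An `SSIMConstants` object.
#' @return A `MetricsReport`: list with vectors `psnr`, `ssim`, their
#'   `psnr_mean`, `psnr_sd`, `ssim_mean`, `ssim_sd`, and `n`.
#' @export
metrics_report <- function(refs, recs, consts = ssim_constants()) {
  stopifnot(length(refs) == length(recs), length(refs) >= 1)
  ps <- mapply(psnr, refs, recs)
  ss <- mapply(ssim, refs, recs, MoreArgs = list(consts = consts))
  structure(list(psnr = ps, ssim = ss,
                 psnr_mean = mean(ps), psnr_sd = stats::sd(ps),
                 ssim_mean = mean(ss), ssim_sd = stats::sd(ss),
                 n = length(ps)),
            class = "MetricsReport")
}
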