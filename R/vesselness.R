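#' @useDynLib mtrdn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Sampled Gaussian and its first/second derivatives on a +/- ceil(3.5*sigma)
# support. Kernels are moment-matched so the discrete operators are exact
# on low-order polynomials: g sums to 1; g1 has zero sum and first moment
# -1 (correlation with a ramp of slope m gives -m); g2 has zero sum and
# second moment 2 (correlation with t^2 gives exactly 2). Without this,
# truncation leaves a constant image with a small nonzero Hessian.
.gauss_kernels <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 / abs(sum(x * g1))
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - mean(g2)
  g2 <- g2 * (2 / sum(x^2 * g2))
  list(g = g, g1 = g1, g2 = g2)
}

#' Gaussian blur with replicate boundary
#'
#' Separable Gaussian smoothing, used as the rasterizer's point-spread
#' function and inside the Hessian filters.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Gaussian SD in pixels (> 0; values below 1e-6 return the
#'   input unchanged).
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma < 1e-6) return(image)
  k <- .gauss_kernels(sigma)
  cpp_sepfilter2(image, k$g, k$g)
}

#' Scale-normalized Hessian eigenvalues of an image
#'
#' Computes the Gaussian-derivative Hessian (Ixx, Ixy, Iyy) at scale
#' `sigma`, multiplies by `sigma^2` (scale normalization, so responses are
#' comparable across scales), and returns the per-pixel eigenvalues ordered
#' by absolute value, `|lambda1| <= |lambda2|`.
#'
#' @param image 2-D numeric matrix, at least 5 x 5, all finite.
#' @param sigma Scale (Gaussian SD) in pixels, > 0.
#' @return List with matrices `lambda1` and `lambda2`.
#' @export
hessian_eigenvalues <- function(image, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(dim(image) < 5)) stop("image must be at least 5 x 5")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  k <- .gauss_kernels(sigma)
  s2 <- sigma^2
  # rows are the first image axis: kr differentiates along rows
  ixx <- s2 * cpp_sepfilter2(image, k$g2, k$g)
  iyy <- s2 * cpp_sepfilter2(image, k$g, k$g2)
  ixy <- s2 * cpp_sepfilter2(image, k$g1, k$g1)

  tr2 <- (ixx + iyy) / 2
  disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  la <- tr2 + disc
  lb <- tr2 - disc
  swap <- abs(la) > abs(lb)
  lambda1 <- ifelse(swap, lb, la)
  lambda2 <- ifelse(swap, la, lb)
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' Parameters of the multiscale vesselness filter
#'
#' @param scales Gaussian SDs in pixels, non-empty, all > 0.
#' @param beta Blobness sensitivity (> 0).
#' @param c Structureness sensitivity; the string `"auto"` resolves, per
#'   scale, to half the maximum Frobenius norm of the Hessian over the
#'   image.
#' @param bright_on_dark If `TRUE` (the photoacoustic case) vessels are
#'   bright structures on a dark background.
#' @return A `VesselnessParams` list.
#' @export
vesselness_params <- function(scales = c(1, 2, 3, 4), beta = 0.5,
                              c = "auto", bright_on_dark = TRUE) {
  if (length(scales) < 1 || any(scales <= 0)) {
    stop("scales must be non-empty and strictly positive")
  }
  if (beta <= 0) stop("beta must be positive")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0)) {
    stop("c must be positive or \"auto\"")
  }
  structure(list(scales = scales, beta = beta, c = c,
                 bright_on_dark = isTRUE(bright_on_dark)),
            class = "VesselnessParams")
}

#' Multiscale Frangi vesselness response
#'
#' At each scale the tubular-structure likelihood is
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' ratio `R_B = lambda1 / lambda2` and structureness
#' `S = sqrt(lambda1^2 + lambda2^2)`, set to zero wherever `lambda2 > 0`
#' (for bright vessels; the sign test flips for dark vessels). The final
#' response is the pixelwise maximum over scales and lies in \[0, 1\].
#'
#' @param image 2-D numeric matrix.
#' @param params A `VesselnessParams`.
#' @return Response matrix in \[0, 1\], same shape as `image`.
#' @export
frangi_response <- function(image, params = vesselness_params()) {
  stopifnot(inherits(params, "VesselnessParams"))
  out <- matrix(0, nrow(image), ncol(image))
  for (sigma in params$scales) {
    ev <- hessian_eigenvalues(image, sigma)
    l1 <- ev$lambda1; l2 <- ev$lambda2
    s2 <- l1^2 + l2^2
    cc <- if (identical(params$c, "auto")) sqrt(max(s2)) / 2 else params$c
    # a structureness ceiling at rounding-noise level means the image is
    # flat at this scale; auto-calibrating c to it would amplify noise
    if (!is.finite(cc) || cc < 1e-8) next
    rb2 <- ifelse(l2 == 0, Inf, (l1 / l2)^2)
    v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[if (params$bright_on_dark) l2 > 0 else l2 < 0] <- 0
    out <- pmax(out, v)
  }
  out
}

#' Build the vessel-enhanced supervision target (ground truth 3)
#'
#' The third training target is the full-sampling 532 nm ground truth
#' passed through the multiscale vesselness filter and min-max normalized
#' back to \[0, 1\].
#'
#' @param gt1 Full-sampling 532 nm image, normalized to \[0, 1\].
#' @param params A `VesselnessParams`.
#' @return Enhanced image in \[0, 1\], same shape as `gt1`.
#' @export
make_ground_truth3 <- function(gt1, params = vesselness_params()) {
  v <- frangi_response(gt1, params)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(matrix(0, nrow(v), ncol(v)))
  (v - lo) / (hi - lo)
}
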