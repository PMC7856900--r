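#' Generate a random branching vessel tree
#'
#' Builds a piecewise-linear vascular tree by recursive random branching:
#' each segment spawns up to two children (one Bernoulli draw per side at
#' probability `branch_prob`), with child radius shrunk by a factor drawn
#' from U(0.6, 0.9), child length by U(0.7, 0.95), and the child direction
#' rotated by +/- U(0.25, 0.7) radians. Children inherit the oxygenation
#' (sO2) of their root, so oxygenation is constant within a tree and varies
#' between roots. Growth is depth-first: both children of a segment are
#' decided left side first, and a child's whole subtree is grown before the
#' right side's Bernoulli draw is made. All endpoints are clipped to the
#' field.
#'
#' RNG draw order (relevant when replaying the recursion): per root --
#' start row, start col, angle, length, radius, sO2; per segment and side --
#' one uniform for the branch decision, then (only if branching) angle
#' offset, length factor, radius factor.
#'
#' @param seed Integer seed; the tree is a pure function of the seed and the
#'   remaining parameters.
#' @param n_roots Number of independent root segments (>= 0).
#' @param max_depth Maximum branching depth (root segments have depth 1).
#' @param field_size Image field in pixels, `c(rows, cols)`; at least 16 x 16.
#' @param branch_prob Per-side branching probability in \[0, 1\].
#' @param radius_range Root radius range in pixels, `c(min, max)`, both > 0.
#' @return An object of class `VesselTree`: a list with `segments` (each a
#'   list with `start`, `end`, `radius`, `so2`, `depth`) and `field_size`.
#' @export
generate_vessel_tree <- function(seed, n_roots = 4, max_depth = 4,
                                 field_size = c(128, 128),
                                 branch_prob = 0.7,
                                 radius_range = c(1.2, 3.5)) {
  stopifnot(length(field_size) == 2)
  if (any(field_size < 16)) {
    stop("field_size must be at least 16 x 16 pixels")
  }
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2]) {
    stop("radius_range must be positive with min <= max")
  }
  if (n_roots < 0 || max_depth < 0) {
    stop("n_roots and max_depth must be non-negative")
  }
  set.seed(seed)
  segments <- list()
  clip <- function(p) pmin(pmax(p, 1), field_size)

  grow <- function(p0, ang, len, radius, so2, depth) {
    p1 <- clip(p0 + len * c(cos(ang), sin(ang)))
    segments[[length(segments) + 1L]] <<- list(
      start = p0, end = p1, radius = radius, so2 = so2, depth = depth
    )
    if (depth >= max_depth) return(invisible(NULL))
    for (side in c(-1, 1)) {
      if (stats::runif(1) < branch_prob) {
        ang2 <- ang + side * stats::runif(1, 0.25, 0.7)
        grow(p1, ang2,
             len * stats::runif(1, 0.7, 0.95),
             radius * stats::runif(1, 0.6, 0.9),
             so2, depth + 1L)
      }
    }
    invisible(NULL)
  }

  if (n_roots > 0 && max_depth > 0) {
    for (r in seq_len(n_roots)) {
      p0 <- c(stats::runif(1, 1, field_size[1]),
              stats::runif(1, 1, field_size[2]))
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.25, 0.45) * min(field_size)
      radius <- stats::runif(1, radius_range[1], radius_range[2])
      so2 <- stats::runif(1, 0.55, 1)
      grow(p0, ang, len, radius, so2, 1L)
    }
  }
  structure(list(segments = segments, field_size = as.integer(field_size)),
            class = "VesselTree")
}

#' Default hemoglobin extinction coefficient table
#'
#' Reads the packaged extinction coefficient constants for oxy- and
#' deoxyhemoglobin at 532 and 560 nm (relative units). 532 nm is treated as
#' isosbestic (equal coefficients) while at 560 nm deoxyhemoglobin absorbs
#' more strongly than oxyhemoglobin, which is what gives the two channels
#' their oxygenation-dependent contrast.
#'
#' @return An `ExtinctionTable`: a 2 x 2 numeric matrix with rows
#'   `c("532", "560")` and columns `c("HbO2", "Hb")`.
#' @export
default_extinction_table <- function() {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "mtrdn", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("HbO2", "Hb")])
  rownames(m) <- as.character(tab$wavelength_nm)
  extinction_table(m)
}

#' Construct and validate an extinction table
#'
#' @param m 2 x 2 numeric matrix, rows = wavelengths (532 then 560),
#'   columns = chromophores (HbO2 then Hb); all entries > 0, nonsingular.
#' @return The validated matrix with class `ExtinctionTable`.
#' @export
extinction_table <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2))) stop("extinction table must be 2 x 2")
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("extinction coefficients must be strictly positive")
  }
  if (abs(det(m)) < 1e-12 * prod(colSums(abs(m)))) {
    stop("extinction table is singular")
  }
  if (is.null(rownames(m))) rownames(m) <- c("532", "560")
  if (is.null(colnames(m))) colnames(m) <- c("HbO2", "Hb")
  class(m) <- c("ExtinctionTable", class(m))
  m
}

#' Rasterize a vessel tree into a two-channel phantom scene
#'
#' Each segment is drawn with an anti-aliased disk brush: pixel coverage is
#' `clamp(radius + 0.5 - distance_to_segment, 0, 1)`. Where segments overlap
#' the segment with the highest coverage wins and supplies the local sO2.
#' The per-pixel absorption at wavelength lambda is
#' `eps_HbO2(lambda) * so2 + eps_Hb(lambda) * (1 - so2)` scaled by coverage,
#' blurred with an isotropic Gaussian point-spread function of the given
#' FWHM, offset by `background_level`, and finally min-max normalized.
#' Normalization is JOINT over the two channels (one shared min and max) so
#' the inter-channel intensity ratio -- the carrier of the sO2 signal -- is
#' preserved; the brighter channel spans \[0, 1\] exactly.
#'
#' @param tree A `VesselTree`.
#' @param psf_fwhm Gaussian PSF full width at half maximum in pixels (> 0).
#' @param extinction An `ExtinctionTable` (default: packaged constants).
#' @param background_level Constant background offset added after blurring,
#'   as a fraction of the peak pre-background absorption.
#' @return A `PhantomScene`: list with `tree`, `gt532`, `gt560` (images in
#'   \[0, 1\]), `so2_true` (NA outside vessels), and logical `vessel_mask`
#'   (the unblurred vessel support, coverage >= 0.5).
#' @export
rasterize_scene <- function(tree, psf_fwhm = 2.5,
                            extinction = default_extinction_table(),
                            background_level = 0.02) {
  stopifnot(inherits(tree, "VesselTree"))
  if (psf_fwhm <= 0) stop("psf_fwhm must be positive")
  extinction <- extinction_table(unclass(extinction))
  nr <- tree$field_size[1]; nc <- tree$field_size[2]

  coverage <- matrix(0, nr, nc)
  so2_px <- matrix(NA_real_, nr, nc)
  for (seg in tree$segments) {
    cov_seg <- .segment_coverage(seg, nr, nc)
    if (is.null(cov_seg)) next
    idx <- cov_seg$idx
    win <- cov_seg$cov > coverage[idx]
    upd <- idx[win, , drop = FALSE]
    coverage[upd] <- cov_seg$cov[win]
    so2_px[upd] <- seg$so2
  }

  vessel_mask <- coverage >= 0.5
  so2_true <- ifelse(vessel_mask, so2_px, NA_real_)

  s <- ifelse(is.na(so2_px), 0, so2_px)
  a532 <- coverage * (extinction["532", "HbO2"] * s +
                        extinction["532", "Hb"] * (1 - s))
  a560 <- coverage * (extinction["560", "HbO2"] * s +
                        extinction["560", "Hb"] * (1 - s))

  sigma <- psf_fwhm / (2 * sqrt(2 * log(2)))
  a532 <- gaussian_blur(a532, sigma)
  a560 <- gaussian_blur(a560, sigma)

  peak <- max(a532, a560)
  bg <- background_level * ifelse(peak > 0, peak, 1)
  a532 <- a532 + bg
  a560 <- a560 + bg

  lo <- min(a532, a560); hi <- max(a532, a560)
  if (hi - lo < .Machine$double.eps) {
    # constant pair: joint min-max of a constant is defined as all-zero
    a532[] <- 0; a560[] <- 0
  } else {
    a532 <- (a532 - lo) / (hi - lo)
    a560 <- (a560 - lo) / (hi - lo)
  }
  structure(list(tree = tree, gt532 = a532, gt560 = a560,
                 so2_true = so2_true, vessel_mask = vessel_mask),
            class = "PhantomScene")
}

# Anti-aliased coverage of one capsule-shaped segment, restricted to its
# bounding box. Returns NULL when the brush misses the field entirely.
.segment_coverage <- function(seg, nr, nc) {
  r <- seg$radius
  lo <- floor(pmin(seg$start, seg$end) - r - 1)
  hi <- ceiling(pmax(seg$start, seg$end) + r + 1)
  i0 <- max(1, lo[1]); i1 <- min(nr, hi[1])
  j0 <- max(1, lo[2]); j1 <- min(nc, hi[2])
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1; jj <- j0:j1
  pi_ <- rep(ii, times = length(jj))
  pj <- rep(jj, each = length(ii))
  d <- .point_segment_dist(pi_, pj, seg$start, seg$end)
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  keep <- cov > 0
  if (!any(keep)) return(NULL)
  idx <- cbind(pi_, pj)[keep, , drop = FALSE]
  list(idx = idx, cov = cov[keep])
}

.point_segment_dist <- function(pi_, pj, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx * vx + vy * vy
  if (len2 < .Machine$double.eps) {
    return(sqrt((pi_ - a[1])^2 + (pj - a[2])^2))
  }
  t <- ((pi_ - a[1]) * vx + (pj - a[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pi_ - (a[1] + t * vx))^2 + (pj - (a[2] + t * vy))^2)
}

#' Split scenes into training and testing groups
#'
#' Disjoint, exhaustive random partition, deterministic per seed; mirrors
#' the separation of animals into a training group and a testing group.
#'
#' @param scenes List of `PhantomScene` objects (length >= 2).
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_scenes <- function(scenes, train_fraction, seed) {
  if (length(scenes) < 2) stop("need at least 2 scenes to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  set.seed(seed)
  n <- length(scenes)
  n_train <- min(max(round(n * train_fraction), 1L), n - 1L)
  idx <- sample.int(n, n_train)
  list(train = scenes[sort(idx)], test = scenes[sort(setdiff(seq_len(n), idx))])
}

#' Write a phantom scene as multi-page TIFF plus a JSON sidecar
#'
#' Pages in order: gt532, gt560, so2_true (undefined pixels stored as 0;
#' the vessel_mask page identifies them), vessel_mask.
#'
#' @param scene A `PhantomScene`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param params Optional named list of generation parameters recorded in
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path, params = list()) {
  so2 <- scene$so2_true
  so2[is.na(so2)] <- 0
  pages <- list(scene$gt532, scene$gt560, so2,
                matrix(as.numeric(scene$vessel_mask),
                       nrow(scene$vessel_mask)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    c(params, list(field_size = scene$tree$field_size,
                   n_segments = length(scene$tree$segments),
                   pages = c("gt532", "gt560", "so2_true", "vessel_mask"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phantom scene written by [write_scene()]
#'
#' @param path TIFF path.
#' @return A `PhantomScene` (with `tree = NULL`; geometry is not stored).
#' @export
read_scene <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  mask <- pages[[4]] > 0.5
  so2 <- pages[[3]]
  so2[!mask] <- NA_real_
  structure(list(tree = NULL, gt532 = pages[[1]], gt560 = pages[[2]],
                 so2_true = so2, vessel_mask = mask),
            class = "PhantomScene")
}
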