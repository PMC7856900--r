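#' Dual-wavelength linear unmixing of oxygen saturation
#'
#' Solves, per pixel, the 2 x 2 linear system
#' `[pa532; pa560] = E [C_HbO2; C_Hb]` for the chromophore concentrations
#' and returns `sO2 = C_HbO2 / (C_HbO2 + C_Hb)` clipped to \[0, 1\].
#' Pixels with non-positive total concentration are undefined (NA).
#' Because sO2 is a per-pixel ratio it is invariant to any common scaling
#' of the two channels, which is why it survives joint min-max
#' normalization of the images.
#'
#' @param pa532,pa560 Photoacoustic amplitude images of identical shape.
#' @param table An `ExtinctionTable` (rows 532/560, columns HbO2/Hb).
#' @return sO2 matrix in \[0, 1\] with NA where undefined.
#' @export
unmix_so2 <- function(pa532, pa560, table = default_extinction_table()) {
  if (!all(dim(pa532) == dim(pa560))) {
    stop("pa532 and pa560 must have the same shape")
  }
  e <- extinction_table(unclass(table))
  einv <- solve(unclass(e))
  pa <- rbind(as.numeric(pa532), as.numeric(pa560))
  conc <- einv %*% pa          # row 1: C_HbO2, row 2: C_Hb
  total <- conc[1, ] + conc[2, ]
  so2 <- ifelse(total > 0, conc[1, ] / total, NA_real_)
  so2 <- pmin(pmax(so2, 0), 1)
  matrix(so2, nrow(pa532), ncol(pa532))
}

#' Mask an sO2 map with a vessel image
#'
#' Thresholds `mask_image` at `threshold` to obtain a vessel mask and
#' passes the sO2 values through UNCHANGED inside the mask (masking selects
#' pixels, it never edits values); pixels outside the mask become NA.
#'
#' @param so2 sO2 matrix (NA where already undefined).
#' @param mask_image Image used as the mask source (e.g. the original
#'   image, the vesselness-filtered image, or the fused reconstruction).
#' @param threshold Mask threshold in \[0, 1\].
#' @param mask_source Label recording which image supplied the mask; one of
#'   `"original"`, `"frangi"`, `"recon3"`.
#' @return An `SO2Map`: list with `so2`, logical `mask`, `mask_source`.
#' @export
apply_mask <- function(so2, mask_image, threshold = 0.1,
                       mask_source = c("recon3", "original", "frangi")) {
  if (!all(dim(so2) == dim(mask_image))) {
    stop("so2 and mask_image must have the same shape")
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  mask_source <- match.arg(mask_source)
  mask <- mask_image >= threshold
  if (!any(mask)) warning("mask is empty at this threshold")
  out <- so2
  out[!mask] <- NA_real_
  structure(list(so2 = out, mask = mask, mask_source = mask_source),
            class = "SO2Map")
}

#' Write an sO2 map as TIFF plus JSON statistics
#'
#' Two pages: the sO2 values (undefined pixels stored as 0) and the mask
#' identifying the defined pixels; summary statistics of the defined
#' pixels go to `<path>.json`.
#'
#' @param so2map An `SO2Map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_so2 <- function(so2map, path) {
  img <- so2map$so2
  defined <- so2map$mask & !is.na(so2map$so2)
  img[!defined] <- 0
  tiff::writeTIFF(list(img, matrix(as.numeric(defined), nrow(img))),
                  path, bits.per.sample = 32L)
  vals <- so2map$so2[so2map$mask & !is.na(so2map$so2)]
  stats <- list(mask_source = so2map$mask_source,
                n_defined = length(vals),
                mean = if (length(vals)) mean(vals) else NA,
                sd = if (length(vals) > 1) stats::sd(vals) else NA)
  jsonlite::write_json(stats, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
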