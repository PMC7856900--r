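#' Cut an image into patches
#'
#' Row-major tiling with the given patch size and stride. When the stride
#' does not reach the right or bottom edge exactly, the last row/column of
#' tiles is shifted inward so the whole image is covered.
#'
#' @param image 2-D numeric matrix.
#' @param patch Patch side length in pixels (<= both image dimensions).
#' @param stride Step between tile origins (>= 1); defaults to `patch`
#'   (non-overlapping tiling).
#' @return List with `patches` (list of `patch` x `patch` matrices) and
#'   `origins` (n x 2 integer matrix of 0-based row/col pixel origins).
#' @export
extract_patches <- function(image, patch, stride = patch) {
  nr <- nrow(image); nc <- ncol(image)
  if (patch > nr || patch > nc) stop("patch larger than image")
  if (stride < 1) stop("stride must be >= 1")
  starts <- function(n) {
    s <- seq(0L, max(n - patch, 0L), by = stride)
    if (s[length(s)] + patch < n) s <- c(s, n - patch)
    as.integer(s)
  }
  ri <- starts(nr); ci <- starts(nc)
  origins <- cbind(rep(ri, times = length(ci)), rep(ci, each = length(ri)))
  # row-major order of tiles: sort by row then col
  ord <- order(origins[, 1], origins[, 2])
  origins <- origins[ord, , drop = FALSE]
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r0 <- origins[i, 1]; c0 <- origins[i, 2]
    image[r0 + seq_len(patch), c0 + seq_len(patch), drop = FALSE]
  })
  list(patches = patches, origins = origins)
}

#' Stitch patches back into a full image
#'
#' Each patch is placed at its origin scaled by `scale`; pixels covered by
#' several overlapping patches are averaged.
#'
#' @param patches List of equally sized matrices.
#' @param origins n x 2 matrix of 0-based low-resolution origins.
#' @param out_shape `c(rows, cols)` of the output image.
#' @param scale Integer factor relating low-resolution origins to output
#'   coordinates.
#' @return Stitched matrix of shape `out_shape`.
#' @export
stitch_patches <- function(patches, origins, out_shape, scale = 1L) {
  acc <- matrix(0, out_shape[1], out_shape[2])
  cnt <- matrix(0, out_shape[1], out_shape[2])
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    r0 <- origins[i, 1] * scale; c0 <- origins[i, 2] * scale
    ri <- r0 + seq_len(nrow(p)); ci <- c0 + seq_len(ncol(p))
    if (max(ri) > out_shape[1] || max(ci) > out_shape[2]) {
      stop("patch at origin (", origins[i, 1], ",", origins[i, 2],
           ") extends beyond out_shape")
    }
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) stop("stitching leaves uncovered pixels")
  acc / cnt
}

#' Build an aligned training patch set from phantom scenes
#'
#' Degrades every scene with the given specification (a fresh noise seed
#' per scene derived from `spec$seed`), computes the vessel-enhanced third
#' target from the 532 nm ground truth, and cuts all five image roles into
#' patches aligned by origin: low-resolution patches from the two inputs,
#' full-resolution patches (origin and size scaled by `spec$s`) from the
#' three ground truths.
#'
#' @param scenes List of `PhantomScene` objects.
#' @param spec A `DegradationSpec`.
#' @param patch_lr Low-resolution patch side (pixels).
#' @param stride_lr Low-resolution stride; defaults to `patch_lr`.
#' @param vparams `VesselnessParams` for the enhancement target.
#' @return A `PatchSet`: lists `input1`, `input2`, `gt1`, `gt2`, `gt3`,
#'   plus `origins` (0-based LR origins), `patch_size_lr`, `scale`.
#' @export
make_patch_set <- function(scenes, spec, patch_lr = 32L,
                           stride_lr = patch_lr,
                           vparams = vesselness_params()) {
  stopifnot(length(scenes) >= 1)
  s <- spec$s
  out <- list(input1 = list(), input2 = list(), gt1 = list(), gt2 = list(),
              gt3 = list(), origins = NULL,
              patch_size_lr = as.integer(patch_lr), scale = as.integer(s))
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    spec_k <- degradation_spec(spec$f, spec$s, spec$noise_sigma,
                               spec$seed + 2L * (k - 1L))
    pair <- degrade_scene(sc, spec_k, provenance = k)
    gt3 <- make_ground_truth3(sc$gt532, vparams)
    lr <- extract_patches(pair$input1, patch_lr, stride_lr)
    lr2 <- extract_patches(pair$input2, patch_lr, stride_lr)
    hr_patch <- patch_lr * s
    hr_origin <- lr$origins * s
    grab_hr <- function(img) {
      lapply(seq_len(nrow(hr_origin)), function(i) {
        img[hr_origin[i, 1] + seq_len(hr_patch),
            hr_origin[i, 2] + seq_len(hr_patch), drop = FALSE]
      })
    }
    out$input1 <- c(out$input1, lr$patches)
    out$input2 <- c(out$input2, lr2$patches)
    out$gt1 <- c(out$gt1, grab_hr(sc$gt532))
    out$gt2 <- c(out$gt2, grab_hr(sc$gt560))
    out$gt3 <- c(out$gt3, grab_hr(gt3))
    out$origins <- rbind(out$origins, lr$origins)
  }
  structure(out, class = "PatchSet")
}

.adam_init <- function(grads) {
  rapply(grads, function(g) g * 0, how = "replace")
}

# one Adam step over the nested grads structure; returns updated
# list(params, m, v)
.adam_update <- function(params, grads, m, v, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (sn in names(grads)) {
    for (ly in names(grads[[sn]])) {
      for (fld in c("dw", "db")) {
        tgt <- if (fld == "dw") "w" else "b"
        g <- grads[[sn]][[ly]][[fld]]
        m[[sn]][[ly]][[fld]] <- beta1 * m[[sn]][[ly]][[fld]] + (1 - beta1) * g
        v[[sn]][[ly]][[fld]] <- beta2 * v[[sn]][[ly]][[fld]] +
          (1 - beta2) * g^2
        mhat <- m[[sn]][[ly]][[fld]] / (1 - beta1^t)
        vhat <- v[[sn]][[ly]][[fld]] / (1 - beta2^t)
        params[[sn]]$layers[[ly]][[tgt]] <-
          params[[sn]]$layers[[ly]][[tgt]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, m = m, v = v)
}

#' Train the multitask model on a patch set
#'
#' Minimizes the weighted multisupervised mean-absolute-error loss by Adam
#' over shuffled mini-batches of aligned patch tuples. Deterministic for a
#' fixed seed on a fixed platform.
#'
#' @param patch_set A `PatchSet` from [make_patch_set()].
#' @param params Initial `MTRDNParams` (its subnet1/2 scale must equal the
#'   patch set's scale).
#' @param steps Number of gradient steps (>= 1).
#' @param lr Adam learning rate.
#' @param batch Mini-batch size (patch tuples per step).
#' @param seed Seed for batch shuffling.
#' @param log_every Record/emit the loss every this many steps (the loss of
#'   every step is always recorded in the history).
#' @param verbose Print line-delimited JSON progress logs.
#' @return A `TrainState`: list with `params` (trained), `step`,
#'   `loss_history` (data.frame step/loss), `config` (optimizer settings),
#'   `seed`.
#' @export
train_model <- function(patch_set, params, steps = 500L, lr = 1e-3,
                        batch = 2L, seed = 1L, log_every = 50L,
                        verbose = FALSE) {
  stopifnot(inherits(patch_set, "PatchSet"), inherits(params, "MTRDNParams"))
  if (steps < 1) stop("steps must be >= 1")
  n <- length(patch_set$input1)
  if (n < 1) stop("empty patch set")
  if (params$subnet1$config$scale != patch_set$scale) {
    stop("subnetwork scale does not match patch set scale")
  }
  set.seed(seed)
  zero <- list(subnet1 = .zero_grads(params$subnet1),
               subnet2 = .zero_grads(params$subnet2),
               subnet3 = .zero_grads(params$subnet3))
  m <- zero; v <- zero
  losses <- numeric(steps)
  for (t in seq_len(steps)) {
    idx <- sample.int(n, min(batch, n))
    acc <- NULL; loss <- 0
    for (i in idx) {
      lg <- .mtrdn_loss_grads(params,
                              patch_set$input1[[i]], patch_set$input2[[i]],
                              patch_set$gt1[[i]], patch_set$gt2[[i]],
                              patch_set$gt3[[i]])
      loss <- loss + lg$loss
      acc <- if (is.null(acc)) lg$grads else .add_grads(acc, lg$grads)
    }
    loss <- loss / length(idx)
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss) at step ", t)
    }
    acc <- .scale_grads(acc, 1 / length(idx))
    upd <- .adam_update(params, acc, m, v, lr, t)
    params <- upd$params; m <- upd$m; v <- upd$v
    losses[t] <- loss
    if (verbose && (t %% log_every == 0 || t == 1)) {
      cat(jsonlite::toJSON(list(step = t, loss = loss), auto_unbox = TRUE,
                           digits = 6), "\n")
    }
  }
  structure(list(params = params, step = steps,
                 loss_history = data.frame(step = seq_len(steps),
                                           loss = losses),
                 config = list(lr = lr, batch = batch),
                 seed = as.integer(seed)),
            class = "TrainState")
}

.zero_grads <- function(net) {
  lapply(net$layers, function(l) list(dw = l$w * 0, db = l$b * 0))
}

.add_grads <- function(a, b) {
  for (sn in names(a)) for (ly in names(a[[sn]])) {
    a[[sn]][[ly]]$dw <- a[[sn]][[ly]]$dw + b[[sn]][[ly]]$dw
    a[[sn]][[ly]]$db <- a[[sn]][[ly]]$db + b[[sn]][[ly]]$db
  }
  a
}

.scale_grads <- function(a, f) {
  for (sn in names(a)) for (ly in names(a[[sn]])) {
    a[[sn]][[ly]]$dw <- a[[sn]][[ly]]$dw * f
    a[[sn]][[ly]]$db <- a[[sn]][[ly]]$db * f
  }
  a
}

#' Reconstruct a full image with a trained model
#'
#' Cuts the two input channels into patches, runs the multitask forward
#' pass per patch, and stitches the three outputs back together (origins
#' scaled by the model's upsampling factor, overlaps averaged).
#'
#' @param params Trained `MTRDNParams`.
#' @param input1,input2 Low-resolution input matrices of identical shape.
#' @param patch Low-resolution patch side; defaults to the whole image.
#' @param stride Low-resolution stride; defaults to `patch`.
#' @return List with matrices `recon1`, `recon2`, `recon3`, each of shape
#'   `dim(input1) * scale`.
#' @export
reconstruct <- function(params, input1, input2, patch = min(dim(input1)),
                        stride = patch) {
  stopifnot(inherits(params, "MTRDNParams"))
  if (!all(dim(input1) == dim(input2))) {
    stop("input1 and input2 must have the same shape")
  }
  s <- params$subnet1$config$scale
  p1 <- extract_patches(input1, patch, stride)
  p2 <- extract_patches(input2, patch, stride)
  outs <- lapply(seq_along(p1$patches), function(i) {
    mtrdn_forward(params, p1$patches[[i]], p2$patches[[i]])
  })
  out_shape <- dim(input1) * s
  list(
    recon1 = stitch_patches(lapply(outs, `[[`, "output1"), p1$origins,
                            out_shape, s),
    recon2 = stitch_patches(lapply(outs, `[[`, "output2"), p1$origins,
                            out_shape, s),
    recon3 = stitch_patches(lapply(outs, `[[`, "output3"), p1$origins,
                            out_shape, s)
  )
}

#' Nearest-neighbor upsampling
#'
#' The no-learning baseline for undersampled inputs: each low-resolution
#' pixel is replicated into an `s` x `s` block.
#'
#' @param image 2-D numeric matrix.
#' @param s Integer upsampling factor >= 1.
#' @return Matrix of shape `dim(image) * s`.
#' @export
upsample_nearest <- function(image, s) {
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1")
  image[rep(seq_len(nrow(image)), each = s),
        rep(seq_len(ncol(image)), each = s), drop = FALSE]
}
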