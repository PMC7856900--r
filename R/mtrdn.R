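#' Assemble a three-subnetwork multitask model
#'
#' Subnetworks 1 and 2 restore the 532 and 560 nm channels (denoising +
#' super-resolution by `scale`); subnetwork 3 fuses their outputs by
#' channel concatenation at full resolution and produces the
#' vessel-enhanced product. One weighted loss supervises all three outputs
#' against their respective ground truths.
#'
#' @param scale Undersampling factor shared by subnetworks 1 and 2.
#' @param D,C,G,G0 Architecture profile passed to every subnetwork.
#' @param loss_weights Non-negative weights `(w1, w2, w3)`; normalized to
#'   sum to one. The fusion branch carries the largest default share since
#'   the fused output is the headline product.
#' @param seed Seed for parameter initialization (each subnetwork uses
#'   `seed`, `seed + 1`, `seed + 2`).
#' @return An `MTRDNParams` list with `subnet1`, `subnet2`, `subnet3`,
#'   `loss_weights`.
#' @export
mtrdn_params <- function(scale = 2L, D = 4L, C = 4L, G = 16L, G0 = 32L,
                         loss_weights = c(0.25, 0.25, 0.5), seed = 1L) {
  if (length(loss_weights) != 3 || any(loss_weights < 0) ||
      sum(loss_weights) <= 0) {
    stop("loss_weights must be three non-negative values, not all zero")
  }
  loss_weights <- loss_weights / sum(loss_weights)
  cfg12 <- rdn_config(D, C, G, G0, scale = scale, in_channels = 1L,
                      out_channels = 1L)
  cfg3 <- rdn_config(D, C, G, G0, scale = 1L, in_channels = 2L,
                     out_channels = 1L)
  structure(list(subnet1 = build_subnetwork(cfg12, seed),
                 subnet2 = build_subnetwork(cfg12, seed + 1L),
                 subnet3 = build_subnetwork(cfg3, seed + 2L),
                 loss_weights = loss_weights),
            class = "MTRDNParams")
}

#' Forward pass of the multitask model
#'
#' @param params An `MTRDNParams`.
#' @param input1,input2 Low-resolution input matrices of identical shape
#'   (532 and 560 nm channels).
#' @param keep_cache Keep activations for gradient computation.
#' @return List with `output1`, `output2`, `output3` (matrices at full,
#'   upscaled resolution) and `caches` when requested.
#' @export
mtrdn_forward <- function(params, input1, input2, keep_cache = FALSE) {
  stopifnot(inherits(params, "MTRDNParams"))
  if (!all(dim(input1) == dim(input2))) {
    stop("input1 and input2 must have the same shape")
  }
  o1 <- rdn_forward(params$subnet1, input1, keep_cache)
  o2 <- rdn_forward(params$subnet2, input2, keep_cache)
  x3 <- .cat3(o1$y, o2$y)
  o3 <- rdn_forward(params$subnet3, x3, keep_cache)
  out <- list(output1 = o1$y[, , 1], output2 = o2$y[, , 1],
              output3 = o3$y[, , 1])
  if (keep_cache) out$caches <- list(c1 = o1$cache, c2 = o2$cache,
                                     c3 = o3$cache)
  out
}

#' Weighted multisupervised restoration loss
#'
#' `w1 L(o1, g1) + w2 L(o2, g2) + w3 L(o3, g3)` with L the mean absolute
#' error and the weights normalized to sum to one.
#'
#' @param outputs List of three output matrices.
#' @param ground_truths List of three matched ground-truth matrices.
#' @param weights Non-negative weights, not all zero.
#' @return Scalar loss.
#' @export
multitask_loss <- function(outputs, ground_truths,
                           weights = c(0.25, 0.25, 0.5)) {
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be three non-negative values, not all zero")
  }
  w <- weights / sum(weights)
  l <- 0
  for (i in 1:3) {
    o <- outputs[[i]]; g <- ground_truths[[i]]
    if (!all(dim(o) == dim(g))) stop("output/ground-truth shape mismatch")
    l <- l + w[i] * mean(abs(o - g))
  }
  l
}

# Loss and full gradient of the multitask model for one patch tuple.
# Returns list(loss, grads = list(subnet1, subnet2, subnet3)).
.mtrdn_loss_grads <- function(params, input1, input2, gt1, gt2, gt3) {
  w <- params$loss_weights / sum(params$loss_weights)
  fw <- mtrdn_forward(params, input1, input2, keep_cache = TRUE)
  o1 <- fw$output1; o2 <- fw$output2; o3 <- fw$output3
  loss <- w[1] * mean(abs(o1 - gt1)) + w[2] * mean(abs(o2 - gt2)) +
    w[3] * mean(abs(o3 - gt3))

  n <- length(o3)
  d_o3 <- array(w[3] * sign(o3 - gt3) / n, c(dim(o3), 1L))
  b3 <- rdn_backward(params$subnet3, fw$caches$c3, d_o3)
  d_x3 <- .split3(b3$dx, c(1L, 1L))
  d_o1 <- d_x3[[1]] + array(w[1] * sign(o1 - gt1) / length(o1),
                            c(dim(o1), 1L))
  d_o2 <- d_x3[[2]] + array(w[2] * sign(o2 - gt2) / length(o2),
                            c(dim(o2), 1L))
  b1 <- rdn_backward(params$subnet1, fw$caches$c1, d_o1)
  b2 <- rdn_backward(params$subnet2, fw$caches$c2, d_o2)
  list(loss = loss,
       grads = list(subnet1 = b1$grads, subnet2 = b2$grads,
                    subnet3 = b3$grads))
}

#' Save a trained model to a single checkpoint file
#'
#' The checkpoint is an RDS file holding the parameters together with the
#' three subnetwork configurations and loss weights serialized as a JSON
#' metadata string, so a checkpoint is self-describing.
#'
#' @param params An `MTRDNParams`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  meta <- jsonlite::toJSON(list(
    subnet1 = unclass(params$subnet1$config),
    subnet2 = unclass(params$subnet2$config),
    subnet3 = unclass(params$subnet3$config),
    loss_weights = params$loss_weights), auto_unbox = TRUE, digits = NA)
  saveRDS(list(meta_json = as.character(meta), params = params), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file path.
#' @return The `MTRDNParams` stored in the checkpoint.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)$params
}
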