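#' Residual dense network configuration
#'
#' Architecture hyperparameters of one subnetwork: `D` residual dense
#' blocks, `C` densely connected convolutions per block with growth rate
#' `G`, base width `G0`, and a sub-pixel upsampling factor `scale` matching
#' the acquisition's undersampling factor. The defaults are a small profile
#' suitable for desk-scale CPU training; the full-scale profile published
#' for image super-resolution (D = 16, C = 8, G = 64) is reachable through
#' the same fields.
#'
#' @param D Number of residual dense blocks.
#' @param C Convolutions per block.
#' @param G Growth rate (channels added per dense convolution).
#' @param G0 Base number of feature channels.
#' @param scale Upsampling factor, one of 1, 2, 4.
#' @param in_channels,out_channels Image channels in and out.
#' @return An `RDNConfig` list.
#' @export
rdn_config <- function(D = 4L, C = 4L, G = 16L, G0 = 32L, scale = 1L,
                       in_channels = 1L, out_channels = 1L) {
  v <- c(D = D, C = C, G = G, G0 = G0, scale = scale,
         in_channels = in_channels, out_channels = out_channels)
  if (any(v < 1)) stop("all RDN configuration fields must be positive")
  if (!scale %in% c(1L, 2L, 4L)) stop("scale must be 1, 2 or 4")
  structure(lapply(as.list(v), as.integer), class = "RDNConfig")
}

.conv_init <- function(cout, cin, k, gain = sqrt(2)) {
  fan_in <- k * k * cin
  list(w = matrix(stats::rnorm(cout * fan_in, 0, gain / sqrt(fan_in)),
                  cout, fan_in),
       b = rep(0, cout), k = as.integer(k))
}

#' Initialize the learnable parameters of one RDN subnetwork
#'
#' Layers: two shallow feature-extraction 3x3 convolutions; `D` residual
#' dense blocks (each `C` dense 3x3 convolutions with ReLU, a 1x1 local
#' feature fusion and a local residual); 1x1 + 3x3 global feature fusion
#' with a global residual back to the first shallow feature map; a 3x3
#' convolution feeding sub-pixel (pixel-shuffle) upsampling when
#' `scale > 1`; and a final 3x3 reconstruction convolution. Weights are
#' He-initialized, biases zero.
#'
#' @param config An `RDNConfig`.
#' @param seed Integer seed for the initialization.
#' @return Named list of conv parameter sets (`w`, `b`, `k`).
#' @export
build_subnetwork <- function(config, seed = 1L) {
  stopifnot(inherits(config, "RDNConfig"))
  set.seed(seed)
  D <- config$D; C <- config$C; G <- config$G; G0 <- config$G0
  p <- list()
  p$sfe1 <- .conv_init(G0, config$in_channels, 3)
  p$sfe2 <- .conv_init(G0, G0, 3)
  for (d in seq_len(D)) {
    for (cc in seq_len(C)) {
      p[[sprintf("b%dc%d", d, cc)]] <- .conv_init(G, G0 + (cc - 1) * G, 3)
    }
    p[[sprintf("b%dlff", d)]] <- .conv_init(G0, G0 + C * G, 1, gain = 1)
  }
  p$gff1 <- .conv_init(G0, D * G0, 1, gain = 1)
  p$gff2 <- .conv_init(G0, G0, 3, gain = 1)
  if (config$scale > 1) {
    p$up <- .conv_init(G0 * config$scale^2, G0, 3)
  }
  p$recon <- .conv_init(config$out_channels, G0, 3, gain = 1)
  structure(list(config = config, layers = p), class = "RDNParams")
}

#' Total learnable parameter count of a subnetwork
#' @param net An `RDNParams` object.
#' @return Integer count of scalars in all weights and biases.
#' @export
rdn_n_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$w) + length(l$b), numeric(1)))
}

.as_chw <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

.cat3 <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

.pixel_shuffle <- function(x, s) {
  d <- dim(x); C <- d[3] %/% (s * s)
  out <- array(0, c(d[1] * s, d[2] * s, C))
  for (c in seq_len(C)) {
    for (dj in seq_len(s)) {
      for (di in seq_len(s)) {
        out[seq(di, d[1] * s, by = s), seq(dj, d[2] * s, by = s), c] <-
          x[, , (c - 1) * s * s + (di - 1) + (dj - 1) * s + 1]
      }
    }
  }
  out
}

.pixel_unshuffle <- function(y, s) {
  d <- dim(y); C <- d[3]
  out <- array(0, c(d[1] %/% s, d[2] %/% s, C * s * s))
  for (c in seq_len(C)) {
    for (dj in seq_len(s)) {
      for (di in seq_len(s)) {
        out[, , (c - 1) * s * s + (di - 1) + (dj - 1) * s + 1] <-
          y[seq(di, d[1], by = s), seq(dj, d[2], by = s), c]
      }
    }
  }
  out
}

#' Forward pass of one RDN subnetwork
#'
#' Fully convolutional: any input of at least 8 x 8 pixels is mapped to an
#' output of `input size * scale`.
#'
#' @param net An `RDNParams` object.
#' @param x Input image: matrix or H x W x C array.
#' @param keep_cache Keep intermediate activations for [rdn_backward()].
#' @return List with `y` (H*scale x W*scale x out_channels array) and,
#'   if requested, `cache`.
#' @export
rdn_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$config; p <- net$layers
  x <- .as_chw(x)
  if (any(dim(x)[1:2] < 8)) stop("input must be at least 8 x 8 pixels")
  if (dim(x)[3] != cfg$in_channels) stop("wrong number of input channels")
  cache <- if (keep_cache) list(x = x) else NULL

  f1 <- cpp_conv2d(x, p$sfe1$w, p$sfe1$b, 3L)
  f2 <- cpp_conv2d(f1, p$sfe2$w, p$sfe2$b, 3L)
  if (keep_cache) { cache$f1 <- f1; cache$f2 <- f2 }

  xb <- f2
  block_outs <- vector("list", cfg$D)
  if (keep_cache) cache$blocks <- vector("list", cfg$D)
  for (d in seq_len(cfg$D)) {
    x0 <- xb
    inp <- x0
    bc <- if (keep_cache) list(ins = vector("list", cfg$C),
                               zs = vector("list", cfg$C)) else NULL
    for (cc in seq_len(cfg$C)) {
      nm <- sprintf("b%dc%d", d, cc)
      z <- cpp_conv2d(inp, p[[nm]]$w, p[[nm]]$b, 3L)
      a <- z * (z > 0)
      if (keep_cache) { bc$ins[[cc]] <- inp; bc$zs[[cc]] <- z }
      inp <- .cat3(inp, a)
    }
    nm <- sprintf("b%dlff", d)
    lf <- cpp_conv2d(inp, p[[nm]]$w, p[[nm]]$b, 1L)
    if (keep_cache) { bc$lff_in <- inp; cache$blocks[[d]] <- bc }
    xb <- lf + x0
    block_outs[[d]] <- xb
  }

  gff_in <- block_outs[[1]]
  if (cfg$D > 1) for (d in 2:cfg$D) gff_in <- .cat3(gff_in, block_outs[[d]])
  g1 <- cpp_conv2d(gff_in, p$gff1$w, p$gff1$b, 1L)
  g2 <- cpp_conv2d(g1, p$gff2$w, p$gff2$b, 3L)
  f <- g2 + f1
  if (keep_cache) { cache$gff_in <- gff_in; cache$g1 <- g1; cache$f <- f }

  if (cfg$scale > 1) {
    u <- cpp_conv2d(f, p$up$w, p$up$b, 3L)
    fout <- .pixel_shuffle(u, cfg$scale)
  } else {
    fout <- f
  }
  if (keep_cache) cache$fout <- fout
  y <- cpp_conv2d(fout, p$recon$w, p$recon$b, 3L)
  list(y = y, cache = cache)
}

# split a H x W x C gradient array into channel ranges
.split3 <- function(dy, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- dy[, , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

#' Backward pass of one RDN subnetwork
#'
#' Backpropagates an output gradient through the cached forward pass,
#' returning the gradient with respect to the input and every learnable
#' parameter.
#'
#' @param net An `RDNParams` object.
#' @param cache Cache from `rdn_forward(..., keep_cache = TRUE)`.
#' @param dy Gradient with respect to the output (array like `y`).
#' @return List with `dx` (gradient w.r.t. the input) and `grads` (named
#'   like `net$layers`, each with `dw`, `db`).
#' @export
rdn_backward <- function(net, cache, dy) {
  cfg <- net$config; p <- net$layers
  grads <- list()

  bw <- cpp_conv2d_bwd(cache$fout, p$recon$w, dy, 3L)
  grads$recon <- list(dw = bw$dw, db = bw$db)
  d_fout <- bw$dx

  if (cfg$scale > 1) {
    d_u <- .pixel_unshuffle(d_fout, cfg$scale)
    bw <- cpp_conv2d_bwd(cache$f, p$up$w, d_u, 3L)
    grads$up <- list(dw = bw$dw, db = bw$db)
    d_f <- bw$dx
  } else {
    d_f <- d_fout
  }

  # f = g2 + f1 (global residual)
  d_f1 <- d_f
  bw <- cpp_conv2d_bwd(cache$g1, p$gff2$w, d_f, 3L)
  grads$gff2 <- list(dw = bw$dw, db = bw$db)
  bw <- cpp_conv2d_bwd(cache$gff_in, p$gff1$w, bw$dx, 1L)
  grads$gff1 <- list(dw = bw$dw, db = bw$db)
  d_block_outs <- .split3(bw$dx, rep(cfg$G0, cfg$D))

  d_carry <- 0
  for (d in rev(seq_len(cfg$D))) {
    d_out <- d_block_outs[[d]] + d_carry
    bc <- cache$blocks[[d]]
    nm <- sprintf("b%dlff", d)
    bw <- cpp_conv2d_bwd(bc$lff_in, p[[nm]]$w, d_out, 1L)
    grads[[nm]] <- list(dw = bw$dw, db = bw$db)
    parts <- .split3(bw$dx, c(cfg$G0, rep(cfg$G, cfg$C)))
    d_x0 <- d_out + parts[[1]]          # local residual + fused-feature path
    d_act <- parts[-1]
    for (cc in rev(seq_len(cfg$C))) {
      dz <- d_act[[cc]] * (bc$zs[[cc]] > 0)
      nm <- sprintf("b%dc%d", d, cc)
      bw <- cpp_conv2d_bwd(bc$ins[[cc]], p[[nm]]$w, dz, 3L)
      grads[[nm]] <- list(dw = bw$dw, db = bw$db)
      parts_in <- .split3(bw$dx, c(cfg$G0, rep(cfg$G, cc - 1L)))
      d_x0 <- d_x0 + parts_in[[1]]
      if (cc > 1) for (j in seq_len(cc - 1L)) {
        d_act[[j]] <- d_act[[j]] + parts_in[[j + 1L]]
      }
    }
    d_carry <- d_x0
  }

  bw <- cpp_conv2d_bwd(cache$f1, p$sfe2$w, d_carry, 3L)
  grads$sfe2 <- list(dw = bw$dw, db = bw$db)
  d_f1 <- d_f1 + bw$dx
  bw <- cpp_conv2d_bwd(cache$x, p$sfe1$w, d_f1, 3L)
  grads$sfe1 <- list(dw = bw$dw, db = bw$db)
  list(dx = bw$dx, grads = grads)
}
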