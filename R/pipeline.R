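#' Default end-to-end run configuration
#'
#' The configuration drives [run_pipeline()]: phantom generation,
#' degradation, vessel enhancement, training, reconstruction, evaluation
#' and sO2 estimation. Values here are the desk-scale study conditions; any
#' field can be overridden, including from a YAML file via
#' [read_run_config()].
#'
#' @param n_scenes Number of phantom scenes.
#' @param field_size Scene size in pixels.
#' @param train_fraction Fraction of scenes used for training.
#' @param f,s,noise_sigma Degradation parameters (energy fraction,
#'   undersampling factor, noise SD).
#' @param D,C,G,G0 Subnetwork architecture profile.
#' @param loss_weights Multisupervision weights `(w1, w2, w3)`.
#' @param steps,lr,batch Training schedule.
#' @param patch_lr Low-resolution patch side for training and inference.
#' @param so2_threshold Mask threshold for the sO2 stage.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for artifacts.
#' @return A `RunConfig` list.
#' @export
run_config <- function(n_scenes = 8L, field_size = c(96L, 96L),
                       train_fraction = 0.75, f = 0.5, s = 2L,
                       noise_sigma = 0.05, D = 4L, C = 4L, G = 16L,
                       G0 = 32L, loss_weights = c(0.25, 0.25, 0.5),
                       steps = 200L, lr = 1e-3, batch = 2L, patch_lr = 32L,
                       so2_threshold = 0.1, seed = 1L,
                       out_dir = tempfile("mtrdn_run_")) {
  cfg <- as.list(environment())
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Fields found in the file override the defaults of [run_config()].
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in names(y)) base[[nm]] <- y[[nm]]
  base
}

#' Run the full pipeline: simulate, degrade, enhance, train, reconstruct,
#' evaluate, unmix
#'
#' Executes every stage in order, writes intermediate artifacts (TIFF
#' images, checkpoint, JSON logs) under `config$out_dir`, and returns a
#' manifest with file hashes, seeds and the evaluation metrics, sufficient
#' to re-run the pipeline reproducibly.
#'
#' @param config A `RunConfig`.
#' @param verbose Print stage progress as line-delimited JSON.
#' @return The run manifest (also written to `manifest.json`): list with
#'   `stages` (per-stage outputs and file hashes), `seeds`, and `metrics`
#'   (mean +/- SD PSNR/SSIM for recon1/2/3 against ground truths 1/2/3 and
#'   the nearest-neighbor baseline against ground truth 3).
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (verbose) cat(jsonlite::toJSON(c(list(stage = stage), list(...)),
                                      auto_unbox = TRUE), "\n")
  }
  manifest <- list(seeds = list(master = config$seed), stages = list())
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  # --- simulate ---------------------------------------------------------
  say("simulate", n = config$n_scenes)
  scenes <- lapply(seq_len(config$n_scenes), function(k) {
    tree <- generate_vessel_tree(seed = config$seed + 100L + k,
                                 field_size = config$field_size)
    rasterize_scene(tree)
  })
  for (k in seq_along(scenes)) {
    write_scene(scenes[[k]],
                keep(file.path(config$out_dir, sprintf("scene_%02d.tif", k))),
                params = list(seed = config$seed + 100L + k))
  }
  sp <- split_scenes(scenes, config$train_fraction, config$seed + 7L)
  manifest$stages$simulate <- list(n_train = length(sp$train),
                                   n_test = length(sp$test))

  # --- degrade + enhance (built into the patch set) ---------------------
  spec <- degradation_spec(config$f, config$s, config$noise_sigma,
                           config$seed + 200L)
  say("degrade", f = spec$f, s = spec$s)
  pset <- make_patch_set(sp$train, spec, patch_lr = config$patch_lr)
  manifest$stages$degrade <- list(f = spec$f, s = spec$s,
                                  noise_sigma = spec$noise_sigma,
                                  dosage_reduction =
                                    compute_dosage_reduction(spec$f, spec$s))
  manifest$stages$enhance <- list(n_patches = length(pset$input1))

  # --- train ------------------------------------------------------------
  say("train", steps = config$steps)
  params0 <- mtrdn_params(scale = config$s, D = config$D, C = config$C,
                          G = config$G, G0 = config$G0,
                          loss_weights = config$loss_weights,
                          seed = config$seed + 300L)
  state <- train_model(pset, params0, steps = config$steps, lr = config$lr,
                       batch = config$batch, seed = config$seed + 400L,
                       verbose = verbose)
  ckpt <- keep(file.path(config$out_dir, "model.ckpt"))
  save_checkpoint(state$params, ckpt)
  utils::write.csv(state$loss_history,
                   keep(file.path(config$out_dir, "loss_history.csv")),
                   row.names = FALSE)
  manifest$stages$train <- list(steps = state$step,
                                final_loss =
                                  state$loss_history$loss[state$step])

  # --- reconstruct + evaluate on held-out scenes ------------------------
  say("reconstruct", n_test = length(sp$test))
  vparams <- vesselness_params()
  recs <- list(r1 = list(), r2 = list(), r3 = list(), base = list())
  gts <- list(g1 = list(), g2 = list(), g3 = list())
  for (k in seq_along(sp$test)) {
    sc <- sp$test[[k]]
    spec_k <- degradation_spec(spec$f, spec$s, spec$noise_sigma,
                               config$seed + 500L + 2L * k)
    pair <- degrade_scene(sc, spec_k)
    rc <- reconstruct(state$params, pair$input1, pair$input2,
                      patch = config$patch_lr)
    recs$r1[[k]] <- rc$recon1; recs$r2[[k]] <- rc$recon2
    recs$r3[[k]] <- rc$recon3
    recs$base[[k]] <- upsample_nearest(pair$input1, spec$s)
    gts$g1[[k]] <- sc$gt532; gts$g2[[k]] <- sc$gt560
    gts$g3[[k]] <- make_ground_truth3(sc$gt532, vparams)
    tiff::writeTIFF(pmin(pmax(rc$recon3, 0), 1),
                    keep(file.path(config$out_dir,
                                   sprintf("recon3_%02d.tif", k))))
  }
  manifest$stages$reconstruct <- list(n_test = length(sp$test),
                                      out_shape = dim(recs$r3[[1]]))
  rep1 <- metrics_report(gts$g1, recs$r1)
  rep2 <- metrics_report(gts$g2, recs$r2)
  rep3 <- metrics_report(gts$g3, recs$r3)
  repb <- metrics_report(gts$g3, recs$base)
  manifest$metrics <- list(
    recon1 = list(psnr_mean = rep1$psnr_mean, psnr_sd = rep1$psnr_sd,
                  ssim_mean = rep1$ssim_mean, ssim_sd = rep1$ssim_sd),
    recon2 = list(psnr_mean = rep2$psnr_mean, psnr_sd = rep2$psnr_sd,
                  ssim_mean = rep2$ssim_mean, ssim_sd = rep2$ssim_sd),
    recon3 = list(psnr_mean = rep3$psnr_mean, psnr_sd = rep3$psnr_sd,
                  ssim_mean = rep3$ssim_mean, ssim_sd = rep3$ssim_sd),
    baseline_nn_input1 = list(psnr_mean = repb$psnr_mean,
                              ssim_mean = repb$ssim_mean),
    n_test = rep3$n)
  manifest$stages$evaluate <- manifest$metrics

  # --- so2 --------------------------------------------------------------
  say("so2")
  sc <- sp$test[[1]]
  so2 <- unmix_so2(sc$gt532, sc$gt560)
  so2map <- apply_mask(so2, recs$r3[[1]], config$so2_threshold, "recon3")
  write_so2(so2map, keep(file.path(config$out_dir, "so2.tif")))
  manifest$stages$so2 <- list(threshold = config$so2_threshold,
                              n_defined = sum(so2map$mask))

  manifest$files <- as.list(tools::md5sum(artifacts))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
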