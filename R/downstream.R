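# Downstream generative-augmentation experiment: train Baseline / Synthetic
# / Enhanced segmentation models and compare them on in-distribution and
# out-of-distribution test sets with the evaluation module.

#' Segmenter configuration
#'
#' A small pixelwise-classification U-Net (two downsamplings) over all C
#' bands — the desk-scale stand-in for a full surgical HSI segmentation
#' architecture.
#'
#' @param widths Channel widths per level (length 3 = two downsamplings).
#' @param n_steps Training steps.
#' @param batch_size,lr Optimizer settings.
#' @param seed Integer seed (initialization and batch order).
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(widths = c(12L, 20L, 28L), n_steps = 350L,
                             batch_size = 4L, lr = 4e-3, seed = 1L) {
  structure(
    list(widths = as.integer(widths), n_steps = as.integer(n_steps),
         batch_size = as.integer(batch_size), lr = lr, seed = as.integer(seed)),
    class = "segmenter_config"
  )
}

#' Train the toy segmentation model
#'
#' Pixelwise softmax cross-entropy over the known classes; fill-label pixels
#' (augmentation voids) are excluded from the loss. Deterministic given the
#' seed.
#'
#' @param dataset List of scenes `list(cube, mask, ...)`.
#' @param n_classes Number of output classes (max known label id + 1).
#' @param config A [segmenter_config()].
#' @return A trained `hsi_segmenter` with a training-loss log.
#' @export
train_segmenter <- function(dataset, n_classes, config = segmenter_config()) {
  if (length(dataset) == 0L) {
    abort_hsi("dataset is empty", "hsisynth_validation_error")
  }
  arrays <- lapply(dataset, cube_array)
  d <- dim(arrays[[1]])
  n_img <- length(arrays)
  masks <- lapply(dataset, function(s) scene_field(s, "mask")$labels)
  K <- as.integer(n_classes)
  net <- unet_init(d[3], K, config$widths, use_temb = FALSE,
                   zero_head = TRUE, seed = derive_seed(config$seed, 31))
  st <- adam_init(net$params)
  bs <- min(config$batch_size, n_img)
  log_loss <- numeric(config$n_steps)
  with_seed(derive_seed(config$seed, 32), {
    for (step in seq_len(config$n_steps)) {
      pick <- sample.int(n_img, bs, replace = bs > n_img)
      x <- array(unlist(arrays[pick]), c(d, bs))
      y <- array(unlist(masks[pick]), c(d[1], d[2], bs))
      fw <- unet_forward(net, x, keep_cache = TRUE)
      logits <- fw$y  # [H, W, K, bs]
      lm <- matrix(aperm(logits, c(1, 2, 4, 3)), d[1] * d[2] * bs, K)
      yv <- as.vector(y)
      valid <- yv < K  # fill labels (>= K) carry no loss
      lmax <- lm[cbind(seq_len(nrow(lm)), max.col(lm, ties.method = "first"))]
      ex <- exp(lm - lmax)
      Z <- rowSums(ex)
      prob <- ex / Z
      n_eff <- sum(valid)
      tgt_idx <- cbind(seq_len(nrow(lm)), yv + 1L)[valid, , drop = FALSE]
      loss <- -mean(log(pmax(prob[tgt_idx], 1e-12)))
      if (!is.finite(loss)) {
        abort_hsi("segmenter training diverged (non-finite loss)",
                  "hsisynth_generation_error")
      }
      log_loss[step] <- loss
      dlm <- prob
      dlm[tgt_idx] <- dlm[tgt_idx] - 1
      dlm[!valid, ] <- 0
      dlm <- dlm / n_eff
      dlogits <- aperm(array(dlm, c(d[1], d[2], bs, K)), c(1, 2, 4, 3))
      bk <- unet_backward(net, fw$cache, dlogits)
      up <- adam_step(net$params, bk$grads, st, lr = config$lr)
      net$params <- up$params; st <- up$state
    }
  })
  structure(
    list(net = net, n_classes = K, config = config,
         log = data.frame(step = seq_len(config$n_steps), loss = log_loss)),
    class = "hsi_segmenter"
  )
}

#' Predict a label map
#'
#' @param model A trained `hsi_segmenter`.
#' @param cube An [hsi_cube()] or H x W x C array.
#' @return Integer H x W matrix of predicted label ids.
#' @export
predict_segmenter <- function(model, cube) {
  x <- cube_array(cube)
  d <- dim(x)
  fw <- unet_forward(model$net, array(x, c(d, 1L)))
  onehot_argmax(array(fw$y, dim(fw$y)[1:3]))
}

#' Generate a synthetic labeled training set
#'
#' One guided-diffusion sample per conditioning mask; the conditioning mask
#' itself is the pair's ground-truth label (the construction that makes
#' generative augmentation label-exact). Masks should already be
#' preprocessed with [reassign_ood_labels()]. Seeds are derived per image
#' from `config$seed` and recorded in each scene.
#'
#' @param dm,ae Trained diffusion model and autoencoder.
#' @param masks List of [semantic_mask()]s.
#' @param config A [sampler_config()].
#' @return List of scenes `list(cube, mask, subject_id, seed)`.
#' @export
generate_synthetic_trainset <- function(dm, ae, masks,
                                        config = sampler_config()) {
  purrr::imap(masks, function(m, i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, 41, i)
    cube <- sample_cube(dm, ae, m, cfg_i,
                        subject_id = sprintf("synth%03d", i))
    list(cube = cube, mask = m, subject_id = sprintf("synth%03d", i),
         seed = cfg_i$seed)
  })
}

#' Experiment plan for the three-arm augmentation study
#'
#' @param real_train Real labeled scenes (the Baseline training set).
#' @param conditioning_masks Masks used to synthesize images (already
#'   preprocessed with [reassign_ood_labels()]).
#' @param test_sets Named list of test scene lists (e.g. `ID`, `occlusion`,
#'   `isolation`, `blur`).
#' @param n_classes Known classes of the segmentation task.
#' @param segmenter A [segmenter_config()].
#' @param sampler A [sampler_config()].
#' @param eval A [eval_config()].
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(real_train, conditioning_masks, test_sets,
                            n_classes, segmenter = segmenter_config(),
                            sampler = sampler_config(), eval = eval_config()) {
  structure(
    list(real_train = real_train, conditioning_masks = conditioning_masks,
         test_sets = test_sets, n_classes = n_classes,
         segmenter = segmenter, sampler = sampler, eval = eval),
    class = "experiment_plan"
  )
}

#' Run the three-arm generative-augmentation experiment
#'
#' Trains (i) Baseline on the real scenes only, (ii) Synthetic on the same
#' number of synthetic scenes only, and (iii) Enhanced on real plus all
#' synthetic scenes; evaluates DSC and NSD per class on every test set with
#' hierarchical aggregation; and computes subject-level bootstrap CIs for
#' Enhanced-Baseline and Synthetic-Baseline. One seed drives all arms so
#' differences are not confounded by initialization draws.
#'
#' @param plan An [experiment_plan()].
#' @param dm,ae Trained diffusion model and autoencoder (unused when
#'   `synthetic` is supplied).
#' @param synthetic Optional pre-generated synthetic scenes (from
#'   [generate_synthetic_trainset()] on `plan$conditioning_masks`), so that
#'   seed replicates of the segmenter need not re-run the sampler.
#' @return An `hsi_experiment`: list with `results` (per arm/test
#'   set/class aggregated metrics), `ci` (bootstrap difference intervals),
#'   `boost` (relative Enhanced-vs-Baseline boost per test set and metric),
#'   and the per-arm record tables.
#' @export
run_experiment <- function(plan, dm = NULL, ae = NULL, synthetic = NULL) {
  synth_all <- synthetic %||%
    generate_synthetic_trainset(dm, ae, plan$conditioning_masks, plan$sampler)
  n_real <- length(plan$real_train)
  if (length(synth_all) < n_real) {
    abort_hsi("need at least as many conditioning masks as real images",
              "hsisynth_validation_error")
  }
  arms <- list(
    Baseline = plan$real_train,
    Synthetic = synth_all[seq_len(n_real)],  # same count as the real set
    Enhanced = c(plan$real_train, synth_all)
  )
  class_ids <- seq_len(plan$n_classes) - 1L
  records <- list()
  for (arm in names(arms)) {
    model <- train_segmenter(arms[[arm]], plan$n_classes, plan$segmenter)
    for (ts in names(plan$test_sets)) {
      scenes <- plan$test_sets[[ts]]
      preds <- lapply(scenes, function(s) predict_segmenter(model, s$cube))
      rec <- metric_records(preds, scenes, class_ids, plan$eval)
      rec$arm <- arm
      rec$test_set <- ts
      records[[paste(arm, ts)]] <- rec
    }
  }
  rec_all <- dplyr::bind_rows(records)
  results <- rec_all |>
    dplyr::group_by(.data$arm, .data$test_set) |>
    dplyr::group_modify(~ hierarchical_aggregate(.x)) |>
    dplyr::ungroup()
  ci <- dplyr::bind_rows(lapply(names(plan$test_sets), function(ts) {
    base <- rec_all[rec_all$arm == "Baseline" & rec_all$test_set == ts, ]
    dplyr::bind_rows(lapply(c("Enhanced", "Synthetic"), function(arm) {
      other <- rec_all[rec_all$arm == arm & rec_all$test_set == ts, ]
      out <- bootstrap_ci_difference(other, base, plan$eval)
      out$comparison <- paste0(arm, "-Baseline")
      out$test_set <- ts
      out
    }))
  }))
  pooled <- results |>
    dplyr::group_by(.data$arm, .data$test_set, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value")
  boost <- pooled |>
    dplyr::mutate(relative_boost = (.data$Enhanced - .data$Baseline) /
                    .data$Baseline) |>
    dplyr::select("test_set", "metric", "Baseline", "Synthetic", "Enhanced",
                  "relative_boost")
  structure(
    list(results = results, ci = ci, boost = boost, records = rec_all),
    class = "hsi_experiment"
  )
}

#' @export
print.hsi_experiment <- function(x, ...) {
  cat("<hsi_experiment>\n")
  print(x$boost)
  invisible(x)
}
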