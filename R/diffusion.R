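# Mask-conditioned diffusion in latent space: variance-preserving forward
# noising, epsilon-prediction U-Net training with condition dropout (for
# classifier-free guidance), deterministic DDIM sampling, and zero-padding of
# non-quadratic latents so every downsampling level sees even resolutions.

#' Linear variance schedule for the forward diffusion process
#'
#' Betas rise linearly from `beta1` to `betaT` (defaults `1e-4` to `2e-2`
#' over `T = 1000` steps, the standard DDPM schedule); `alpha_bars` is the
#' cumulative product of `1 - beta`, strictly decreasing in (0, 1].
#'
#' @param T_steps Number of diffusion steps (>= 2).
#' @param kind Schedule family; only `"linear"` is provided.
#' @param beta1,betaT First and last beta.
#' @return A `noise_schedule`: list with `T`, `betas`, `alpha_bars`.
#' @examples
#' sch <- make_schedule(1000)
#' sch$alpha_bars[1000] < 0.01
#' @export
make_schedule <- function(T_steps = 1000L, kind = c("linear"),
                          beta1 = 1e-4, betaT = 2e-2) {
  kind <- match.arg(kind)
  if (!is_count(T_steps) || T_steps < 2) {
    abort_hsi("T_steps must be an integer >= 2", "hsisynth_config_error")
  }
  betas <- seq(beta1, betaT, length.out = T_steps)
  if (any(betas <= 0) || any(betas >= 1)) {
    abort_hsi("betas must lie in (0, 1)", "hsisynth_config_error")
  }
  structure(
    list(T = as.integer(T_steps), betas = betas,
         alpha_bars = cumprod(1 - betas)),
    class = "noise_schedule"
  )
}

#' Forward diffusion step
#'
#' Closed-form jump to timestep `t`:
#' `z_t = sqrt(abar_t) * z0 + sqrt(1 - abar_t) * eps`. Variance-preserving:
#' unit-variance `z0` and `eps` give unit-variance `z_t` at every `t`.
#'
#' @param z0 Clean latent array (any shape).
#' @param t Timestep in 1..T.
#' @param eps Noise array, same shape as `z0`.
#' @param schedule A [make_schedule()].
#' @return Noised array `z_t`.
#' @export
forward_diffuse <- function(z0, t, eps, schedule) {
  if (t < 1 || t > schedule$T) {
    abort_hsi("t out of schedule range", "hsisynth_config_error")
  }
  ab <- schedule$alpha_bars[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

#' Pad a latent to even downsampling resolutions
#'
#' Zero-pads the spatial dims up to the next multiple of `2^d` (bottom/right)
#' and records the crop box; `crop_latent(pad_latent(x))` is the identity.
#' Needed because the denoiser halves the resolution `d` times.
#'
#' @param latent h x w x c array (or `hsi_latent`).
#' @param d Number of downsampling levels.
#' @return List with `values` (padded array) and `crop` (`c(h, w)` original
#'   dims).
#' @export
pad_latent <- function(latent, d) {
  z <- if (inherits(latent, "hsi_latent")) latent$values else latent
  dm <- dim(z)
  mult <- 2L^as.integer(d)
  ph <- (mult - dm[1] %% mult) %% mult
  pw <- (mult - dm[2] %% mult) %% mult
  out <- array(0, c(dm[1] + ph, dm[2] + pw, dm[3]))
  out[seq_len(dm[1]), seq_len(dm[2]), ] <- z
  list(values = out, crop = dm[1:2])
}

#' @rdname pad_latent
#' @param padded Output of [pad_latent()] or a padded array.
#' @param crop Original `c(h, w)` dims (taken from `padded$crop` if present).
#' @export
crop_latent <- function(padded, crop = NULL) {
  if (is.list(padded) && !is.null(padded$crop)) {
    crop <- padded$crop
    padded <- padded$values
  }
  padded[seq_len(crop[1]), seq_len(crop[2]), , drop = FALSE]
}

#' Encode a one-hot mask into a condition tensor
#'
#' The conditioning pathway of the diffusion model: a simple nearest-neighbor
#' spatial rescale of the one-hot stack to the (padded) latent resolution
#' followed by a single learned 1x1 convolution to `c_cond` channels. The
#' result is concatenated to `z_t` at every denoising step. Nearest-neighbor
#' is used so label identity is never interpolated.
#'
#' @param onehot H x W x K one-hot array (see [one_hot()]).
#' @param target_hw Target `c(h, w)` spatial dims.
#' @param Wc K x c_cond weight matrix of the condition convolution.
#' @param bc Length-`c_cond` bias.
#' @return h x w x c_cond condition tensor.
#' @export
encode_condition <- function(onehot, target_hw, Wc, bc) {
  d <- dim(onehot)
  if (d[3] != nrow(Wc)) {
    abort_hsi("one-hot class count does not match condition weights",
              "hsisynth_shape_error")
  }
  res <- nn_rescale(onehot, target_hw)
  h <- dim(res)[1]; w <- dim(res)[2]
  m <- matrix(res, h * w, d[3])
  out <- sweep(m %*% Wc, 2L, bc, "+")
  array(out, c(h, w, ncol(Wc)))
}

# Nearest-neighbor spatial rescale of an H x W x K array.
nn_rescale <- function(x, target_hw) {
  d <- dim(x)
  if (d[1] == target_hw[1] && d[2] == target_hw[2]) return(x)
  ri <- pmin(d[1], floor(((seq_len(target_hw[1]) - 0.5) * d[1]) / target_hw[1]) + 1L)
  ci <- pmin(d[2], floor(((seq_len(target_hw[2]) - 0.5) * d[2]) / target_hw[2]) + 1L)
  x[ri, ci, , drop = FALSE]
}

#' Combine conditional and unconditional noise predictions
#'
#' Classifier-free guidance:
#' `eps_hat = eps_uncond + lambda * (eps_cond - eps_uncond)`. `lambda = 1`
#' returns the conditional prediction unchanged; `lambda = 2` (the package
#' default for sampling) doubles the push toward the condition.
#'
#' @param eps_cond,eps_uncond Same-shape arrays.
#' @param lambda_cfg Guidance scale (>= 0).
#' @return Guided noise prediction.
#' @export
cfg_combine <- function(eps_cond, eps_uncond, lambda_cfg) {
  if (lambda_cfg == 1) return(eps_cond)  # exact identity, no rounding
  eps_uncond + lambda_cfg * (eps_cond - eps_uncond)
}

#' One deterministic DDIM update
#'
#' Estimates the clean latent
#' `x0_hat = (z_t - sqrt(1 - abar_t) * eps_hat) / sqrt(abar_t)` and moves to
#' `t_prev`: `z = sqrt(abar_prev) * x0_hat + sqrt(1 - abar_prev) * eps_hat`
#' at `eta = 0`; `eta > 0` replaces part of the deterministic direction with
#' seeded fresh noise. `abar_0` is defined as 1, so `t_prev = 0` returns
#' `x0_hat`.
#'
#' @param z_t Current latent array.
#' @param eps_hat Noise prediction, same shape.
#' @param t,t_prev Current and target timesteps, `t > t_prev >= 0`.
#' @param schedule A [make_schedule()].
#' @param eta Stochasticity in `[0, 1]` (0 = deterministic).
#' @param seed Seed for the `eta > 0` noise.
#' @return Latent at `t_prev`.
#' @export
ddim_step <- function(z_t, eps_hat, t, t_prev, schedule, eta = 0, seed = 1L) {
  if (!(t > t_prev && t_prev >= 0)) {
    abort_hsi("ddim_step requires t > t_prev >= 0", "hsisynth_config_error")
  }
  ab_t <- schedule$alpha_bars[t]
  ab_p <- if (t_prev == 0) 1 else schedule$alpha_bars[t_prev]
  x0 <- (z_t - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
  if (eta == 0) {
    sqrt(ab_p) * x0 + sqrt(1 - ab_p) * eps_hat
  } else {
    sigma <- eta * sqrt((1 - ab_p) / (1 - ab_t)) * sqrt(1 - ab_t / ab_p)
    dirc <- sqrt(pmax(1 - ab_p - sigma^2, 0)) * eps_hat
    noise <- with_seed(seed, array(stats::rnorm(length(z_t)), dim(z_t)))
    sqrt(ab_p) * x0 + dirc + sigma * noise
  }
}

#' Diffusion model configuration
#'
#' @param c_cond Condition tensor channels.
#' @param p_drop Condition dropout probability during training (the
#'   unconditional passes required by classifier-free guidance).
#' @param n_steps Training steps.
#' @param batch_size,lr Optimizer settings.
#' @param widths U-Net channel widths per level (length = number of levels;
#'   `length - 1` downsamplings).
#' @param lr_decay Factor the learning rate decays to (geometrically) over
#'   the run.
#' @param T_steps Diffusion steps of the training schedule.
#' @param seed Integer seed.
#' @return A `dm_config` list.
#' @export
dm_config <- function(c_cond = 4L, p_drop = 0.1, n_steps = 3000L,
                      batch_size = 8L, lr = 2e-3, widths = c(16L, 32L),
                      lr_decay = 0.1, T_steps = 1000L, seed = 1L) {
  if (p_drop < 0 || p_drop >= 1) {
    abort_hsi("p_drop must be in [0, 1)", "hsisynth_config_error")
  }
  structure(
    list(c_cond = as.integer(c_cond), p_drop = p_drop,
         n_steps = as.integer(n_steps), batch_size = as.integer(batch_size),
         lr = lr, widths = as.integer(widths), lr_decay = lr_decay,
         T_steps = as.integer(T_steps), seed = as.integer(seed)),
    class = "dm_config"
  )
}

#' Sampler configuration
#'
#' @param steps DDIM steps (default 100, a uniform sub-sequence of the
#'   training schedule).
#' @param lambda_cfg Guidance scale (default 2).
#' @param eta DDIM stochasticity (default 0: deterministic).
#' @param seed Integer seed.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(steps = 100L, lambda_cfg = 2, eta = 0, seed = 1L) {
  if (eta < 0 || eta > 1) {
    abort_hsi("eta must be in [0, 1]", "hsisynth_config_error")
  }
  if (lambda_cfg < 0) {
    abort_hsi("lambda_cfg must be >= 0", "hsisynth_config_error")
  }
  structure(
    list(steps = as.integer(steps), lambda_cfg = lambda_cfg, eta = eta,
         seed = as.integer(seed)),
    class = "sampler_config"
  )
}

# Uniformly spaced DDIM timestep sub-sequence of [1, T], including T,
# descending.
ddim_timesteps <- function(T_steps, n) {
  n <- min(n, T_steps)
  ts <- unique(round(seq(T_steps, 1, length.out = n)))
  sort(ts, decreasing = TRUE)
}

#' Predict noise with the denoiser
#'
#' Runs the U-Net on the channel concatenation of `z_t` and the condition
#' tensor (an all-zeros tensor is the designated null condition of
#' classifier-free guidance). Deterministic given the weights; with the
#' zero-initialized output head an untrained model predicts exactly zero.
#'
#' @param dm A trained `hsi_dm` (or its `net`).
#' @param z_t h x w x c_lat latent array (padded as the model requires).
#' @param condition h x w x c_cond condition tensor or `NULL` for the null
#'   condition.
#' @param t Timestep (scalar).
#' @return eps_hat array, same shape as `z_t`.
#' @export
denoise_predict <- function(dm, z_t, condition = NULL, t) {
  net <- if (inherits(dm, "hsisynth_unet")) dm else dm$net
  d <- dim(z_t)
  if (is.null(condition)) {
    condition <- array(0, c(d[1], d[2], net$c_in - d[3]))
  }
  if (!all(dim(condition)[1:2] == d[1:2])) {
    abort_hsi("condition tensor spatial dims must match z_t", "hsisynth_shape_error")
  }
  x <- array(c(z_t, condition), c(d[1], d[2], d[3] + dim(condition)[3], 1L))
  y <- unet_forward(net, x, tvec = t)$y
  array(y, dim(z_t))
}

#' Train the mask-conditioned diffusion model
#'
#' Epsilon-prediction objective on standardized AE latents: each step draws a
#' minibatch of scenes, a uniform timestep per sample, fresh noise, and
#' minimizes the mean squared error between the drawn noise and the U-Net
#' prediction given `z_t` concatenated with the encoded mask condition. With
#' probability `p_drop` a sample's condition tensor is replaced by the null
#' (all-zeros) condition so the model also learns the unconditional score.
#' The condition convolution is trained jointly.
#'
#' @param ae A trained `hsi_ae` (frozen here).
#' @param dataset List of scenes `list(cube, mask, ...)`.
#' @param config A [dm_config()].
#' @param schedule Optional [make_schedule()]; built from `config$T_steps`
#'   when `NULL`.
#' @param n_classes Number of one-hot channels; defaults to the number of
#'   legend entries of the first mask.
#' @return A trained `hsi_dm`: list with the U-Net, condition weights, the
#'   schedule, configs and a training log.
#' @export
train_dm <- function(ae, dataset, config = dm_config(), schedule = NULL,
                     n_classes = NULL) {
  if (is.null(schedule)) schedule <- make_schedule(config$T_steps)
  if (is.null(n_classes)) {
    n_classes <- max(dataset[[1]]$mask$legend$ids) + 1L
  }
  L <- length(config$widths)
  d_down <- L - 1L
  # precompute standardized latents (posterior means; frozen encoder) and
  # one-hot masks rescaled to the padded latent grid
  lat <- lapply(dataset, function(sc) {
    post <- encode(ae, sc$cube)
    pad_latent(post$mean * ae$scale_factor, d_down)
  })
  crop <- lat[[1]]$crop
  z0_all <- lapply(lat, `[[`, "values")
  dz <- dim(z0_all[[1]])
  oh_all <- lapply(dataset, function(sc) {
    oh <- one_hot(sc$mask, n_classes)
    nn_rescale(oh, dz[1:2])
  })
  n_img <- length(dataset)
  c_lat <- dz[3]; c_cond <- config$c_cond
  net <- unet_init(c_lat + c_cond, c_lat, config$widths,
                   seed = derive_seed(config$seed, 11))
  cond_par <- with_seed(derive_seed(config$seed, 12), list(
    Wc = init_mat(n_classes, c_cond, sqrt(1 / n_classes)),
    bc = numeric(c_cond)
  ))
  st <- adam_init(net$params)
  st_c <- adam_init(cond_par)
  bs <- config$batch_size
  log_loss <- numeric(config$n_steps)
  drop_count <- 0L
  with_seed(derive_seed(config$seed, 13), {
    for (step in seq_len(config$n_steps)) {
      pick <- sample.int(n_img, bs, replace = bs > n_img)
      tvec <- sample.int(schedule$T, bs, replace = TRUE)
      z0 <- array(unlist(z0_all[pick]), c(dz, bs))
      eps <- array(stats::rnorm(length(z0)), dim(z0))
      ab <- schedule$alpha_bars[tvec]
      sab <- rep(sqrt(ab), each = prod(dz))
      s1ab <- rep(sqrt(1 - ab), each = prod(dz))
      zt <- sab * z0 + s1ab * eps
      ohb <- array(unlist(oh_all[pick]), c(dz[1], dz[2], n_classes, bs))
      dropped <- stats::runif(bs) < config$p_drop
      drop_count <- drop_count + sum(dropped)
      ohm <- matrix(aperm(ohb, c(1, 2, 4, 3)), dz[1] * dz[2] * bs, n_classes)
      condm <- sweep(ohm %*% cond_par$Wc, 2L, cond_par$bc, "+")
      cond <- aperm(array(condm, c(dz[1], dz[2], bs, c_cond)), c(1, 2, 4, 3))
      if (any(dropped)) cond[, , , dropped] <- 0
      x <- array(0, c(dz[1], dz[2], c_lat + c_cond, bs))
      x[, , seq_len(c_lat), ] <- zt
      x[, , c_lat + seq_len(c_cond), ] <- cond
      lr_step <- config$lr *
        (config$lr_decay %||% 0.1)^((step - 1) / config$n_steps)
      fw <- unet_forward(net, x, tvec = tvec, keep_cache = TRUE)
      diffa <- fw$y - eps
      loss <- mean(diffa^2)
      if (!is.finite(loss)) {
        abort_hsi("diffusion training diverged (non-finite loss)",
                  "hsisynth_generation_error")
      }
      log_loss[step] <- loss
      bk <- unet_backward(net, fw$cache, 2 * diffa / length(diffa))
      up <- adam_step(net$params, bk$grads, st, lr = lr_step)
      net$params <- up$params; st <- up$state
      # gradient into the condition channels trains the condition conv
      dcond <- bk$dx[, , c_lat + seq_len(c_cond), , drop = FALSE]
      if (any(dropped)) dcond[, , , dropped] <- 0
      dcondm <- matrix(aperm(dcond, c(1, 2, 4, 3)), nrow(ohm), c_cond)
      gW <- crossprod(ohm, dcondm)
      gb <- colSums(dcondm)
      upc <- adam_step(cond_par, list(Wc = gW, bc = gb), st_c, lr = lr_step)
      cond_par <- upc$params; st_c <- upc$state
    }
  })
  structure(
    list(net = net, cond = cond_par, schedule = schedule, config = config,
         n_classes = n_classes, c_lat = c_lat, crop = crop,
         latent_hw = dz[1:2],
         log = data.frame(step = seq_len(config$n_steps), loss = log_loss),
         drop_fraction = drop_count / (config$n_steps * bs)),
    class = "hsi_dm"
  )
}

#' Synthesize a hyperspectral cube from a semantic mask
#'
#' Full guided DDIM sampling: start from seeded standard-normal `z_T`,
#' iterate over a uniformly spaced timestep sub-sequence with two denoiser
#' evaluations per step (conditioned and null-conditioned) combined by
#' [cfg_combine()], then unscale by the AE `scale_factor`, decode, crop and
#' clip at zero. Deterministic given the seed at `eta = 0`.
#'
#' @param dm A trained `hsi_dm`.
#' @param ae The `hsi_ae` the latents came from.
#' @param mask A [semantic_mask()] at cube resolution.
#' @param config A [sampler_config()].
#' @param wavelengths Wavelength axis for the output cube; defaults to an
#'   even 500-1000 nm grid.
#' @param subject_id Provenance tag for the synthetic cube.
#' @return An [hsi_cube()] with the geometry of `mask`.
#' @export
sample_cube <- function(dm, ae, mask, config = sampler_config(),
                        wavelengths = NULL, subject_id = "synthetic") {
  if (is.null(dm$net)) {
    abort_hsi("diffusion model is not trained", "hsisynth_validation_error")
  }
  oh <- one_hot(mask, dm$n_classes)
  oh_l <- nn_rescale(oh, dm$latent_hw)
  hw <- dm$latent_hw
  cond <- encode_condition(oh_l, hw, dm$cond$Wc, dm$cond$bc)
  sch <- dm$schedule
  ts <- ddim_timesteps(sch$T, config$steps)
  z <- with_seed(derive_seed(config$seed, 21),
                 array(stats::rnorm(hw[1] * hw[2] * dm$c_lat),
                       c(hw[1], hw[2], dm$c_lat)))
  skip_uncond <- config$lambda_cfg == 1
  for (i in seq_along(ts)) {
    t <- ts[i]
    t_prev <- if (i < length(ts)) ts[i + 1] else 0L
    eps_c <- denoise_predict(dm, z, cond, t)
    eps_hat <- if (skip_uncond) eps_c else {
      eps_u <- denoise_predict(dm, z, NULL, t)
      cfg_combine(eps_c, eps_u, config$lambda_cfg)
    }
    z <- ddim_step(z, eps_hat, t, t_prev, sch, eta = config$eta,
                   seed = derive_seed(config$seed, 22, i))
  }
  z <- crop_latent(z, dm$crop)
  data <- decode(ae, z / ae$scale_factor)
  if (is.null(wavelengths)) {
    wavelengths <- seq(500, 1000, length.out = dim(data)[3])
  }
  hsi_cube(pmax(data, 0), wavelengths, subject_id = subject_id)
}

#' Save / load a diffusion checkpoint
#'
#' @param dm A trained `hsi_dm`.
#' @param path Destination file.
#' @return `path` invisibly; [load_dm()] returns the restored model.
#' @export
save_dm <- function(dm, path) {
  saveRDS(list(object = dm, r_version = R.version.string,
               package_version = as.character(utils::packageVersion("hsisynth"))),
          path)
  invisible(path)
}

#' @rdname save_dm
#' @export
load_dm <- function(path) readRDS(path)$object
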