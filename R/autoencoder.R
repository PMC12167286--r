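# KL-regularized variational autoencoder compressing cubes spatially (factor
# f) and spectrally (C -> latent_channels), trained with a pixelwise
# reconstruction loss only: no perceptual term (not applicable to
# hyperspectral data) and no adversarial term.
#
# The encoder is a single strided convolution (kernel f, stride f) onto
# 2*latent_channels maps (posterior mean and log-variance); the decoder is
# the mirrored transposed convolution. Phantom pixel spectra lie near a
# low-rank manifold spanned by the class reference spectra, so this linear
# pair already attains near-noise-floor reconstruction while keeping
# training cheap; the contract (shapes, losses, determinism) does not depend
# on the internals.

LOGVAR_MIN <- -30
LOGVAR_MAX <- 20

#' Autoencoder configuration
#'
#' @param spatial_factor Spatial downsampling factor f (a power of 2).
#' @param latent_channels Latent channel count.
#' @param lambda_kl KL regularization weight; kept small (default `1e-6`)
#'   since reconstruction quality benefits from weak regularization.
#' @param recon_loss `"L1"` (default) or `"L2"` pixelwise reconstruction loss.
#' @param epochs,batch_size,lr Training schedule.
#' @param seed Integer seed for init, shuffling and reparameterization noise.
#' @return An `ae_config` list.
#' @export
ae_config <- function(spatial_factor = 2L, latent_channels = 4L,
                      lambda_kl = 1e-6, recon_loss = c("L1", "L2"),
                      epochs = 60L, batch_size = 16L, lr = 3e-2, seed = 1L) {
  recon_loss <- match.arg(recon_loss)
  f <- as.integer(spatial_factor)
  if (f < 1L || bitwAnd(f, f - 1L) != 0L) {
    abort_hsi("spatial_factor must be a power of 2", "hsisynth_config_error")
  }
  if (!is_count(latent_channels)) {
    abort_hsi("latent_channels must be a positive integer", "hsisynth_config_error")
  }
  if (lambda_kl < 0) {
    abort_hsi("lambda_kl must be nonnegative", "hsisynth_config_error")
  }
  structure(
    list(spatial_factor = f, latent_channels = as.integer(latent_channels),
         lambda_kl = lambda_kl, recon_loss = recon_loss,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, seed = as.integer(seed)),
    class = "ae_config"
  )
}

cube_array <- function(x) {
  if (inherits(x, "hsi_cube")) x$data
  else if (is.list(x) && !is.null(x$cube)) x$cube$data
  else x
}

new_ae <- function(config, C, seed) {
  f <- config$spatial_factor
  cin <- f * f * C
  cl <- config$latent_channels
  with_seed(seed, {
    # log-variance bias starts low so early training is near-deterministic;
    # the KL term is free to raise it later
    structure(
      list(
        config = config, C = as.integer(C),
        We = init_mat(cin, 2L * cl, sqrt(1 / cin)),
        be = c(numeric(cl), rep(-6, cl)),
        Wd = init_mat(cl, cin, sqrt(1 / cl)),
        bd = numeric(cin),
        scale_factor = 1,
        log = NULL
      ),
      class = "hsi_ae"
    )
  })
}

ae_unfold <- function(ae, x) {
  d <- dim(x)
  f <- ae$config$spatial_factor
  if (d[1] %% f != 0L || d[2] %% f != 0L) {
    abort_hsi(
      sprintf("spatial dims (%d, %d) not divisible by factor %d; pad first",
              d[1], d[2], f),
      "hsisynth_shape_error"
    )
  }
  if (d[3] != ae$C) {
    abort_hsi("band count does not match the trained autoencoder",
              "hsisynth_shape_error")
  }
  info <- im2col_index(d[1], d[2], d[3], f, f, 0L)
  list(xcol = im2col(x, info), info = info, N = d[4])
}

#' Encode a cube into a latent posterior
#'
#' Applies the strided-convolution encoder and returns the diagonal-Gaussian
#' posterior over the latent: an h x w x latent_channels mean and
#' log-variance (h = H/f, w = W/f). Deterministic given the weights.
#'
#' @param ae A trained (or freshly initialized) `hsi_ae`.
#' @param cube An [hsi_cube()] or an H x W x C array with (H, W) divisible
#'   by the spatial factor.
#' @return An `hsi_posterior`: list with `mean` and `logvar` arrays.
#' @export
encode <- function(ae, cube) {
  x <- cube_array(cube)
  d <- dim(x)
  x4 <- array(x, c(d[1], d[2], d[3], 1L))
  uf <- ae_unfold(ae, x4)
  E <- sweep(uf$xcol %*% ae$We, 2L, ae$be, "+")
  cl <- ae$config$latent_channels
  h <- uf$info$Ho; w <- uf$info$Wo
  mean_ <- array(E[, seq_len(cl)], c(h, w, cl))
  logvar <- array(pmin(pmax(E[, cl + seq_len(cl)], LOGVAR_MIN), LOGVAR_MAX),
                  c(h, w, cl))
  structure(list(mean = mean_, logvar = logvar), class = "hsi_posterior")
}

#' Draw a latent sample from a posterior
#'
#' Standard reparameterization: `mean + exp(logvar / 2) * eps` with seeded
#' standard-normal `eps`. As `logvar -> -Inf` the draw collapses to the mean.
#'
#' @param posterior An `hsi_posterior` from [encode()].
#' @param seed Integer seed for the noise draw.
#' @param scale_factor Standardization constant stored with the latent
#'   (latents are multiplied by it before entering the diffusion model).
#' @return An `hsi_latent`: list with `values` and `scale_factor`.
#' @export
sample_latent <- function(posterior, seed = 1L, scale_factor = 1) {
  eps <- with_seed(seed, array(stats::rnorm(length(posterior$mean)),
                               dim(posterior$mean)))
  values <- posterior$mean + exp(posterior$logvar / 2) * eps
  structure(list(values = values, scale_factor = scale_factor),
            class = "hsi_latent")
}

#' Decode a latent back to cube space
#'
#' Mirrored transposed convolution of the encoder; returns an H x W x C
#' array (finite, possibly slightly negative before clipping at the cube
#' boundary). Deterministic given the weights.
#'
#' @param ae An `hsi_ae`.
#' @param latent An `hsi_latent` or an h x w x latent_channels array.
#' @return An H x W x C numeric array.
#' @export
decode <- function(ae, latent) {
  z <- if (inherits(latent, "hsi_latent")) latent$values else latent
  d <- dim(z)
  cl <- ae$config$latent_channels
  if (d[3] != cl) {
    abort_hsi("latent channel count does not match the autoencoder",
              "hsisynth_shape_error")
  }
  f <- ae$config$spatial_factor
  H <- d[1] * f; W <- d[2] * f
  info <- im2col_index(H, W, ae$C, f, f, 0L)
  zmat <- matrix(z, d[1] * d[2], cl)
  ycol <- sweep(zmat %*% ae$Wd, 2L, ae$bd, "+")
  # non-overlapping fold: indices are a permutation, plain assignment
  out <- numeric(H * W * ae$C)
  for (j in seq_len(ncol(ycol))) out[info$idx[, j]] <- ycol[, j]
  array(out, c(H, W, ae$C))
}

#' KL divergence of a latent posterior from the standard normal
#'
#' Mean over latent cells of `0.5 * (mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param posterior An `hsi_posterior`.
#' @return A nonnegative scalar.
#' @examples
#' p <- structure(list(mean = array(1, c(1, 1, 1)),
#'                     logvar = array(0, c(1, 1, 1))), class = "hsi_posterior")
#' kl_term(p)  # 0.5
#' @export
kl_term <- function(posterior) {
  mu <- posterior$mean
  lv <- posterior$logvar
  mean(0.5 * (mu^2 + exp(lv) - 1 - lv))
}

#' Autoencoder training loss
#'
#' Pixelwise reconstruction term (mean absolute or mean squared error) plus
#' `lambda_kl` times [kl_term()]. There is deliberately no perceptual or
#' adversarial component.
#'
#' @param cube Original H x W x C array or [hsi_cube()].
#' @param reconstruction Decoded H x W x C array.
#' @param posterior The encoding `hsi_posterior`.
#' @param lambda_kl KL weight.
#' @param recon_loss `"L1"` or `"L2"`.
#' @return Scalar loss.
#' @export
ae_loss <- function(cube, reconstruction, posterior, lambda_kl = 1e-6,
                    recon_loss = c("L1", "L2")) {
  recon_loss <- match.arg(recon_loss)
  x <- cube_array(cube)
  if (!all(dim(x) == dim(reconstruction))) {
    abort_hsi("cube and reconstruction shapes differ", "hsisynth_shape_error")
  }
  rec <- if (recon_loss == "L1") mean(abs(reconstruction - x)) else
    mean((reconstruction - x)^2)
  rec + lambda_kl * kl_term(posterior)
}

#' Train the autoencoder
#'
#' Minibatch Adam on the [ae_loss()] objective with reparameterized latent
#' draws. Every 5th image is held out for validation; after training the
#' global standard deviation of sampled training latents is computed and its
#' reciprocal stored as `scale_factor`, so that diffusion operates on
#' roughly unit-scale latents (the variance-preserving forward process
#' assumes this).
#'
#' @param dataset List of scenes (`list(cube, mask, ...)`) or of
#'   [hsi_cube()] objects; all images must share (H, W, C).
#' @param config An [ae_config()].
#' @return A trained `hsi_ae` with a `log` data frame (epoch, train and
#'   validation loss, validation median relative error).
#' @export
train_ae <- function(dataset, config = ae_config()) {
  if (length(dataset) == 0L) {
    abort_hsi("dataset is empty", "hsisynth_validation_error")
  }
  arrays <- lapply(dataset, cube_array)
  d <- dim(arrays[[1]])
  X <- array(unlist(arrays), c(d[1], d[2], d[3], length(arrays)))
  N <- dim(X)[4]
  val_idx <- if (N >= 5L) seq(5L, N, by = 5L) else integer(0)
  tr_idx <- setdiff(seq_len(N), val_idx)
  ae <- new_ae(config, d[3], derive_seed(config$seed, 1))
  uf_all <- ae_unfold(ae, X)
  # spectral initialization: start the linear pair at the principal-subspace
  # optimum of the training patches; Adam then refines it under the L1 + KL
  # objective. Deterministic, and far more robust than a random start.
  cl <- config$latent_channels
  mu0 <- colMeans(uf_all$xcol)
  cv <- crossprod(sweep(uf_all$xcol, 2L, mu0)) / nrow(uf_all$xcol)
  eig <- eigen(cv, symmetric = TRUE)
  V <- eig$vectors[, seq_len(cl), drop = FALSE]
  ae$We[, seq_len(cl)] <- V
  ae$be[seq_len(cl)] <- -as.vector(crossprod(V, mu0))
  ae$Wd <- t(V)
  ae$bd <- mu0
  P <- uf_all$info$Ho * uf_all$info$Wo
  cl <- config$latent_channels
  row_block <- function(n) (n - 1L) * P + seq_len(P)
  tr_rows <- unlist(lapply(tr_idx, row_block))
  va_rows <- unlist(lapply(val_idx, row_block))
  Xtr <- uf_all$xcol[tr_rows, , drop = FALSE]
  Xva <- if (length(va_rows)) uf_all$xcol[va_rows, , drop = FALSE] else NULL
  params <- list(We = ae$We, be = ae$be, Wd = ae$Wd, bd = ae$bd)
  st <- adam_init(params)
  lam <- config$lambda_kl
  eval_loss <- function(Xc) {
    E <- sweep(Xc %*% params$We, 2L, params$be, "+")
    mu <- E[, seq_len(cl), drop = FALSE]
    lv <- pmin(pmax(E[, cl + seq_len(cl), drop = FALSE], LOGVAR_MIN), LOGVAR_MAX)
    Y <- sweep(mu %*% params$Wd, 2L, params$bd, "+")
    rec <- if (config$recon_loss == "L1") mean(abs(Y - Xc)) else mean((Y - Xc)^2)
    kl <- mean(0.5 * (mu^2 + exp(lv) - 1 - lv))
    relerr <- stats::median(abs(Y - Xc) / pmax(abs(Xc), 1e-3))
    c(loss = rec + lam * kl, relerr = relerr)
  }
  log_rows <- list()
  n_rows <- nrow(Xtr)
  bs_rows <- max(1L, config$batch_size) * P
  with_seed(derive_seed(config$seed, 2), {
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$lr * 0.97^(ep - 1)  # geometric decay
      ord <- sample.int(n_rows)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n_rows, by = bs_rows)) {
        rows <- ord[start:min(start + bs_rows - 1L, n_rows)]
        Xb <- Xtr[rows, , drop = FALSE]
        nb_el <- length(Xb)
        E <- sweep(Xb %*% params$We, 2L, params$be, "+")
        mu <- E[, seq_len(cl), drop = FALSE]
        lv_raw <- E[, cl + seq_len(cl), drop = FALSE]
        clamp <- lv_raw > LOGVAR_MIN & lv_raw < LOGVAR_MAX
        lv <- pmin(pmax(lv_raw, LOGVAR_MIN), LOGVAR_MAX)
        epsm <- matrix(stats::rnorm(length(mu)), nrow(mu), cl)
        z <- mu + exp(lv / 2) * epsm
        Y <- sweep(z %*% params$Wd, 2L, params$bd, "+")
        diffm <- Y - Xb
        loss <- (if (config$recon_loss == "L1") mean(abs(diffm)) else mean(diffm^2)) +
          lam * mean(0.5 * (mu^2 + exp(lv) - 1 - lv))
        if (!is.finite(loss)) {
          abort_hsi("autoencoder training diverged (non-finite loss)",
                    "hsisynth_generation_error")
        }
        dY <- if (config$recon_loss == "L1") sign(diffm) / nb_el else
          2 * diffm / nb_el
        dWd <- crossprod(z, dY)
        dbd <- colSums(dY)
        dz <- tcrossprod(dY, params$Wd)
        n_lat <- length(mu)
        dmu <- dz + lam * mu / n_lat
        dlv <- (dz * epsm * 0.5 * exp(lv / 2) +
                  lam * 0.5 * (exp(lv) - 1) / n_lat) * clamp
        dE <- cbind(dmu, dlv)
        dWe <- crossprod(Xb, dE)
        dbe <- colSums(dE)
        up <- adam_step(params, list(We = dWe, be = dbe, Wd = dWd, bd = dbd),
                        st, lr = lr_ep)
        params <- up$params; st <- up$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      va <- if (!is.null(Xva)) eval_loss(Xva) else c(loss = NA, relerr = NA)
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = va[["loss"]],
                                   val_relerr = va[["relerr"]])
    }
  })
  ae$We <- params$We; ae$be <- params$be
  ae$Wd <- params$Wd; ae$bd <- params$bd
  ae$log <- do.call(rbind, log_rows)
  # latent standardization over the training split
  E <- sweep(Xtr %*% ae$We, 2L, ae$be, "+")
  mu <- E[, seq_len(cl), drop = FALSE]
  lv <- pmin(pmax(E[, cl + seq_len(cl), drop = FALSE], LOGVAR_MIN), LOGVAR_MAX)
  zs <- with_seed(derive_seed(config$seed, 3),
                  mu + exp(lv / 2) * matrix(stats::rnorm(length(mu)), nrow(mu), cl))
  ae$scale_factor <- 1 / stats::sd(as.vector(zs))
  ae
}

#' Median per-voxel relative reconstruction error
#'
#' Encodes each scene with the posterior mean, decodes, and reports the
#' median over all voxels of `|x_hat - x| / max(x, 1e-3)`.
#'
#' @param ae A trained `hsi_ae`.
#' @param dataset List of scenes or cubes.
#' @return Scalar median relative error.
#' @export
ae_reconstruction_error <- function(ae, dataset) {
  errs <- lapply(dataset, function(sc) {
    x <- cube_array(sc)
    post <- encode(ae, x)
    xhat <- decode(ae, post$mean)
    as.vector(abs(xhat - x) / pmax(abs(x), 1e-3))
  })
  stats::median(unlist(errs))
}

#' Save / load an autoencoder checkpoint
#'
#' The checkpoint is a single-file container holding weights, configuration,
#' the latent `scale_factor` and the R version; reloading reproduces the
#' model bit-exactly.
#'
#' @param ae A trained `hsi_ae`.
#' @param path Destination file.
#' @return `path` invisibly ([save_ae()]); the restored `hsi_ae`
#'   ([load_ae()]).
#' @export
save_ae <- function(ae, path) {
  saveRDS(list(object = ae, r_version = R.version.string,
               package_version = as.character(utils::packageVersion("hsisynth"))),
          path)
  invisible(path)
}

#' @rdname save_ae
#' @export
load_ae <- function(path) {
  ck <- readRDS(path)
  ck$object
}
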