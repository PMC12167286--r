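fake_schedule <- function(alpha_bars) {
  structure(list(T = length(alpha_bars),
                 betas = rep(0.5, length(alpha_bars)),
                 alpha_bars = alpha_bars),
            class = "noise_schedule")
}

test_that("the linear schedule has the contracted shape", {
  sch <- make_schedule(1000)
  expect_length(sch$alpha_bars, 1000)
  expect_true(all(diff(sch$alpha_bars) < 0))
  expect_gt(sch$alpha_bars[1], 0.99)
  expect_lt(sch$alpha_bars[1000], 0.01)
  # constant beta: closed form (1 - c)^t
  sch2 <- make_schedule(5, beta1 = 0.2, betaT = 0.2)
  expect_equal(sch2$alpha_bars, 0.8^(1:5))
  # hand product for T = 2, beta = 0.5
  sch3 <- make_schedule(2, beta1 = 0.5, betaT = 0.5)
  expect_equal(sch3$alpha_bars, c(0.5, 0.25))
  expect_error(make_schedule(1), class = "hsisynth_config_error")
})

test_that("forward diffusion follows the closed form and preserves variance", {
  # hand value: abar = 0.25, z0 = 2, eps = 1 -> 0.5*2 + sqrt(0.75)*1
  sch <- fake_schedule(c(0.9, 0.25))
  z <- forward_diffuse(2, 2, 1, sch)
  expect_equal(z, 0.5 * 2 + sqrt(0.75), tolerance = 1e-9)
  expect_equal(round(z, 5), 1.86603)
  # abar ~= 1 reduces to the identity
  sch1 <- fake_schedule(c(1, 0.5))
  expect_equal(forward_diffuse(3.7, 1, 0.2, sch1), 3.7)
  expect_error(forward_diffuse(1, 5, 1, sch), class = "hsisynth_config_error")
  # Monte-Carlo variance preservation at 1e5 cells
  set.seed(4)
  n <- 1e5
  z0 <- rnorm(n); eps <- rnorm(n)
  for (ab in c(0.9, 0.5, 0.1)) {
    zt <- sqrt(ab) * z0 + sqrt(1 - ab) * eps
    expect_equal(var(zt), 1, tolerance = 0.02)
  }
})

test_that("pad/crop round trip is the identity with the contracted geometry", {
  z <- array(rnorm(30 * 40 * 3), c(30, 40, 3))
  p <- pad_latent(z, 3)
  expect_equal(dim(p$values)[1:2], c(32, 40))  # next multiples of 8
  expect_equal(crop_latent(p), z)
  # already-divisible dims: identity padding
  z2 <- array(rnorm(120 * 160 * 2), c(120, 160, 2))
  p2 <- pad_latent(z2, 3)
  expect_equal(dim(p2$values)[1:2], c(120, 160))
  expect_identical(crop_latent(p2), z2)
})

test_that("condition encoding rescales nearest-neighbor then projects", {
  # blocky 4 x 4 one-hot downscaled by 2 keeps labels exactly
  m <- matrix(c(0L, 0L, 1L, 1L,
                0L, 0L, 1L, 1L,
                1L, 1L, 0L, 0L,
                1L, 1L, 0L, 0L), 4, 4, byrow = TRUE)
  oh <- one_hot(m, 2)
  small <- hsisynth:::nn_rescale(oh, c(2, 2))
  expect_identical(onehot_argmax(small),
                   matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  # single-class mask gives a spatially constant condition tensor
  ohu <- one_hot(matrix(0L, 8, 8), 3)
  Wc <- matrix(rnorm(3 * 4), 3, 4)
  ct <- encode_condition(ohu, c(4, 4), Wc, rnorm(4))
  expect_equal(max(apply(ct, 3, function(ch) diff(range(ch)))), 0)
  # full-scale geometry: 480 x 640 one-hot -> 120 x 160 x 8
  oh_big <- one_hot(matrix(0L, 480, 640), 3)
  Wc8 <- matrix(rnorm(3 * 8), 3, 8)
  ct_big <- encode_condition(oh_big, c(120, 160), Wc8, numeric(8))
  expect_equal(dim(ct_big), c(120, 160, 8))
})

test_that("classifier-free guidance combination obeys its identities", {
  ec <- array(rnorm(12), c(2, 2, 3))
  eu <- array(rnorm(12), c(2, 2, 3))
  expect_identical(cfg_combine(ec, eu, 1), ec)      # lambda = 1: conditional
  expect_identical(cfg_combine(ec, ec, 7.3), ec)    # equal inputs: any lambda
  expect_equal(cfg_combine(1, 0, 2), 2)             # hand value
  expect_equal(cfg_combine(ec, eu, 2), eu + 2 * (ec - eu))
})

test_that("ddim_step matches the hand example and inverts the forward map", {
  sch <- fake_schedule(c(0.64, 0.25))
  # hand example: abar_t = 0.25, abar_prev = 0.64
  z <- ddim_step(1.86603, 1.0, t = 2, t_prev = 1, sch)
  expect_equal(z, 2.2, tolerance = 1e-5)
  # t_prev = 0 returns the x0 estimate (abar_0 = 1)
  x0 <- ddim_step(1.86603, 1.0, t = 2, t_prev = 0, sch)
  expect_equal(x0, 2.0, tolerance = 1e-5)
  # with the true noise the x0 estimate is exact on random tensors
  set.seed(8)
  sch2 <- make_schedule(100)
  z0 <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  eps <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  zt <- forward_diffuse(z0, 60, eps, sch2)
  expect_equal(ddim_step(zt, eps, 60, 0, sch2), z0, tolerance = 1e-10)
  expect_error(ddim_step(1, 1, 3, 3, sch2), class = "hsisynth_config_error")
  # eta > 0: seeded noise, reproducible, and different from the eta = 0 path
  s1 <- ddim_step(zt, eps, 60, 30, sch2, eta = 1, seed = 5)
  s2 <- ddim_step(zt, eps, 60, 30, sch2, eta = 1, seed = 5)
  s3 <- ddim_step(zt, eps, 60, 30, sch2, eta = 1, seed = 6)
  d0 <- ddim_step(zt, eps, 60, 30, sch2)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_false(identical(s1, d0))
})

test_that("an untrained denoiser with zero head predicts exactly zero", {
  net <- hsisynth:::unet_init(6, 4, c(8, 12), seed = 3)
  z <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  eps_hat <- denoise_predict(net, z, NULL, 5)
  expect_equal(dim(eps_hat), dim(z))
  expect_true(all(eps_hat == 0))
  # determinism
  net$params$head_W[] <- rnorm(length(net$params$head_W), 0, 0.01)
  e1 <- denoise_predict(net, z, NULL, 5)
  e2 <- denoise_predict(net, z, NULL, 5)
  expect_identical(e1, e2)
})

test_that("ddim timestep subsets are uniform, descending and include T", {
  ts <- hsisynth:::ddim_timesteps(200, 50)
  expect_equal(ts[1], 200)
  expect_equal(length(ts), 50)
  expect_true(all(diff(ts) < 0))
  expect_true(all(ts >= 1))
})

test_that("diffusion training logs a dropout fraction near p_drop", {
  # ~1e4 Bernoulli draws across steps x batch
  cfg <- phantom_config(n_subjects = 2, images_per_subject = 3, H = 8, W = 8,
                        C = 8, n_organs = 2, seed = 31)
  ds <- make_dataset(cfg)
  ae <- train_ae(ds, ae_config(2, 2, epochs = 4, batch_size = 2, seed = 1))
  dmc <- dm_config(c_cond = 2, p_drop = 0.1, n_steps = 1250, batch_size = 8,
                   T_steps = 50, widths = c(4L, 6L), seed = 5)
  dm <- cached("tiny_dm", train_dm(ae, ds, dmc))
  expect_equal(dm$drop_fraction, 0.1, tolerance = 0.3)
  expect_lt(mean(utils::tail(dm$log$loss, 100)),
            mean(dm$log$loss[1:100]))
  # p_drop = 0 means every call is conditioned
  dmc0 <- dm_config(c_cond = 2, p_drop = 0, n_steps = 20, batch_size = 4,
                    T_steps = 50, widths = c(4L, 6L), seed = 5)
  dm0 <- train_dm(ae, ds, dmc0)
  expect_equal(dm0$drop_fraction, 0)
  .test_cache$tiny_ae <- ae
  .test_cache$tiny_ds <- ds
})

test_that("sampling is a pure function of (weights, mask, seed) at eta = 0", {
  dm <- .test_cache$tiny_dm
  ae <- .test_cache$tiny_ae
  ds <- .test_cache$tiny_ds
  skip_if(is.null(dm), "tiny diffusion model not built")
  sc <- sampler_config(steps = 10, lambda_cfg = 2, seed = 42)
  c1 <- sample_cube(dm, ae, ds[[1]]$mask, sc)
  c2 <- sample_cube(dm, ae, ds[[1]]$mask, sc)
  expect_identical(c1$data, c2$data)
  expect_equal(dim(c1$data), dim(ds[[1]]$cube$data))
  sc2 <- sampler_config(steps = 10, lambda_cfg = 2, seed = 43)
  expect_false(identical(sample_cube(dm, ae, ds[[1]]$mask, sc2)$data, c1$data))
})
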