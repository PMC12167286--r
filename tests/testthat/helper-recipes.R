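# Reference desk-scale recipes shared by the acceptance tests. Built once
# per test run and cached; criteria 4-6 all draw on the same phantom study,
# autoencoder and diffusion model.

recipe_phantoms <- function() {
  cached("recipe_phantoms", {
    cfg <- phantom_config(n_subjects = 20, images_per_subject = 10,
                          H = 32, W = 32, C = 25, n_organs = 3, seed = 11)
    ds <- make_dataset(cfg)
    list(cfg = cfg, ds = ds, lib = attr(ds, "library"),
         train = ds[1:160], held = ds[161:200])
  })
}

recipe_ae <- function() {
  cached("recipe_ae", {
    ph <- recipe_phantoms()
    train_ae(ph$ds, ae_config(spatial_factor = 2, latent_channels = 4,
                              epochs = 60, seed = 5))
  })
}

recipe_dm <- function() {
  cached("recipe_dm", {
    ph <- recipe_phantoms()
    train_dm(recipe_ae(), ph$train,
             dm_config(c_cond = 8, p_drop = 0.1, n_steps = 8000, lr = 3e-3,
                       lr_decay = 0.1, T_steps = 200, widths = c(16L, 32L),
                       seed = 7))
  })
}

recipe_synth <- function() {
  cached("recipe_synth", {
    ph <- recipe_phantoms()
    dm <- recipe_dm()
    samp <- sampler_config(steps = 50, lambda_cfg = 2, seed = 99)
    synth <- generate_synthetic_trainset(dm, recipe_ae(),
                                         lapply(ph$held, `[[`, "mask"), samp)
    for (i in seq_along(synth)) synth[[i]]$subject_id <- ph$held[[i]]$subject_id
    synth
  })
}
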