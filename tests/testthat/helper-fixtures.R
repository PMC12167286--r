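# Shared fixtures, built in code at test time.

tiny_cube <- function(H = 4, W = 4, C = 3, value = 0.5,
                      wavelengths = seq(500, by = 5, length.out = C),
                      subject_id = "pig01") {
  hsi_cube(array(value, c(H, W, C)), wavelengths, subject_id = subject_id)
}

tiny_legend <- function(n_organs = 1) {
  label_legend(0:n_organs, c("blue cloth", paste0("organ_", seq_len(n_organs))))
}

tiny_mask <- function(labels = matrix(c(0L, 1L, 1L, 0L), 2, 2),
                      legend = tiny_legend()) {
  semantic_mask(labels, legend)
}

# small noise-free phantom: every pixel of class k is exactly gain*library[k]
noise_free_config <- function(H = 24, W = 24, C = 16, n_organs = 2, seed = 3) {
  phantom_config(n_subjects = 1, images_per_subject = 1, H = H, W = W, C = C,
                 n_organs = n_organs, sigma_m = 0, sigma_a = 0,
                 illum_amp = 0, seed = seed)
}

# Heavier artifacts (trained models) shared across test files, built once.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- force(expr)
  .test_cache[[name]]
}
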