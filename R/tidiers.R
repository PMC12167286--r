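# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# result tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an autoencoder training log
#'
#' @param x A trained `hsi_ae`.
#' @param ... Unused.
#' @return A tibble with one row per epoch (train/validation loss, median
#'   relative error).
#' @method tidy hsi_ae
#' @export
tidy.hsi_ae <- function(x, ...) tibble::as_tibble(x$log)

#' @rdname tidy.hsi_ae
#' @method glance hsi_ae
#' @export
glance.hsi_ae <- function(x, ...) {
  tibble::tibble(
    spatial_factor = x$config$spatial_factor,
    latent_channels = x$config$latent_channels,
    lambda_kl = x$config$lambda_kl,
    epochs = x$config$epochs,
    scale_factor = x$scale_factor,
    final_val_loss = utils::tail(x$log$val_loss, 1),
    final_val_relerr = utils::tail(x$log$val_relerr, 1)
  )
}

#' Tidy a diffusion training log
#'
#' @param x A trained `hsi_dm`.
#' @param ... Unused.
#' @return A tibble of per-step training loss.
#' @method tidy hsi_dm
#' @export
tidy.hsi_dm <- function(x, ...) tibble::as_tibble(x$log)

#' @rdname tidy.hsi_dm
#' @method glance hsi_dm
#' @export
glance.hsi_dm <- function(x, ...) {
  tibble::tibble(
    n_steps = x$config$n_steps,
    T_steps = x$schedule$T,
    p_drop = x$config$p_drop,
    drop_fraction = x$drop_fraction,
    final_loss = mean(utils::tail(x$log$loss, 50))
  )
}

#' Tidy experiment results
#'
#' @param x An `hsi_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return The per-arm/test-set/class aggregated metric tibble.
#' @method tidy hsi_experiment
#' @export
tidy.hsi_experiment <- function(x, ...) x$results

#' @rdname tidy.hsi_experiment
#' @method glance hsi_experiment
#' @export
glance.hsi_experiment <- function(x, ...) x$boost

#' Plot aggregated experiment metrics
#'
#' One panel per metric, test sets on the x axis, one point per class
#' colored by arm — the standard summary view of a generative-augmentation
#' study.
#'
#' @param object An `hsi_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsi_experiment
#' @export
autoplot.hsi_experiment <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$test_set, y = .data$value,
                               colour = .data$arm)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "test set", y = "hierarchically aggregated value",
                  colour = "model") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot real-vs-synthetic class spectra
#'
#' Median l1-normalized class spectra of two datasets overlaid per class,
#' the standard check that generated spectra match real ones in shape.
#'
#' @param real_dataset,synth_dataset Scene lists.
#' @param class_ids Integer label ids to show.
#' @param class_names Optional names for facets.
#' @return A ggplot object.
#' @export
plot_spectral_agreement <- function(real_dataset, synth_dataset, class_ids,
                                    class_names = NULL) {
  wl <- real_dataset[[1]]$cube$wavelengths
  rows <- purrr::map(class_ids, function(k) {
    nm <- if (is.null(class_names)) paste("class", k) else
      class_names[[match(k, class_ids)]]
    out <- list()
    for (src in c("real", "synthetic")) {
      ds <- if (src == "real") real_dataset else synth_dataset
      cs <- class_spectrum(ds, k)
      if (is.null(cs)) next
      out[[src]] <- tibble::tibble(wavelength = wl, reflectance = cs$median,
                                   sd = cs$sd, dataset = src, class = nm)
    }
    dplyr::bind_rows(out)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$wavelength,
                                     y = .data$reflectance,
                                     colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = "median l1-normalized reflectance") +
    ggplot2::theme_minimal()
}

#' Show an RGB preview of a cube
#'
#' @param cube An [hsi_cube()].
#' @param ... Passed to [rgb_reconstruction()].
#' @return A ggplot object.
#' @export
plot_cube_rgb <- function(cube, ...) {
  rgb_arr <- rgb_reconstruction(cube, ...)
  d <- dim(rgb_arr)
  df <- tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), d[2]),
    col = grDevices::rgb(rgb_arr[, , 1], rgb_arr[, , 2], rgb_arr[, , 3])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
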