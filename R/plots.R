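#' Plot methods
#'
#' `autoplot()` methods render the package's result types with ggplot2:
#' a `mode_spectrum` as normalized participation ratio versus eigenvalue,
#' a `pr_histogram` as the binned distribution (optionally with a
#' `lorentzian_fit` overlay), and a `denoise_result` as the denoised image
#' raster with the discarded eigenvalue band annotated in the subtitle.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name qldenoise-plots
NULL

#' @rdname qldenoise-plots
#' @param selection Optional `mode_selection`; kept/discarded modes are
#'   colored and the eigenvalue band edges drawn.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mode_spectrum <- function(object, selection = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue,
                                        y = .data$normalized_participation))
  if (is.null(selection)) {
    p <- p + ggplot2::geom_point(size = 0.4, alpha = 0.6)
  } else {
    df$kept <- selection$keep_mask
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue,
                                          y = .data$normalized_participation,
                                          colour = .data$kept)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                              `FALSE` = "#bbbbbb"),
                                   name = "kept")
    for (e in c(selection$E_low, selection$E_high)) {
      if (is.finite(e)) p <- p + ggplot2::geom_vline(xintercept = e,
                                                     linetype = "dashed")
    }
  }
  p + ggplot2::labs(x = "eigenvalue",
                    y = "normalized participation ratio") +
    ggplot2::theme_minimal()
}

#' @rdname qldenoise-plots
#' @param fit Optional `lorentzian_fit` drawn over the histogram.
#' @export
autoplot.pr_histogram <- function(object, fit = NULL, ...) {
  df <- tibble::tibble(center = object$bin_centers, count = object$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_col(width = mean(diff(object$bin_edges)),
                      fill = "#74add1", colour = "grey30", linewidth = 0.2)
  if (!is.null(fit)) {
    grid <- seq(min(object$bin_edges), max(object$bin_edges),
                length.out = 400)
    curve <- tibble::tibble(
      center = grid,
      count = fit$amplitude * fit$gamma^2 /
        ((grid - fit$lambda0)^2 + fit$gamma^2)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "#d73027",
                                linewidth = 0.8)
  }
  p + ggplot2::labs(x = "normalized participation ratio", y = "modes") +
    ggplot2::theme_minimal()
}

#' @rdname qldenoise-plots
#' @export
autoplot.denoise_result <- function(object, ...) {
  img <- object$denoised
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img)
  )
  subtitle <- if (!is.null(object$selection)) {
    paste0("kept ", object$selection$n_kept, "/", object$spectrum$n_tot,
           " modes; compression ",
           format(round(object$selection$compression_fraction, 3)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(subtitle = subtitle, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a benchmark sweep
#'
#' Mean SSIM and PSNR per noise level and method, with replicate spread.
#'
#' @param results Tibble from [benchmark_sweep()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  long <- tidyr_pivot(results)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snr_db, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "target SNR (dB)", y = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (ssim + psnr columns)
tidyr_pivot <- function(results) {
  dplyr::bind_rows(
    dplyr::transmute(results, snr_db = .data$snr_db, method = .data$method,
                     metric = "SSIM", value = .data$ssim),
    dplyr::transmute(results, snr_db = .data$snr_db, method = .data$method,
                     metric = "PSNR (dB)", value = .data$psnr_db)
  )
}
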