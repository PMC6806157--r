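#' Plot an incremental-subset accuracy curve
#'
#' Accuracy against the number of top-ranked features, the figure used to
#' decide where the curve saturates and extraction effort stops paying.
#'
#' @param object A `patchfreq_curve` from [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot patchfreq_curve
#' @export
autoplot.patchfreq_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(
      x = "top-ranked features used",
      y = "test accuracy",
      title = "Accuracy vs. feature subset size"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PCA feature ranking
#'
#' @param object A `patchfreq_ranking` from [rank_features_pca()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot patchfreq_ranking
#' @export
autoplot.patchfreq_ranking <- function(object, ...) {
  df <- dplyr::mutate(object,
    feature = factor(.data$feature, levels = rev(.data$feature))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "explained-variance share",
      y = NULL,
      title = "PCA feature importance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark stage decomposition
#'
#' @param object A `patchfreq_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot patchfreq_benchmark
#' @export
autoplot.patchfreq_benchmark <- function(object, ...) {
  df <- dplyr::filter(object, .data$stage != "Total")
  df <- dplyr::mutate(df,
    stage = factor(.data$stage, levels = benchmark_stage_labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mean_ns)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_ns - .data$sd_ns,
        ymax = .data$mean_ns + .data$sd_ns
      ),
      width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "time per image (ns)",
      title = "Extraction/classification time by stage"
    ) +
    ggplot2::theme_minimal()
}

#' Display a patch as an image
#'
#' @param patch Numeric matrix in \[0, 1\].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_patch <- function(patch, title = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(patch)), times = ncol(patch)),
    col = rep(seq_len(ncol(patch)), each = nrow(patch)),
    value = as.numeric(patch)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(
      low = "black", high = "white", limits = c(0, 1)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity", title = title) +
    ggplot2::theme_void()
}
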