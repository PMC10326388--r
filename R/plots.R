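# ggplot2 figures for the main result types.

#' Plot an axial slice of an activation map
#'
#' Shows the percent-change values of a chosen slice, either all voxels or
#' only the significant (zeroed-elsewhere) map used for composites.
#'
#' @param object An `activation_map`.
#' @param slice Axial slice index (default the middle slice).
#' @param which `"percent"` or `"zeroed"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, slice = NULL,
                                    which = c("percent", "zeroed"), ...) {
  which <- match.arg(which)
  vol <- object[[which]]
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  df <- expand.grid(x = seq_len(dim(vol)[1]), y = seq_len(dim(vol)[2]))
  df$value <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "grey95", high = "#b2182b",
      na.value = "white", name = "% change"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0("BOLD percent change, slice ", slice),
      subtitle = object$subject_id
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectivity network's weights
#'
#' @param object A `connectivity_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_network
#' @export
autoplot.connectivity_network <- function(object, ...) {
  df <- tidy.connectivity_network(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, node_a = "node_b", node_b = "node_a")
  )
  ggplot2::ggplot(df2, ggplot2::aes(
    factor(.data$node_a), factor(.data$node_b),
    fill = .data$weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", name = "Z"
    ) +
    ggplot2::labs(x = "region", y = "region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Group-mean time course with standard-error ribbon
#'
#' @param courses Tibble with columns `acquisition`, `percent_change`,
#'   `subject_id`, `group` (stack the per-subject [time_course()] outputs).
#' @param threshold_pct Optional horizontal reference line (e.g. the 1%
#'   noise-floor threshold).
#' @return A ggplot.
#' @export
plot_time_course <- function(courses, threshold_pct = 1) {
  summ <- courses |>
    dplyr::group_by(.data$group, .data$acquisition) |>
    dplyr::summarise(
      mean_pct = mean(.data$percent_change),
      se = sd(.data$percent_change) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(
    .data$acquisition, .data$mean_pct,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_pct - .data$se,
        ymax = .data$mean_pct + .data$se
      ),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "acquisition", y = "BOLD change (%)",
      colour = "group", fill = "group"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold_pct)) {
    p <- p + ggplot2::geom_hline(
      yintercept = threshold_pct, linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Dose-response boxplot of region VOA counts
#'
#' @param voa Tibble from the activation pipeline (`region_id`, `dose`,
#'   `n_voxels`, `sign`).
#' @param region_ids Regions to show (default: 6 with the largest spread).
#' @param sign `"positive"` or `"negative"` counts.
#' @return A ggplot.
#' @export
plot_dose_response <- function(voa, region_ids = NULL, sign = "positive") {
  d <- dplyr::filter(voa, .data$sign == !!sign)
  if (is.null(region_ids)) {
    spread <- d |>
      dplyr::group_by(.data$region_id) |>
      dplyr::summarise(s = stats::var(.data$n_voxels), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$s))
    region_ids <- head(spread$region_id, 6)
  }
  d <- dplyr::filter(d, .data$region_id %in% region_ids)
  ggplot2::ggplot(d, ggplot2::aes(
    factor(.data$dose, levels = unique(.data$dose)), .data$n_voxels
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~ .data$region_name, scales = "free_y") +
    ggplot2::labs(x = "dose", y = "volume of activation (voxels)") +
    ggplot2::theme_minimal()
}
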