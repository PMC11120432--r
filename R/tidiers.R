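#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cumulative link mixed model fit
#'
#' @param x A `clmm_fit`.
#' @param ... Unused.
#'
#' @return A tibble with one row per parameter: `term`, `type`
#'   (`threshold`, `fixed`, `re_sd`), `estimate`, `std.error` (NA for
#'   random-effect SDs).
#' @export
tidy.clmm_fit <- function(x, ...) {
  K1 <- length(x$thresholds)
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = c(paste0("theta", seq_len(K1)), names(x$beta),
             if (length(x$re_sd)) paste0("sd_", names(x$re_sd))),
    type = c(rep("threshold", K1), rep("fixed", length(x$beta)),
             rep("re_sd", length(x$re_sd))),
    estimate = c(x$thresholds, unname(x$beta), unname(x$re_sd)),
    std.error = c(se, rep(NA_real_, length(x$re_sd)))
  )
}

#' @export
glance.clmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n, n_categories = x$n_categories,
    n_random_terms = length(x$re_sd), converged = x$convergence
  )
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x An `rm_anova_fit`.
#' @param ... Unused.
#'
#' @return The Tukey-Kramer pairwise comparison tibble.
#' @export
tidy.rm_anova_fit <- function(x, ...) {
  x$pairwise
}

#' @export
glance.rm_anova_fit <- function(x, ...) {
  tibble::tibble(statistic = x$f, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, ms_error = x$ms_error,
                 n_specimens = x$n_specimens)
}

map_display_range <- function(kind) {
  # the conventional fixed display windows: 0-100 ms (T2), 0-70 ms (T1rho)
  if (kind == "T2") c(0, 100) else c(0, 70)
}

#' Plot a parameter map slice
#'
#' Renders one slice of a fitted relaxation map with the conventional
#' fixed display range (0-100 ms for T2, 0-70 ms for T1rho); invalid
#' voxels are blank.
#'
#' @param object A `parameter_map`.
#' @param slice_index Slice to display; default central.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.parameter_map <- function(object,
                                   slice_index = ceiling(dim(object$values_ms)[3] / 2),
                                   ...) {
  vals <- object$values_ms[, , slice_index]
  vals[!object$valid[, , slice_index]] <- NA_real_
  df <- tidyr::expand_grid(x = seq_len(nrow(vals)), y = seq_len(ncol(vals)))
  df$value <- as.vector(vals)
  rng <- map_display_range(object$kind)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = pmin(pmax(.data$value, rng[1]), rng[2]))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = rng, na.value = "grey20",
                                  name = sprintf("%s [ms]", object$kind)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map (%s), slice %d", object$kind,
                                  object$sequence_name, slice_index)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated block image
#'
#' @param object An `image_stack`.
#' @param block Block index to display.
#' @param slice_index Slice to display; default central.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.image_stack <- function(object, block = 1L,
                                 slice_index = ceiling(object$phantom_ref$dim[3] / 2),
                                 ...) {
  vals <- object$volumes[[block]][, , slice_index]
  df <- tidyr::expand_grid(x = seq_len(nrow(vals)), y = seq_len(ncol(vals)))
  df$value <- as.vector(vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "SI [a.u.]") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, block %d (%s), slice %d",
                                  object$sequence$name, block,
                                  object$sequence$blocks[[block]]$label,
                                  slice_index)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-sequence image-quality metrics
#'
#' @param metrics A metrics tibble from [compare_sequences()] (rows may
#'   pool both weightings).
#'
#' @return A ggplot object, one facet per metric.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, cols = c("weber", "cnr", "cv"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sequence, y = .data$value,
                                     fill = .data$sequence)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
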