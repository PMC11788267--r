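# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth-dose profile
#'
#' @param object a `ddk_profile`.
#' @param ... unused.
#' @return A ggplot: relative dose vs depth.
#' @exportS3Method ggplot2::autoplot
autoplot.ddk_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth_mm, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth [mm]", y = "relative dose",
                  title = attr(object, "meta")$kind) +
    ggplot2::theme_minimal()
}

#' Plot scored quality metrics along depth
#'
#' Dose (scaled), dirty-dose fractions per threshold and dose-averaged LET
#' in one panel, mirroring the usual depth-profile displays.
#'
#' @param object a `ddk_quality` table.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ddk_quality <- function(object, ...) {
  thr <- attr(object, "thresholds")
  f_cols <- vapply(thr, function(t) metric_col("f", t), character(1))
  df <- tibble::as_tibble(object)
  df$dose_rel <- df$dose / max(df$dose)
  long <- tidyr::pivot_longer(
    df[, c("depth_mm", "dose_rel", f_cols, "letd")],
    -"depth_mm", names_to = "metric", values_to = "value")
  long$value[long$metric == "letd"] <-
    long$value[long$metric == "letd"] / max(df$letd, na.rm = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth_mm, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "depth [mm]", y = "relative value / fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model benchmark
#'
#' Bar chart of ln(SF) RMSE per fitted model.
#'
#' @param object a `ddk_benchmark` from [benchmark_models()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ddk_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)[, c("model", "rmse_weighted")]
  df$model <- stats::reorder(df$model, df$rmse_weighted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$rmse_weighted)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "RMSE of ln(SF)") +
    ggplot2::theme_minimal()
}

#' Plot RBE-weighted dose along depth
#'
#' @param rwp output of [rbe_weighted_profile()].
#' @return A ggplot with physical and RBE-weighted dose.
#' @export
plot_rbe_profile <- function(rwp) {
  long <- tidyr::pivot_longer(rwp[, c("depth_mm", "dose_gy", "rbe_dose_gy")],
                              -"depth_mm", names_to = "series",
                              values_to = "gy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth_mm, y = .data$gy,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth [mm]", y = "dose [Gy]", colour = NULL) +
    ggplot2::theme_minimal()
}
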