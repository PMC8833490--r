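#' Plot a binned activity/posture/behavior overview
#'
#' Stacked-bar overview of the seconds per label in each bin, one of
#' the three label families at a time. Requires ggplot2 (suggested);
#' reporting never fails on a headless machine because plotting is
#' strictly optional.
#'
#' @param overview Data frame from [aggregate_overview()].
#' @param family One of `"activity"`, `"posture"`, `"behavior"`.
#' @return A ggplot object.
#' @export
plot_overview <- function(overview,
                          family = c("activity", "posture", "behavior")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  family <- match.arg(family)
  cols <- grep(paste0("^", family, "_"), names(overview), value = TRUE)
  long <- do.call(rbind, lapply(cols, function(cl) data.frame(
    bin_start = overview$bin_start,
    label = sub(paste0("^", family, "_"), "", cl),
    seconds = overview[[cl]])))
  ggplot2::ggplot(long, ggplot2::aes(
    x = bin_start / 3600, y = seconds, fill = label)) +
    ggplot2::geom_col(width = diff(range(overview$bin_start / 3600)) /
                        max(1, nrow(overview) - 1) * 0.9) +
    ggplot2::labs(x = "time (h)", y = "seconds per bin", fill = family) +
    ggplot2::theme_minimal()
}

#' Plot a 1 Hz behavior timeline
#'
#' Step-style timeline of the per-second behavior labels, mirroring a
#' raster/ethogram view. Requires ggplot2 (suggested).
#'
#' @param timeline Data frame from [behavior_timeline()].
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  keep <- !is.na(timeline$behavior)
  ggplot2::ggplot(timeline[keep, ], ggplot2::aes(
    x = t / 60, y = behavior)) +
    ggplot2::geom_point(shape = 15, size = 1) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("bin_start", "seconds", "label", "t", "behavior"))
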