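#' Summarize an ensemble grid and report condition trends
#'
#' Collapses a [simulate_ensemble()] table (or any table with columns
#' `head_m`, `amplitude_m`, `lambda_q`) to per-condition means with
#' standard errors, fits the trend of the summary exponent against head
#' and against amplitude, and builds the corresponding plots. With
#' `out_dir` set, deterministic TSV tables (and PNG figures) are written;
#' rerunning on the same grid produces byte-identical TSVs.
#'
#' @param grid Data frame of per-run summaries; rows with `ok == FALSE`
#'   (if present) are dropped.
#' @param out_dir Optional output directory for `by_head.tsv`,
#'   `by_amplitude.tsv`, `trends.tsv` and the figures.
#' @param plots If `FALSE`, skip building ggplot objects.
#' @return A list: `by_head`, `by_amplitude` (data frames with columns
#'   condition, `mean_lambda`, `se_lambda`, `n`), `trend_head`,
#'   `trend_amplitude` ([lambda_trend()] fits, `NULL` when fewer than two
#'   distinct conditions), and `plots`.
#' @export
report <- function(grid, out_dir = NULL, plots = TRUE) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    abort_empty_input("`grid` must be a non-empty data frame")
  }
  needed <- c("head_m", "amplitude_m", "lambda_q")
  if (!all(needed %in% names(grid))) {
    abort_invalid_input(sprintf("`grid` must have columns %s",
                                paste(needed, collapse = ", ")))
  }
  if ("ok" %in% names(grid)) grid <- grid[grid$ok %in% TRUE, , drop = FALSE]
  grid <- grid[is.finite(grid$lambda_q), ]
  if (nrow(grid) == 0L) abort_empty_input("no successful runs in `grid`")

  summarize_by <- function(cond) {
    agg <- lapply(split(grid$lambda_q, grid[[cond]]), function(v) {
      c(mean_lambda = mean(v),
        se_lambda = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v))
    })
    out <- data.frame(condition = as.numeric(names(agg)),
                      do.call(rbind, agg), row.names = NULL)
    names(out)[1] <- cond
    out[order(out[[cond]]), , drop = FALSE]
  }
  by_head <- summarize_by("head_m")
  by_amplitude <- summarize_by("amplitude_m")

  trend_of <- function(cond) {
    if (length(unique(grid[[cond]])) < 2L) return(NULL)
    lambda_trend(grid[[cond]], grid$lambda_q)
  }
  trend_head <- trend_of("head_m")
  trend_amplitude <- trend_of("amplitude_m")

  plot_list <- NULL
  if (isTRUE(plots)) {
    mk_plot <- function(df, cond, xlab) {
      pd <- data.frame(condition = df[[cond]], mean_lambda = df$mean_lambda,
                       se_lambda = df$se_lambda)
      ggplot2::ggplot(pd, ggplot2::aes(x = condition, y = mean_lambda)) +
        ggplot2::geom_pointrange(ggplot2::aes(
          ymin = mean_lambda - se_lambda, ymax = mean_lambda + se_lambda)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = xlab, y = expression(lambda[75] ~ (s^-1))) +
        ggplot2::theme_classic()
    }
    plot_list <- list(
      by_head = mk_plot(by_head, "head_m", "hydrostatic head (m)"),
      by_amplitude = mk_plot(by_amplitude, "amplitude_m", "wall amplitude (m)"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv <- function(df, name) {
      utils::write.table(format(df, digits = 15), file.path(out_dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_tsv(by_head, "by_head.tsv")
    write_tsv(by_amplitude, "by_amplitude.tsv")
    trends <- data.frame(
      condition = c("head_m", "amplitude_m"),
      slope = c(trend_head$slope %||% NA_real_,
                trend_amplitude$slope %||% NA_real_),
      std_error = c(trend_head$std_error %||% NA_real_,
                    trend_amplitude$std_error %||% NA_real_))
    write_tsv(trends, "trends.tsv")
    if (isTRUE(plots)) {
      ggplot2::ggsave(file.path(out_dir, "lambda_by_head.png"),
                      plot_list$by_head, width = 4, height = 3, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "lambda_by_amplitude.png"),
                      plot_list$by_amplitude, width = 4, height = 3, dpi = 150)
    }
  }

  list(by_head = by_head, by_amplitude = by_amplitude,
       trend_head = trend_head, trend_amplitude = trend_amplitude,
       plots = plot_list)
}
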