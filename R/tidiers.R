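#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_hline
#'   geom_rect labs theme_minimal facet_wrap .data
#' @export
ggplot2::autoplot

#' Tidy an SPM result into a per-node tibble
#'
#' @param x An `spm_t` object.
#' @param ... Unused.
#' @return Tibble with one row per stride node: `node` (0-100% stride), `t`,
#'   `t_star`, `significant` (node inside a supra-threshold cluster), and the
#'   two condition means/SDs.
#' @export
tidy.spm_t <- function(x, ...) {
  sig <- rep(FALSE, length(x$t))
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      sig[(x$clusters$start[i]:x$clusters$end[i]) + 1L] <- TRUE
  tibble(variable = x$variable, comparison = x$comparison,
         node = x$node, t = x$t, t_star = x$t_star, significant = sig,
         mean_a = x$mean_a, sd_a = x$sd_a, mean_b = x$mean_b, sd_b = x$sd_b)
}

#' One-row summary of an SPM result
#'
#' @param x An `spm_t` object.
#' @param ... Unused.
#' @return Tibble: `variable`, `comparison`, `df`, `fwhm`, `resels`,
#'   `t_star`, `alpha`, `n_clusters`, `significant`, `min_p`.
#' @export
glance.spm_t <- function(x, ...) {
  tibble(variable = x$variable, comparison = x$comparison, df = x$df,
         fwhm = x$fwhm, resels = x$resels, t_star = x$t_star,
         alpha = x$alpha, n_clusters = nrow(x$clusters),
         significant = x$significant,
         min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_)
}

#' Tidy a stride matrix into long format
#'
#' @param x A `stride_matrix`.
#' @param ... Unused.
#' @return Tibble: `variable`, `condition`, `trial`, `stride`, `node`,
#'   `value`.
#' @export
tidy.stride_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  vals <- unclass(x)
  tibble(variable = attr(x, "variable"), condition = attr(x, "condition"),
         trial = rep(prov$trial, each = ncol(vals)),
         stride = rep(prov$stride, each = ncol(vals)),
         node = rep(seq_len(ncol(vals)) - 1L, nrow(vals)),
         value = as.vector(t(vals)))
}

#' Tidy a study report into its per-comparison summaries
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return One row per comparison: [glance.spm_t()] columns.
#' @export
tidy.study_report <- function(x, ...) bind_rows(lapply(x$results, glance))

#' One-row summary of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return Tibble with total stride counts per analysis, comparison counts
#'   and the number of significant comparisons.
#' @export
glance.study_report <- function(x, ...) {
  tl <- tidy(x)
  acct <- x$accounting %>% group_by(.data$analysis) %>%
    summarise(strides = sum(.data$kept), .groups = "drop")
  tibble(
    semg_strides = acct$strides[acct$analysis == "sEMG"],
    kinematic_strides = if ("kinematic" %in% acct$analysis)
      acct$strides[acct$analysis == "kinematic"] else 0L,
    comparisons = nrow(tl),
    significant = sum(tl$significant),
    alpha = x$alpha, seed = x$seed)
}

#' @export
print.study_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<study_report> %d sEMG + %d kinematic strides, %d comparisons (%d significant at alpha %g)\n",
              g$semg_strides, g$kinematic_strides, g$comparisons,
              g$significant, g$alpha))
  print(x$accounting)
  invisible(x)
}

#' Two-panel SPM plot for one comparison
#'
#' Mirrors the standard SPM figure layout: condition means with +/- SD
#' ribbons on the left panel, the t-field with the critical threshold and
#' shaded significant clusters on the right panel.
#'
#' @param object An `spm_t` object.
#' @param ... Unused.
#' @return A ggplot object (faceted two-panel figure).
#' @export
autoplot.spm_t <- function(object, ...) {
  td <- tidy(object)
  waves <- bind_rows(
    tibble(node = td$node, m = td$mean_a, s = td$sd_a,
           condition = object$label_a),
    tibble(node = td$node, m = td$mean_b, s = td$sd_b,
           condition = object$label_b)) %>%
    mutate(panel = "mean ± SD")
  tpanel <- tibble(node = td$node, t = td$t, panel = "SPM{t}")
  cl <- object$clusters
  p <- ggplot() +
    geom_ribbon(data = waves,
                aes(x = .data$node, ymin = .data$m - .data$s,
                    ymax = .data$m + .data$s, fill = .data$condition),
                alpha = 0.25) +
    geom_line(data = waves,
              aes(x = .data$node, y = .data$m, colour = .data$condition))
  if (nrow(cl))
    p <- p + geom_rect(data = mutate(cl, panel = "SPM{t}"),
                       aes(xmin = .data$start, xmax = .data$end,
                           ymin = -Inf, ymax = Inf),
                       fill = "grey70", alpha = 0.5)
  p +
    geom_line(data = tpanel, aes(x = .data$node, y = .data$t)) +
    geom_hline(data = tibble(y = c(-1, 1) * object$t_star, panel = "SPM{t}"),
               aes(yintercept = .data$y), linetype = "dashed",
               colour = "red") +
    facet_wrap(~panel, scales = "free_y") +
    labs(title = sprintf("%s: %s", object$variable, object$comparison),
         x = "% stride", y = NULL) +
    theme_minimal()
}

#' Plot the detected impacts over the displacement curve
#'
#' @param displacement Displacement series, mm.
#' @param rate Sampling rate, Hz.
#' @param events `gait_events` from [detect_impacts()].
#' @param window Time window (s) to show, default first 10 s.
#' @return A ggplot object.
#' @export
plot_gait_events <- function(displacement, rate, events, window = c(0, 10)) {
  t <- (seq_along(displacement) - 1) / rate
  keep <- t >= window[1] & t <= window[2]
  ev <- events$impact_time[events$impact_time >= window[1] &
                             events$impact_time <= window[2]]
  ggplot(tibble(t = t[keep], d = displacement[keep]),
         aes(.data$t, .data$d)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = ev, colour = "red", linetype = "dotted") +
    labs(x = "time (s)", y = "TS vertical displacement (mm)") +
    theme_minimal()
}
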