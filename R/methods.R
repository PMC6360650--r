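#' Tidy a detection result
#'
#' @param x A `poremod_sites` table.
#' @param ... Unused.
#' @return A plain tibble of per-site results (attributes stripped).
#' @export
tidy.poremod_sites <- function(x, ...) {
  as_tibble(unclass_sites(x))
}

#' One-row summary of a detection result
#'
#' @param x A `poremod_sites` table.
#' @param alpha Significance cutoff used for the `n_significant` count
#'   (default 0.01, on the combined p-value).
#' @param ... Unused.
#' @return Tibble with one row: site counts, the top-ranked position, and the
#'   smallest combined p-value.
#' @export
glance.poremod_sites <- function(x, alpha = 0.01, ...) {
  d <- unclass_sites(x)
  top <- d$ref_position[!is.na(d$rank) & d$rank == 1L]
  tibble(
    n_sites = nrow(d),
    n_ranked = sum(!is.na(d$rank)),
    n_significant = sum(d$p_combined < alpha & !is.na(d$rank), na.rm = TRUE),
    top_position = if (length(top)) top else NA_integer_,
    min_p_combined = suppressWarnings(min(d$p_combined, na.rm = TRUE))
  )
}

unclass_sites <- function(x) {
  attr(x, "config") <- NULL
  class(x) <- setdiff(class(x), "poremod_sites")
  x
}

#' Plot a detection result along the reference
#'
#' Manhattan-style plot of -log10 combined p-values by reference position;
#' accepted (ranked) sites are highlighted and known truth positions can be
#' marked.
#'
#' @param object A `poremod_sites` table.
#' @param truth Optional 0-based truth positions to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poremod_sites <- function(object, truth = NULL, ...) {
  d <- tidy(object)
  d$neglog10p <- -d$log_p_combined / log(10)
  d$accepted <- !is.na(d$rank)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ref_position,
                                       y = .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted), size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#2166AC"),
                                 name = "accepted") +
    ggplot2::labs(x = "reference position (0-based)",
                  y = expression(-log[10] ~ "combined p-value"))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_vline(xintercept = truth, colour = "#B2182B",
                                 alpha = 0.25, linewidth = 0.3)
  }
  p
}

#' Plot precision/recall against the percentile grid
#'
#' @param object A `poremod_pr` table.
#' @param ... Unused.
#' @return A ggplot object with one line per measure (and per method, if a
#'   `method` column is present).
#' @export
autoplot.poremod_pr <- function(object, ...) {
  d <- as_tibble(object)
  d <- tidyr::pivot_longer(d, c("precision", "recall"),
                           names_to = "measure", values_to = "value")
  aes <- if ("method" %in% names(d)) {
    ggplot2::aes(x = .data$percentile * 100, y = .data$value,
                 colour = .data$method, linetype = .data$measure)
  } else {
    ggplot2::aes(x = .data$percentile * 100, y = .data$value,
                 linetype = .data$measure)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ranking percentile (%)", y = NULL)
}

#' Per-site signal distributions for the two groups
#'
#' Density overlay of the pooled normalized signals of both groups at selected
#' positions — useful for inspecting top-ranked candidate sites.
#'
#' @param pooled Pooled site table from [pool_position_signals()].
#' @param positions 0-based reference positions to plot.
#' @return A ggplot object faceted by position.
#' @export
plot_site_signals <- function(pooled, positions) {
  rows <- pooled[pooled$ref_position %in% positions, , drop = FALSE]
  if (nrow(rows) == 0L) abort("no pooled data at the requested positions")
  d <- bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    tibble(
      ref_position = rows$ref_position[i],
      group = rep(c("modified", "control"),
                  c(length(rows$signals1[[i]]), length(rows$signals2[[i]]))),
      signal = c(rows$signals1[[i]], rows$signals2[[i]])
    )
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signal, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~ref_position, scales = "free") +
    ggplot2::labs(x = "normalized signal", y = "density")
}
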