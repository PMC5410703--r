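#' Plot a metaplot profile
#'
#' One line per sequence context over the 5'->3' window axis, with the
#' upstream/body/downstream boundaries marked. Uses ggplot2 when
#' available, otherwise base graphics.
#'
#' @param profile a [metaplot()] (or [resampled_metaplot()]) table.
#' @param main plot title.
#' @return the ggplot object, or `NULL` (base graphics), invisibly.
#' @export
plot_metaplot <- function(profile, main = "gene-body methylation") {
  flank <- attr(profile, "flank_bp")
  breaks <- if (!is.null(flank) && flank > 0L) c(20.5, 40.5) else numeric()
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(profile,
           ggplot2::aes(x = window_index, y = mean_level,
                        colour = context)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_vline(xintercept = breaks, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::labs(x = "window (5' → 3')",
                    y = "weighted methylation", title = main) +
      ggplot2::theme_minimal()
    return(invisible(p))
  }
  ctxs <- unique(profile$context)
  cols <- stats::setNames(seq_along(ctxs), ctxs)
  plot(NA, xlim = range(profile$window_index),
       ylim = c(0, max(profile$mean_level, na.rm = TRUE)),
       xlab = "window (5' -> 3')", ylab = "weighted methylation",
       main = main)
  for (ctx in ctxs) {
    d <- profile[profile$context == ctx, ]
    graphics::lines(d$window_index, d$mean_level, col = cols[[ctx]])
  }
  graphics::abline(v = breaks, lty = 2L, col = "grey60")
  graphics::legend("topright", legend = ctxs, col = cols, lty = 1L,
                   bty = "n")
  invisible(NULL)
}

utils::globalVariables(c(
  "window_index", "mean_level", "context", "meth_reads", "total_reads",
  "covered_sites", "meth_sites", "weighted_level", "gene_id", "strand",
  "region", "out_idx", "position_index", "draw", "sd_level", "n_genes",
  "k", "n", "p_value", "q_value", "label", "chrom", "pos", "level",
  "n_draws"))
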