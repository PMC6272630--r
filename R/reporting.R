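#' Render a benchmark colour map
#'
#' Draws one of the four benchmark colour maps — RMSDmin, RMSDave,
#' N(RMSD < R) or Protocol Score — with structures on the x axis and
#' protocols on the y axis. The colour scale is a continuous monotone map
#' normalised to the grid's value range, oriented so that the best value
#' (lowest for the RMSD metrics, highest for N(RMSD < R) and the score)
#' always sits at the blue end; failed cells get no colour and are marked
#' with an exclamation glyph. Alongside the ggplot object a numeric grid
#' (including the colour index actually used) is returned, and written as
#' TSV when `out_dir` is given, so downstream checks never have to read
#' pixels.
#'
#' For the unbounded RMSD metrics the colour index caps values at `ceiling`
#' (default 10 Angstrom) so a single catastrophic pose cannot wash out the
#' contrast; the cap is presentation-only and the exported `value` column
#' keeps the raw number.
#'
#' @param m a [benchmark_matrix()].
#' @param metric one of `"rmsd_min"`, `"rmsd_ave"`, `"n_below_R"`,
#'   `"score"`.
#' @param ceiling colour-scale cap in Angstrom for RMSD metrics.
#' @param failure_marker glyph drawn on failed cells.
#' @param out_dir if given, `<metric>_map.tsv` and `<metric>_map.png` are
#'   written there.
#' @return object of class `bench_heatmap`: list with `grid` (data.frame:
#'   structure_id, protocol_abbrev, value, colour_index, failed), `plot`
#'   (ggplot), `metric` and `orientation`.
#' @export
render_heatmap <- function(m, metric = c("rmsd_min", "rmsd_ave",
                                         "n_below_R", "score"),
                           ceiling = 10, failure_marker = "!",
                           out_dir = NULL) {
  stopifnot(inherits(m, "benchmark_matrix"))
  if (!is.character(metric) ||
      !metric[1] %in% c("rmsd_min", "rmsd_ave", "n_below_R", "score"))
    stop("unknown metric '", metric[1],
         "'; expected rmsd_min, rmsd_ave, n_below_R or score", call. = FALSE)
  metric <- metric[1]
  orientation <- if (metric %in% c("rmsd_min", "rmsd_ave"))
    "best_is_low" else "best_is_high"
  grid <- data.frame(
    structure_id = m$structure_id, protocol_abbrev = m$protocol_abbrev,
    value = as.numeric(m[[metric]]), failed = m$failed,
    stringsAsFactors = FALSE
  )
  grid$value[grid$failed] <- NA_real_
  v <- grid$value
  if (orientation == "best_is_low") v <- pmin(v, ceiling)
  rng <- range(v, na.rm = TRUE)
  idx <- if (diff(rng) == 0) rep(1, length(v)) else
    (v - rng[1]) / diff(rng)
  if (orientation == "best_is_low") idx <- 1 - idx
  grid$colour_index <- idx            # 1 = best = blue end
  grid$colour_index[grid$failed] <- NA_real_

  grid$structure_id <- factor(grid$structure_id,
                              levels = attr(m, "structures"))
  grid$protocol_abbrev <- factor(grid$protocol_abbrev,
                                 levels = rev(attr(m, "protocols")))
  plt <- ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$structure_id, y = .data$protocol_abbrev,
    fill = .data$colour_index)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(
      data = grid[grid$failed, , drop = FALSE],
      label = failure_marker, colour = "black", size = 4) +
    ggplot2::scale_fill_gradient(low = "red", high = "blue",
                                 limits = c(0, 1), na.value = "white",
                                 name = metric) +
    ggplot2::labs(x = "X-ray structure", y = "docking protocol",
                  title = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  out <- structure(list(grid = grid, plot = plt, metric = metric,
                        orientation = orientation),
                   class = "bench_heatmap")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    exp <- grid
    exp$structure_id <- as.character(exp$structure_id)
    exp$protocol_abbrev <- as.character(exp$protocol_abbrev)
    utils::write.table(exp, file.path(out_dir, paste0(metric, "_map.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ggplot2::ggsave(file.path(out_dir, paste0(metric, "_map.png")), plt,
                    width = 8, height = 6, dpi = 120)
  }
  out
}

#' @export
print.bench_heatmap <- function(x, ...) {
  cat("<bench_heatmap> metric ", x$metric, " (", x$orientation, "), ",
      nrow(x$grid), " cells\n", sep = "")
  print(x$plot)
  invisible(x)
}

#' Rank table with per-cell breakdown
#'
#' Tabular companion of the rank views: one row per protocol (or per
#' protein structure), its summed Protocol Score, rank, and the per-cell
#' score breakdown in wide format.
#'
#' @param m a [benchmark_matrix()].
#' @param by `"protocol"` or `"protein"`.
#' @return data.frame: `name`, `score_sum`, `rank`, then one score column
#'   per structure (or per protocol). Failed cells show NA in the
#'   breakdown but count 0 in the sum.
#' @export
tabulate_ranks <- function(m, by = c("protocol", "protein")) {
  stopifnot(inherits(m, "benchmark_matrix"))
  if (nrow(m) == 0L) stop("empty benchmark matrix", call. = FALSE)
  by <- match.arg(by)
  ranks <- if (by == "protocol") rank_protocols(m) else rank_proteins(m)
  key <- if (by == "protocol") "protocol_abbrev" else "structure_id"
  other <- if (by == "protocol") "structure_id" else "protocol_abbrev"
  wide <- stats::reshape(
    m[, c(key, other, "score")], direction = "wide",
    idvar = key, timevar = other, v.names = "score")
  names(wide) <- sub("^score\\.", "", names(wide))
  out <- merge(ranks, wide, by.x = "name", by.y = key, sort = FALSE)
  out[order(out$rank), , drop = FALSE]
}
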