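#' Protocol Score rubric
#'
#' The per-cell Protocol Score awards one point for each satisfied
#' criterion, giving the 0-3 scale used throughout the benchmark:
#' \itemize{
#'   \item `RMSDmin < R` — the protocol reproduced the crystallographic
#'     binding mode at least once;
#'   \item `RMSDave < R` — the whole pose ensemble sits near the reference,
#'     not just a lucky pose;
#'   \item `n_below_R >= ceiling(fraction * n_poses)` — at least a
#'     `fraction` of the poses individually beat the resolution cutoff.
#' }
#' Thresholds are configurable: `min_threshold`/`ave_threshold` replace the
#' per-structure resolution R when set, and `fraction` (default 0.5) tunes
#' the ensemble criterion.
#'
#' @param fraction required fraction of poses below R, in (0, 1].
#' @param min_threshold,ave_threshold fixed RMSD thresholds in Angstrom, or
#'   `NULL` to use each structure's resolution R.
#' @return object of class `score_rubric`.
#' @export
score_rubric <- function(fraction = 0.5, min_threshold = NULL,
                         ave_threshold = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  for (th in list(min_threshold, ave_threshold))
    if (!is.null(th) && (!is.numeric(th) || th <= 0))
      stop("thresholds must be positive", call. = FALSE)
  structure(list(fraction = fraction, min_threshold = min_threshold,
                 ave_threshold = ave_threshold),
            class = "score_rubric")
}

#' Count poses with RMSD below the resolution
#'
#' The N(RMSD < R) quality metric: how many poses of a run individually
#' beat the structure's crystallographic resolution. "Below" is strict.
#'
#' @param rmsds numeric vector of pose RMSDs in Angstrom.
#' @param R resolution cutoff in Angstrom, > 0.
#' @return integer count.
#' @export
n_below_resolution <- function(rmsds, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("R must be a single positive number", call. = FALSE)
  sum(rmsds < R)
}

#' Protocol Score of one benchmark cell
#'
#' @param stats list (or one-row data.frame) with `rmsd_min`, `rmsd_ave`,
#'   `n_below_R` and `n_poses`.
#' @param R resolution cutoff in Angstrom.
#' @param rubric a [score_rubric()].
#' @return integer score in 0..3.
#' @export
protocol_score <- function(stats, R, rubric = score_rubric()) {
  stopifnot(inherits(rubric, "score_rubric"))
  th_min <- if (is.null(rubric$min_threshold)) R else rubric$min_threshold
  th_ave <- if (is.null(rubric$ave_threshold)) R else rubric$ave_threshold
  need <- ceiling(rubric$fraction * stats$n_poses)
  sum(stats$rmsd_min < th_min,
      stats$rmsd_ave < th_ave,
      stats$n_below_R >= need)
}

#' Evaluate one structure-protocol benchmark cell
#'
#' Computes the heavy-atom RMSD of every pose against the crystallographic
#' reference ligand (see [rmsd()]; positional correspondence, no refit),
#' and derives the cell statistics: RMSDmin, RMSDmax, RMSDave (arithmetic
#' mean over all returned poses), the N(RMSD < R) count and the Protocol
#' Score. An empty pose set, or a pose set whose atoms do not correspond to
#' the reference, yields a failed cell carrying no statistics.
#'
#' @param ref a [reference_complex()]; its `resolution` is the cutoff R.
#' @param poses a [pose_set()].
#' @param rubric a [score_rubric()].
#' @return one-row data.frame (class `benchmark_cell`) with columns
#'   `structure_id`, `protocol_abbrev`, `rmsd_min`, `rmsd_max`, `rmsd_ave`,
#'   `n_below_R`, `n_poses`, `score`, `failed`, `reason`.
#' @export
evaluate_cell <- function(ref, poses, rubric = score_rubric()) {
  stopifnot(inherits(ref, "reference_complex"), inherits(poses, "pose_set"))
  cell <- function(rmsd_min = NA_real_, rmsd_max = NA_real_,
                   rmsd_ave = NA_real_, n_below_R = NA_integer_,
                   n_poses = NA_integer_, score = NA_integer_,
                   failed = FALSE, reason = NA_character_) {
    structure(data.frame(
      structure_id = poses$structure_id,
      protocol_abbrev = poses$protocol_abbrev,
      rmsd_min = rmsd_min, rmsd_max = rmsd_max, rmsd_ave = rmsd_ave,
      n_below_R = n_below_R, n_poses = n_poses, score = score,
      failed = failed, reason = reason, stringsAsFactors = FALSE
    ), class = c("benchmark_cell", "data.frame"))
  }
  if (length(poses$poses) == 0L)
    return(cell(failed = TRUE, reason = "no poses"))
  r <- try(vapply(poses$poses, rmsd, numeric(1), b = ref$ligand),
           silent = TRUE)
  if (inherits(r, "try-error"))
    return(cell(failed = TRUE, reason = conditionMessage(attr(r, "condition"))))
  n_below <- n_below_resolution(r, ref$resolution)
  stats <- list(rmsd_min = min(r), rmsd_ave = mean(r),
                n_below_R = n_below, n_poses = length(r))
  cell(rmsd_min = min(r), rmsd_max = max(r), rmsd_ave = mean(r),
       n_below_R = as.integer(n_below), n_poses = length(r),
       score = as.integer(protocol_score(stats, ref$resolution, rubric)))
}

#' Assemble a complete benchmark matrix
#'
#' A benchmark matrix is the full structure x protocol grid of evaluated
#' cells; every combination is present, failures included as flagged cells,
#' so a run over 20 structures and the full 17-protocol registry always has
#' 340 cells.
#'
#' @param cells data.frame of [evaluate_cell()] rows.
#' @param structures,protocols orderings for the grid axes; defaults are
#'   the orders of first appearance in `cells`.
#' @return object of class `benchmark_matrix`: the cell data.frame with
#'   `structures` and `protocols` attributes.
#' @export
benchmark_matrix <- function(cells,
                             structures = unique(cells$structure_id),
                             protocols = unique(cells$protocol_abbrev)) {
  stopifnot(is.data.frame(cells))
  key <- paste(cells$structure_id, cells$protocol_abbrev)
  if (anyDuplicated(key))
    stop("duplicate structure-protocol cells", call. = FALSE)
  grid <- expand.grid(structure_id = structures, protocol_abbrev = protocols,
                      stringsAsFactors = FALSE)
  gkey <- paste(grid$structure_id, grid$protocol_abbrev)
  if (!setequal(key, gkey))
    stop("incomplete benchmark grid: expected ",
         length(structures), " x ", length(protocols), " = ",
         nrow(grid), " cells, got ", nrow(cells), call. = FALSE)
  cells <- cells[match(gkey, key), , drop = FALSE]
  rownames(cells) <- NULL
  ok <- !cells$failed
  stopifnot(all(cells$rmsd_min[ok] <= cells$rmsd_ave[ok] + 1e-12),
            all(cells$rmsd_ave[ok] <= cells$rmsd_max[ok] + 1e-12))
  structure(cells, structures = structures, protocols = protocols,
            class = c("benchmark_matrix", "data.frame"))
}

#' Evaluate a full grid of pose sets
#'
#' @param references list of [reference_complex()].
#' @param pose_sets list of [pose_set()] covering the full grid (missing
#'   combinations become failed cells).
#' @param rubric a [score_rubric()].
#' @return a [benchmark_matrix()].
#' @export
evaluate_matrix <- function(references, pose_sets, rubric = score_rubric()) {
  refs <- stats::setNames(references,
                          vapply(references, `[[`, character(1), "pdb_id"))
  protocols <- unique(vapply(pose_sets, `[[`, character(1),
                             "protocol_abbrev"))
  cells <- vector("list", length(names(refs)) * length(protocols))
  k <- 0L
  idx <- stats::setNames(
    seq_along(pose_sets),
    vapply(pose_sets, function(p) paste(p$structure_id, p$protocol_abbrev),
           character(1)))
  for (sid in names(refs)) {
    for (proto in protocols) {
      k <- k + 1L
      i <- idx[paste(sid, proto)]
      ps <- if (is.na(i)) {
        pose_set(sid, refs[[sid]]$ligand_code, proto, list())
      } else pose_sets[[i]]
      cells[[k]] <- evaluate_cell(refs[[sid]], ps, rubric)
    }
  }
  benchmark_matrix(do.call(rbind, cells), structures = names(refs),
                   protocols = protocols)
}

#' @export
print.benchmark_matrix <- function(x, ...) {
  s <- attr(x, "structures") %||% unique(x$structure_id)
  p <- attr(x, "protocols") %||% unique(x$protocol_abbrev)
  cat("<benchmark_matrix> ", length(s), " structures x ",
      length(p), " protocols = ", nrow(x), " cells (",
      sum(x$failed), " failed)\n", sep = "")
  NextMethod()
}

rank_by <- function(m, field) {
  stopifnot(inherits(m, "benchmark_matrix"))
  score <- ifelse(m$failed, 0L, m$score)  # failed cells contribute nothing
  sums <- tapply(score, m[[field]], sum)
  out <- data.frame(name = names(sums), score_sum = as.integer(sums),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score_sum, out$name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank docking protocols by summed Protocol Score
#'
#' Sums each protocol's score over all structures (failed cells count 0)
#' and sorts in descending order; ties break alphabetically.
#'
#' @param m a [benchmark_matrix()].
#' @return data.frame with columns `name`, `score_sum`, `rank`.
#' @export
rank_protocols <- function(m) rank_by(m, "protocol_abbrev")

#' Rank protein structures by summed Protocol Score
#'
#' Same aggregation as [rank_protocols()], summed over protocols for each
#' structure: high-sum structures are the robust choices for subsequent
#' virtual screening.
#'
#' @inheritParams rank_protocols
#' @return data.frame with columns `name`, `score_sum`, `rank`.
#' @export
rank_proteins <- function(m) rank_by(m, "structure_id")

#' Write the benchmark summary file
#'
#' One TSV row per cell, named per the output naming scheme, with
#' RMSDmin/max/ave, N(RMSD < R), the Protocol Score and the failure flag;
#' failed rows carry the flag and no statistics. [read_summary()] restores
#' the matrix exactly.
#'
#' @param m a [benchmark_matrix()].
#' @param file output path, or `NULL` for text only.
#' @param ligand_codes optional named character vector mapping structure id
#'   to ligand code (used for the name column; defaults to "lig").
#' @return the TSV text, invisibly.
#' @export
write_summary <- function(m, file = NULL, ligand_codes = NULL) {
  stopifnot(inherits(m, "benchmark_matrix"))
  lig <- if (is.null(ligand_codes)) rep("lig", nrow(m)) else
    unname(ligand_codes[m$structure_id])
  out <- data.frame(
    name = mapply(format_output_name, lig, m$structure_id,
                  m$protocol_abbrev, USE.NAMES = FALSE),
    m[, c("structure_id", "protocol_abbrev", "rmsd_min", "rmsd_max",
          "rmsd_ave", "n_below_R", "n_poses", "score", "failed")],
    stringsAsFactors = FALSE
  )
  con <- textConnection("txt", "w", local = TRUE)
  utils::write.table(format(out, digits = 17, trim = TRUE, justify = "none"),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  txt <- paste0(paste(txt, collapse = "\n"), "\n")
  if (!is.null(file)) cat(txt, file = file)
  invisible(txt)
}

#' Read a benchmark summary file back into a matrix
#'
#' @param file path to a TSV written by [write_summary()].
#' @return a [benchmark_matrix()].
#' @export
read_summary <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  cells <- d[, c("structure_id", "protocol_abbrev", "rmsd_min", "rmsd_max",
                 "rmsd_ave", "n_below_R", "n_poses", "score", "failed")]
  cells$n_below_R <- as.integer(cells$n_below_R)
  cells$n_poses <- as.integer(cells$n_poses)
  cells$score <- as.integer(cells$score)
  cells$reason <- ifelse(cells$failed, "flagged in summary", NA_character_)
  benchmark_matrix(cells)
}
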