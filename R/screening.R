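#' Split a screening library into chunks
#'
#' Large SDF libraries are docked in pieces; this splits the molecule list
#' into consecutive chunks whose concatenation restores the original order
#' exactly. All chunks have `chunk_size` records except possibly the last.
#'
#' @param library non-empty list of [molecule()].
#' @param chunk_size records per chunk, >= 1; see [default_chunk_size()].
#' @return list of `library_chunk` objects (fields `index`, `molecules`,
#'   `start`, `end`).
#' @export
split_library <- function(library, chunk_size) {
  if (length(library) == 0L) stop("empty library", call. = FALSE)
  if (!is.numeric(chunk_size) || chunk_size < 1)
    stop("chunk_size must be >= 1", call. = FALSE)
  chunk_size <- as.integer(chunk_size)
  n <- length(library)
  starts <- seq(1L, n, by = chunk_size)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    e <- min(s + chunk_size - 1L, n)
    structure(list(index = i, molecules = library[s:e], start = s, end = e),
              class = "library_chunk")
  })
}

#' Default chunk size for a library
#'
#' Aims at roughly four waves of chunks per available slot so lanes stay
#' load-balanced without excessive file churn.
#'
#' @param n library size.
#' @param effective_slots concurrent slots of the chosen protocol's lane.
#' @return integer chunk size >= 1.
#' @export
default_chunk_size <- function(n, effective_slots) {
  max(1L, as.integer(ceiling(n / (4 * effective_slots))))
}

#' Merge chunks back into a library
#'
#' @param chunks list of `library_chunk`.
#' @return list of [molecule()] in original library order.
#' @export
merge_chunks <- function(chunks) {
  chunks <- chunks[order(vapply(chunks, `[[`, integer(1), "index"))]
  do.call(c, lapply(chunks, `[[`, "molecules"))
}

#' Spike benchmark ligands into a screening library
#'
#' Appends the ligands used in the benchmark study to the library as known
#' actives (tagged `BENCHMARK_LIGAND = "yes"` in their SD tags) so that
#' enrichment can be assessed after the screen.
#'
#' @param library list of [molecule()].
#' @param benchmark_ligands list of [molecule()] to append (possibly empty).
#' @return the spiked library.
#' @export
spike_benchmark_ligands <- function(library, benchmark_ligands) {
  tagged <- lapply(benchmark_ligands, function(m) {
    m$sd_tags["BENCHMARK_LIGAND"] <- "yes"
    m
  })
  c(library, tagged)
}

#' Merge screening results and rank globally
#'
#' Combines per-chunk result sets, keeps the best-scoring pose per molecule
#' id (the molecule name), and sorts in the scoring function's favourable
#' direction — ascending for `lower_better` scores, descending for
#' `higher_better`; ties break by molecule id. Records whose score tag is
#' missing or unparseable are warned about and ranked last. The result is
#' independent of how the library was chunked and of input order.
#'
#' @param chunks list of result sets: each element either a list of
#'   [molecule()] or a path to an SDF result file.
#' @param score_tag name of the SD tag holding the docking score.
#' @param direction `"lower_better"` or `"higher_better"` (each scoring
#'   function's convention is in [dock_protocols()]).
#' @return object of class `vs_ranking`: data.frame with columns `id`,
#'   `score`, `rank`, plus a `direction` attribute.
#' @export
merge_and_rank <- function(chunks, score_tag,
                           direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  mols <- do.call(c, lapply(chunks, function(ch)
    if (is.character(ch)) read_sdf(ch) else ch))
  ids <- vapply(mols, `[[`, character(1), "name")
  scores <- vapply(mols, function(m) {
    v <- suppressWarnings(as.numeric(m$sd_tags[score_tag]))
    if (length(v) == 0L) NA_real_ else v
  }, numeric(1))
  if (anyNA(scores))
    warning(sum(is.na(scores)), " record(s) without a parseable '",
            score_tag, "' tag; ranked last", call. = FALSE)
  better <- function(x, y) {
    if (is.na(x)) return(FALSE)
    if (is.na(y)) return(TRUE)
    if (direction == "lower_better") x < y else x > y
  }
  best <- list()
  for (i in seq_along(ids)) {
    cur <- best[[ids[i]]]
    if (is.null(cur) || better(scores[i], cur)) best[[ids[i]]] <- scores[i]
  }
  out <- data.frame(id = names(best),
                    score = unname(unlist(best)),
                    stringsAsFactors = FALSE)
  key <- if (direction == "lower_better") out$score else -out$score
  out <- out[order(is.na(out$score), key, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, direction = direction,
            class = c("vs_ranking", "data.frame"))
}

#' Estimate wall-clock time for a screening campaign
#'
#' First-order estimate from the benchmark's measured average execution
#' time per ligand-protein complex and the number of slots the protocol's
#' lane provides: `n_ligands * avg_exec_time / effective_slots`.
#'
#' @param n_ligands library size, > 0.
#' @param avg_exec_time average seconds per docking run, > 0.
#' @param effective_slots concurrent slots available to the protocol, > 0.
#' @return estimated seconds.
#' @export
estimate_time <- function(n_ligands, avg_exec_time, effective_slots) {
  if (any(c(n_ligands, avg_exec_time, effective_slots) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  n_ligands * avg_exec_time / effective_slots
}

#' Restart manifest for an interrupted screening run
#'
#' Lists the chunk-protocol work items still pending, so a resumed run does
#' no duplicate work and, once merged, is indistinguishable from an
#' uninterrupted one.
#'
#' @param planned data.frame with columns `chunk` and `protocol`: the full
#'   work plan.
#' @param completed data.frame (same columns) of finished items; must be a
#'   subset of `planned`.
#' @param file optional path; the manifest TSV (chunk, protocol, status) is
#'   written there.
#' @return data.frame of pending items with a `status` column
#'   (`"pending"`), invisibly written to `file` when given.
#' @export
write_restart_manifest <- function(planned, completed, file = NULL) {
  stopifnot(is.data.frame(planned), is.data.frame(completed),
            all(c("chunk", "protocol") %in% names(planned)))
  pk <- paste(planned$chunk, planned$protocol)
  if (nrow(completed)) {
    ck <- paste(completed$chunk, completed$protocol)
    if (!all(ck %in% pk))
      stop("consistency error: completed item(s) not in the plan: ",
           paste(setdiff(ck, pk), collapse = "; "), call. = FALSE)
  } else ck <- character(0)
  pending <- planned[!pk %in% ck, c("chunk", "protocol"), drop = FALSE]
  pending$status <- rep("pending", nrow(pending))
  rownames(pending) <- NULL
  if (!is.null(file))
    utils::write.table(pending, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  pending
}
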