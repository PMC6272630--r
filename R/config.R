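#' Benchmark configuration
#'
#' Bundles the tunable settings shared by every protocol, with the
#' standard defaults: 20 output poses per run, a 1.0 Angstrom RMSD
#' threshold for calling poses unique (an engine-side setting, carried in
#' the configuration only), a 20 Angstrom binding-cavity radius and a
#' 0.375 Angstrom grid spacing for grid-based engines.
#'
#' @param poses_per_run output conformations per docking run (default 20).
#' @param unique_pose_rmsd_threshold RMSD below which two poses count as
#'   the same pose, Angstrom (default 1.0).
#' @param cavity_radius inclusion-sphere radius, Angstrom (default 20).
#' @param grid_spacing grid spacing, Angstrom (default 0.375).
#' @param rubric a [score_rubric()].
#' @param scheduler_policy optional [license_policy()] for dispatch
#'   simulation.
#' @return object of class `bench_config`.
#' @export
bench_config <- function(poses_per_run = 20L,
                         unique_pose_rmsd_threshold = 1.0,
                         cavity_radius = 20,
                         grid_spacing = 0.375,
                         rubric = score_rubric(),
                         scheduler_policy = NULL) {
  num <- c(poses_per_run = poses_per_run,
           unique_pose_rmsd_threshold = unique_pose_rmsd_threshold,
           cavity_radius = cavity_radius, grid_spacing = grid_spacing)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad))
    stop("validation error: non-positive value for ",
         paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(inherits(rubric, "score_rubric"))
  structure(list(
    poses_per_run = as.integer(poses_per_run),
    unique_pose_rmsd_threshold = as.numeric(unique_pose_rmsd_threshold),
    cavity_radius = as.numeric(cavity_radius),
    grid_spacing = as.numeric(grid_spacing),
    rubric = rubric, scheduler_policy = scheduler_policy
  ), class = "bench_config")
}

#' @export
print.bench_config <- function(x, ...) {
  cat("<bench_config>\n",
      "  poses_per_run:              ", x$poses_per_run, "\n",
      "  unique_pose_rmsd_threshold: ", x$unique_pose_rmsd_threshold, " A\n",
      "  cavity_radius:              ", x$cavity_radius, " A (cube side ",
      round(cube_side(x$cavity_radius), 4), " A)\n",
      "  grid_spacing:               ", x$grid_spacing, " A\n", sep = "")
  invisible(x)
}

config_keys <- c("poses_per_run", "unique_pose_rmsd_threshold",
                 "cavity_radius", "grid_spacing", "rubric_fraction")

#' Load a benchmark configuration file
#'
#' Reads a flat `key = value` (or `key: value`) file; keys not present
#' take the defaults of [bench_config()]. Valid keys: `poses_per_run`,
#' `unique_pose_rmsd_threshold`, `cavity_radius`, `grid_spacing`,
#' `rubric_fraction`. The fully resolved configuration is echoed to the
#' message stream.
#'
#' @param path path to the config file, or `NULL` for pure defaults.
#' @return a [bench_config()].
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("config parse error at line: '", ln, "'", call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% config_keys)
        stop("unknown config key '", key, "'; valid keys: ",
             paste(config_keys, collapse = ", "), call. = FALSE)
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v))
        stop("validation error: non-numeric value for '", key, "'",
             call. = FALSE)
      vals[[key]] <- v
    }
  }
  rubric <- if (is.null(vals$rubric_fraction)) score_rubric() else
    score_rubric(fraction = vals$rubric_fraction)
  vals$rubric_fraction <- NULL
  cfg <- do.call(bench_config, c(vals, list(rubric = rubric)))
  message(sprintf(
    "resolved config: poses_per_run=%d rmsd_threshold=%g cavity_radius=%g grid_spacing=%g",
    cfg$poses_per_run, cfg$unique_pose_rmsd_threshold, cfg$cavity_radius,
    cfg$grid_spacing))
  cfg
}

#' Run a full benchmark from a manifest
#'
#' Orchestrates the whole pipeline: reads the reference ligands (mol2) and
#' pose files (SDF) listed in the manifest, evaluates every
#' structure-protocol cell (missing or unreadable pose files become
#' flagged failures — the run always completes), assembles the complete
#' benchmark matrix, and writes the summary TSV plus the four colour maps
#' with their numeric grid exports to `out_dir`. Inputs are never
#' modified; reruns on the same inputs produce byte-identical summaries.
#'
#' @param manifest path to a manifest TSV, or an equivalent data.frame,
#'   with columns `pdb_id`, `resolution`, `ligand_mol2`, `protocol`,
#'   `poses_sdf`.
#' @param config a [bench_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return object of class `bench_run`: list with `matrix` (a
#'   [benchmark_matrix()]), `protocol_ranks`, `protein_ranks`, `n_failed`,
#'   and `paths` of written files.
#' @export
run_bench <- function(manifest, config = bench_config(), out_dir = NULL) {
  man <- if (is.data.frame(manifest)) manifest else
    utils::read.table(manifest, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("pdb_id", "resolution", "ligand_mol2", "protocol", "poses_sdf")
  if (!all(need %in% names(man)))
    stop("manifest error: missing column(s) ",
         paste(setdiff(need, names(man)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(man$pdb_id, man$protocol)))
    stop("manifest error: duplicate structure-protocol rows", call. = FALSE)
  bad_res <- !is.finite(man$resolution) | man$resolution <= 0
  if (any(bad_res))
    stop("manifest error: non-positive resolution for ",
         paste(unique(man$pdb_id[bad_res]), collapse = ", "), call. = FALSE)

  structures <- unique(man$pdb_id)
  protocols <- unique(man$protocol)
  refs <- lapply(structures, function(sid) {
    row <- man[man$pdb_id == sid, ][1, ]
    lig <- read_mol2(row$ligand_mol2)
    code <- sub("-.*$", "", basename(row$ligand_mol2))
    reference_complex(sid, row$resolution, code, lig)
  })
  names(refs) <- structures

  pose_sets <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    code <- refs[[row$pdb_id]]$ligand_code
    poses <- if (file.exists(row$poses_sdf)) {
      tryCatch(read_sdf(row$poses_sdf), error = function(e) {
        warning("unreadable pose file ", row$poses_sdf, ": ",
                conditionMessage(e), call. = FALSE)
        list()
      })
    } else {
      warning("missing pose file ", row$poses_sdf, "; cell flagged failed",
              call. = FALSE)
      list()
    }
    pose_set(row$pdb_id, code, row$protocol, poses)
  })

  m <- evaluate_matrix(refs, pose_sets, config$rubric)
  lig_codes <- stats::setNames(
    vapply(refs, `[[`, character(1), "ligand_code"), structures)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summary_path <- file.path(out_dir, "summary.tsv")
    write_summary(m, summary_path, ligand_codes = lig_codes)
    paths <- summary_path
    for (metric in c("rmsd_min", "rmsd_ave", "n_below_R", "score")) {
      render_heatmap(m, metric, out_dir = out_dir)
      paths <- c(paths, file.path(out_dir, paste0(metric, "_map.tsv")),
                 file.path(out_dir, paste0(metric, "_map.png")))
    }
  }
  structure(list(matrix = m, protocol_ranks = rank_protocols(m),
                 protein_ranks = rank_proteins(m),
                 n_failed = sum(m$failed), paths = paths),
            class = "bench_run")
}

#' @export
print.bench_run <- function(x, ...) {
  cat("<bench_run> ", nrow(x$matrix), " cells, ", x$n_failed, " failed\n",
      "top protocol: ", x$protocol_ranks$name[1], " (score sum ",
      x$protocol_ranks$score_sum[1], ")\n", sep = "")
  invisible(x)
}
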