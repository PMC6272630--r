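#' Read a Tripos mol2 file
#'
#' Reads a ligand (or receptor) structure in Tripos mol2 format into a
#' [molecule()]. Parsing of the record structure is delegated to
#' [bio3d::read.mol2()]; element symbols are inferred from the SYBYL atom
#' type (the token before the "."), falling back to the leading letters of
#' the atom name, with a warning, when the type is not a known element.
#' Atom order and coordinates are kept exactly as written; nothing is
#' recentred or stripped on read.
#'
#' @param file path to a mol2 file containing `@<TRIPOS>MOLECULE` and
#'   `@<TRIPOS>ATOM` records.
#' @return a [molecule()]; partial charges are captured from the charge
#'   column when present.
#' @examples
#' f <- tempfile(fileext = ".mol2")
#' write_mol2(molecule("co", c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0))), f)
#' read_mol2(f)
#' @export
read_mol2 <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!any(grepl("^@<TRIPOS>MOLECULE", lines)))
    stop("mol2 parse error: no @<TRIPOS>MOLECULE record in '", file, "'",
         call. = FALSE)
  if (!any(grepl("^@<TRIPOS>ATOM", lines)))
    stop("mol2 parse error: no @<TRIPOS>ATOM record in '", file,
         "' (searched ", length(lines), " lines)", call. = FALSE)
  m2 <- suppressWarnings(bio3d::read.mol2(file))
  at <- m2$atom
  element <- sub("\\..*$", "", at$elety)
  known <- normalise_element(element) %in% names(atomic_weights)
  if (!all(known)) {
    fallback <- sub("[^A-Za-z].*$", "", at$elena[!known])
    warning("element not recognisable from SYBYL type(s) ",
            paste(unique(at$elety[!known]), collapse = ", "),
            "; falling back to atom-name prefix", call. = FALSE)
    element[!known] <- fallback
  }
  molecule(
    name = if (is.null(m2$name) || !nzchar(m2$name)) "mol" else m2$name,
    element = element,
    coords = cbind(at$x, at$y, at$z),
    charges = if ("charge" %in% names(at)) at$charge else NULL
  )
}

#' Write a molecule to a Tripos mol2 file
#'
#' Inverse of [read_mol2()]; coordinates survive the round trip to 4
#' decimals and atom order is preserved. Atoms are written with their plain
#' element symbol as SYBYL type (no hybridisation suffix) and no bond
#' records, which is sufficient for the purely geometric pipeline.
#'
#' @param mol a [molecule()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mol2 <- function(mol, file) {
  at <- mol$atoms
  n <- nrow(at)
  charge <- ifelse(is.na(at$charge), 0, at$charge)
  m2 <- structure(list(
    atom = data.frame(
      eleno = seq_len(n),
      elena = paste0(at$element, seq_len(n)),
      x = at$x, y = at$y, z = at$z,
      elety = at$element,
      resno = rep(1L, n), resid = rep("LIG", n),
      charge = charge, statbit = rep(NA_character_, n),
      stringsAsFactors = FALSE
    ),
    bond = NULL, substructure = NULL,
    xyz = matrix(as.numeric(t(as.matrix(at[, c("x", "y", "z")]))), nrow = 1),
    info = c(n, 0, 0, 0, 0),
    name = mol$name
  ), class = "mol2")
  bio3d::write.mol2(m2, file = file)
  invisible(file)
}

# -- SDF V2000 ---------------------------------------------------------------
# Hand-written codec: the pipeline emits topology-free pose records (0 bonds,
# down to 1 atom), which the installed SDF container libraries reject as
# invalid. Only the fields the geometric pipeline touches are modelled:
# atoms (element + coordinates), record name and data tags.

#' Read an SD file (V2000)
#'
#' One [molecule()] per record, in file order; SD data tags are preserved in
#' `sd_tags`. An empty file yields an empty list. V3000 connection tables
#' are rejected.
#'
#' @param file path to an SD file.
#' @return list of [molecule()].
#' @export
read_sdf <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L)
    stop("SDF parse error: no record terminator ($$$$) found", call. = FALSE)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:(ends[k] - 1L)]
    # tolerate blank separator lines between records: realign so that the
    # counts line (carrying the V2000 marker) sits at record line 4
    while (length(rec) >= 5L && !nzchar(trimws(rec[1L])) &&
           !grepl("V2000", rec[4L]) && grepl("V2000", rec[5L])) {
      rec <- rec[-1L]
    }
    mols[[k]] <- parse_sdf_record(rec, k)
  }
  mols
}

parse_sdf_record <- function(rec, index) {
  if (length(rec) < 4L)
    stop("SDF parse error: truncated record ", index, call. = FALSE)
  counts <- rec[4L]
  if (grepl("V3000", counts))
    stop("SDF record ", index, " uses a V3000 connection table; ",
         "only V2000 is supported", call. = FALSE)
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(natoms) || natoms < 1L)
    stop("SDF parse error: bad counts line in record ", index, call. = FALSE)
  if (length(rec) < 4L + natoms)
    stop("SDF parse error: truncated record ", index,
         " (expected ", natoms, " atom lines)", call. = FALSE)
  atom_lines <- rec[5:(4L + natoms)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  el <- trimws(substr(atom_lines, 32, 34))
  if (anyNA(c(x, y, z)))
    stop("SDF parse error: bad atom line in record ", index, call. = FALSE)
  rest <- rec[-seq_len(4L + natoms)]
  molecule(name = trimws(rec[1L]), element = el, coords = cbind(x, y, z),
           sd_tags = parse_sd_tags(rest))
}

parse_sd_tags <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) return(character(0))
  tags <- character(0)
  for (h in hdr) {
    name <- sub("^>[^<]*<([^>]+)>.*$", "\\1", lines[h])
    i <- h + 1L
    val <- character(0)
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           !startsWith(lines[i], ">")) {
      val <- c(val, lines[i])
      i <- i + 1L
    }
    tags[name] <- paste(val, collapse = "\n")
  }
  tags
}

#' Write molecules to an SD file (V2000)
#'
#' @param mols a [molecule()] or list of them.
#' @param file output path, or `NULL` to return the text only.
#' @return the SDF text as a character scalar, invisibly.
#' @export
write_sdf <- function(mols, file = NULL) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  stopifnot(length(mols) >= 0,
            all(vapply(mols, inherits, logical(1), "molecule")))
  blocks <- vapply(mols, sdf_record_string, character(1))
  txt <- paste(blocks, collapse = "")
  if (!is.null(file)) cat(txt, file = file)
  invisible(txt)
}

sdf_record_string <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  if (n > 999L)
    stop("molecule '", mol$name, "' has ", n,
         " atoms; V2000 records support at most 999", call. = FALSE)
  lines <- c(
    mol$name,
    "  benchpose",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            at$x, at$y, at$z, at$element),
    "M  END"
  )
  for (tag in names(mol$sd_tags)) {
    lines <- c(lines, sprintf("> <%s>", tag),
               strsplit(mol$sd_tags[[tag]], "\n", fixed = TRUE)[[1]], "")
  }
  paste0(paste(lines, collapse = "\n"), "\n$$$$\n")
}

# -- PDB metadata ------------------------------------------------------------

#' Extract benchmark metadata from a PDB file
#'
#' Reads only the header records a benchmark needs: the crystallographic
#' resolution from the `REMARK   2 RESOLUTION.` record and the bound
#' chemical component codes from `HET` records (waters, residue name HOH,
#' are excluded). No 3D protein parsing is done.
#'
#' @param file path to a PDB-format file.
#' @return list with `resolution` (Angstrom) and `ligand_codes` (character
#'   vector in file order, unique).
#' @export
parse_pdb_metadata <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rem) == 0L)
    stop("PDB metadata error: no 'REMARK   2 RESOLUTION.' record; ",
         "enter the resolution manually", call. = FALSE)
  if (any(grepl("NOT APPLICABLE", rem)))
    stop("PDB metadata error: resolution is 'NOT APPLICABLE'; ",
         "enter the resolution manually", call. = FALSE)
  res <- suppressWarnings(
    as.numeric(sub("^REMARK   2 RESOLUTION\\. *([0-9.]+).*$", "\\1", rem[1]))
  )
  if (is.na(res))
    stop("PDB metadata error: unparseable resolution record: ", rem[1],
         call. = FALSE)
  het <- grep("^HET ", lines, value = TRUE)
  codes <- unique(trimws(substr(het, 8, 10)))
  codes <- codes[nzchar(codes) & codes != "HOH"]
  list(resolution = res, ligand_codes = codes)
}

# -- selection & naming ------------------------------------------------------

#' Select the preferred binding record
#'
#' Applies the affinity-measure hierarchy Ki > Kd > IC50: the returned
#' record belongs to the highest-priority measure present. Within that
#' measure the strongest (lowest-value) record is returned, which makes the
#' selection invariant to input order.
#'
#' @param records list of [binding_record()].
#' @return a [binding_record()], or `NULL` for an empty list.
#' @export
select_binding_record <- function(records) {
  if (length(records) == 0L) return(NULL)
  stopifnot(all(vapply(records, inherits, logical(1), "binding_record")))
  for (measure in c("Ki", "Kd", "IC50")) {
    hits <- Filter(function(r) r$measure == measure, records)
    if (length(hits)) {
      vals <- vapply(hits, `[[`, numeric(1), "value")
      units <- vapply(hits, `[[`, character(1), "unit")
      return(hits[[order(vals, units)[1L]]])
    }
  }
  NULL
}

#' Filter reference complexes by resolution cutoff
#'
#' Keeps complexes with resolution strictly below `cutoff` (the benchmark
#' selection criterion R < cutoff), preserving input order.
#'
#' @param complexes list of [reference_complex()].
#' @param cutoff resolution cutoff in Angstrom, > 0.
#' @return filtered list.
#' @export
filter_by_resolution <- function(complexes, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number", call. = FALSE)
  Filter(function(x) x$resolution < cutoff, complexes)
}

#' Canonical output file name for a benchmark run
#'
#' Builds the "ligand abbreviation - protein identifier - protocol
#' abbreviation" name used for every generated file, e.g.
#' `"stu-1NVR-VINA-std"`. The ligand code is lower-cased.
#'
#' @param ligand_code 3-letter ligand id.
#' @param pdb_id PDB code.
#' @param protocol_abbrev protocol abbreviation.
#' @return character scalar.
#' @export
format_output_name <- function(ligand_code, pdb_id, protocol_abbrev) {
  parts <- c(ligand_code, pdb_id, protocol_abbrev)
  if (any(!nzchar(parts)) || any(is.na(parts)))
    stop("all name parts must be non-empty", call. = FALSE)
  if (any(grepl("[/\\\\]", parts)))
    stop("name parts must not contain path separators", call. = FALSE)
  paste(tolower(ligand_code), pdb_id, protocol_abbrev, sep = "-")
}

#' Split a formatted output name into its parts
#'
#' Protocol abbreviations themselves contain hyphens, so the protocol part
#' is recognised as the longest registry abbreviation that suffixes the
#' name; the remainder splits into ligand code and PDB id at its first
#' hyphen.
#'
#' @param name a name produced by [format_output_name()].
#' @param protocols character vector of valid protocol abbreviations
#'   (default: the full registry).
#' @return list with `ligand_code`, `pdb_id`, `protocol_abbrev`.
#' @export
parse_output_name <- function(name, protocols = dock_protocols()$abbreviation) {
  hit <- protocols[vapply(protocols, function(p)
    endsWith(name, paste0("-", p)), logical(1))]
  if (length(hit) == 0L)
    stop("no registry protocol abbreviation matches '", name, "'",
         call. = FALSE)
  proto <- hit[which.max(nchar(hit))]
  stem <- substr(name, 1, nchar(name) - nchar(proto) - 1L)
  cut <- regexpr("-", stem, fixed = TRUE)
  if (cut < 0)
    stop("cannot split '", stem, "' into ligand and PDB id", call. = FALSE)
  list(ligand_code = substr(stem, 1, cut - 1L),
       pdb_id = substring(stem, cut + 1L),
       protocol_abbrev = proto)
}

#' Detect missing docking outputs
#'
#' Compares the benchmark plan against the output files actually present
#' and flags every structure-protocol pair with no matching file as a
#' failed job. A file matches a pair when its base name (extension
#' stripped) ends with `"<structure>-<protocol>"`, per the output naming
#' scheme. Unexpected extra files are ignored (reported via a message).
#'
#' @param expected data.frame with columns `structure` and `protocol`.
#' @param found character vector of file names or paths.
#' @return data.frame of failures (columns `structure`, `protocol`); zero
#'   rows when all outputs are present.
#' @export
detect_missing_outputs <- function(expected, found) {
  stopifnot(is.data.frame(expected),
            all(c("structure", "protocol") %in% names(expected)))
  stems <- sub("\\.[A-Za-z0-9]+$", "", basename(found))
  want <- paste0(expected$structure, "-", expected$protocol)
  matched_file <- rep(FALSE, length(stems))
  missing <- logical(nrow(expected))
  for (i in seq_len(nrow(expected))) {
    hit <- endsWith(stems, want[i])
    missing[i] <- !any(hit)
    matched_file <- matched_file | hit
  }
  if (any(!matched_file) && length(stems))
    message(sum(!matched_file), " file(s) not part of the benchmark plan; ",
            "ignored")
  expected[missing, c("structure", "protocol"), drop = FALSE]
}
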