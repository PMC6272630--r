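# All fixtures are built in code at test time.

co_molecule <- function() {
  molecule("co", c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
}

mol2_text <- function() {
  c("@<TRIPOS>MOLECULE", "toy", "3 0 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "1 C1   0.0000  0.0000  0.0000 C.3  1 LIG  0.1200",
    "2 N1   1.2345 -0.5000  2.0000 N.ar 1 LIG -0.3400",
    "3 O1  -1.0000  0.2500  0.7500 O.2  1 LIG -0.5100")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

sdf_text_3rec <- function() {
  m1 <- molecule("alpha", c("C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                 sd_tags = c(SCORE = "-7.2"))
  m2 <- molecule("beta", "N", rbind(c(0, 1, 2)))
  m3 <- molecule("gamma", c("C", "C", "S"),
                 rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1)),
                 sd_tags = c(SCORE = "-5.5", NOTE = "two\nlines"))
  list(mols = list(m1, m2, m3))
}

pdb_text <- function(resolution_line = "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.") {
  c("HEADER    TRANSFERASE                             01-JAN-10   1ABC",
    resolution_line,
    "HET    STU  A 400      28",
    "HET    HOH  A 501       1",
    "ATOM      1  N   MET A   1      11.104   6.134  -6.504  1.00  0.00")
}

# independent naive RMSD: explicit per-atom loop, no vectorisation
naive_rmsd <- function(a, b) {
  pa <- coords(a, heavy_only = TRUE)
  pb <- coords(b, heavy_only = TRUE)
  total <- 0
  for (i in seq_len(nrow(pa))) {
    total <- total + (pa[i, 1] - pb[i, 1])^2 +
      (pa[i, 2] - pb[i, 2])^2 + (pa[i, 3] - pb[i, 3])^2
  }
  sqrt(total / nrow(pa))
}

random_molecule <- function(n, seed) {
  withr::with_seed(seed, {
    el <- sample(c("C", "N", "O", "S", "H"), n, replace = TRUE,
                 prob = c(0.5, 0.15, 0.15, 0.05, 0.15))
    molecule(paste0("rnd", seed), el, matrix(runif(3 * n, -5, 5), ncol = 3))
  })
}

# small evaluated benchmark matrix from explicit per-cell RMSD targets
toy_matrix <- function(targets_by_cell, resolutions) {
  sids <- names(resolutions)
  protos <- names(targets_by_cell[[1]])
  cells <- list()
  for (sid in sids) {
    ref_mol <- make_reference_ligand(10, seed = match(sid, sids))
    ref <- reference_complex(sid, resolutions[[sid]], "lig", ref_mol)
    for (p in protos) {
      ps <- make_pose_set(ref_mol, targets_by_cell[[sid]][[p]],
                          seed = 100 + length(cells),
                          structure_id = sid, ligand_code = "lig",
                          protocol_abbrev = p)
      cells[[length(cells) + 1L]] <- evaluate_cell(ref, ps)
    }
  }
  benchmark_matrix(do.call(rbind, cells), structures = sids,
                   protocols = protos)
}
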