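test_that("mol2 reading infers elements from SYBYL types and keeps order", {
  f <- write_tmp(mol2_text(), ".mol2")
  m <- read_mol2(f)
  expect_s3_class(m, "molecule")
  expect_equal(m$atoms$element, c("C", "N", "O"))
  expect_equal(m$atoms$mass[2], 14.007)  # N.ar -> N, standard weight
  expect_true(all(m$atoms$is_heavy))
  expect_equal(m$atoms$x, c(0, 1.2345, -1))
  expect_equal(m$atoms$charge, c(0.12, -0.34, -0.51))
})

test_that("mol2 read-write-read round trip preserves geometry to 4 decimals", {
  f1 <- write_tmp(mol2_text(), ".mol2")
  m1 <- read_mol2(f1)
  f2 <- tempfile(fileext = ".mol2")
  write_mol2(m1, f2)
  m2 <- read_mol2(f2)
  expect_equal(m2$atoms$element, m1$atoms$element)
  expect_equal(coords(m2), coords(m1), tolerance = 1e-4)
  expect_equal(m2$atoms$charge, m1$atoms$charge, tolerance = 1e-4)
})

test_that("mol2 parse errors name the problem", {
  f <- write_tmp(c("@<TRIPOS>MOLECULE", "x", "1 0"), ".mol2")
  expect_error(read_mol2(f), "ATOM")
  f2 <- write_tmp(c("not a mol2 file"), ".mol2")
  expect_error(read_mol2(f2), "MOLECULE")
})

test_that("unknown element symbols are reported", {
  expect_error(molecule("x", "Xx", rbind(c(0, 0, 0))), "Xx")
})

test_that("SDF reading preserves record order, tags and handles empty files", {
  fx <- sdf_text_3rec()
  f <- tempfile(fileext = ".sdf")
  write_sdf(fx$mols, f)
  back <- read_sdf(f)
  expect_length(back, 3)
  expect_equal(vapply(back, `[[`, character(1), "name"),
               c("alpha", "beta", "gamma"))
  expect_equal(back[[1]]$sd_tags[["SCORE"]], "-7.2")
  expect_equal(back[[3]]$sd_tags[["NOTE"]], "two\nlines")
  # tag multiset survives the round trip
  expect_equal(sort(unlist(lapply(back, function(m) m$sd_tags))),
               sort(unlist(lapply(fx$mols, function(m) m$sd_tags))))
  # empty file is an empty list, not an error
  expect_identical(read_sdf(write_tmp(character(0), ".sdf")), list())
})

test_that("SDF round trip preserves atoms and coordinates to 4 decimals", {
  mols <- lapply(1:4, function(i) random_molecule(5 + i, seed = i))
  f <- tempfile(fileext = ".sdf")
  write_sdf(mols, f)
  back <- read_sdf(f)
  for (i in seq_along(mols)) {
    expect_equal(back[[i]]$atoms$element, mols[[i]]$atoms$element)
    expect_equal(coords(back[[i]]), coords(mols[[i]]), tolerance = 1e-4)
  }
})

test_that("single-record SDF ends in $$$$ and a 20-pose set gives 20 records", {
  txt <- write_sdf(molecule("solo", "C", rbind(c(0, 0, 0))))
  expect_match(txt, "\\$\\$\\$\\$\n$")
  ref <- make_reference_ligand(8, seed = 3)
  ps <- make_pose_set(ref, rep(1, 20), seed = 4)
  f <- tempfile(fileext = ".sdf")
  write_sdf(ps$poses, f)
  expect_length(read_sdf(f), 20)
})

test_that("malformed SDF records are rejected with the record index", {
  fx <- sdf_text_3rec()
  lines <- strsplit(write_sdf(fx$mols), "\n")[[1]]
  # drop one atom line from the second record to truncate it
  counts2 <- grep("V2000", lines)[2]
  expect_error(read_sdf(write_tmp(lines[-(counts2 + 1)], ".sdf")),
               "record 2")
  v3 <- c("name", "  prog", "",
          "  0  0  0  0  0  0  0  0  0  0999 V3000", "M  END", "$$$$")
  expect_error(read_sdf(write_tmp(v3, ".sdf")), "V3000")
})

test_that("PDB metadata extraction reads resolution and non-water HET codes", {
  md <- parse_pdb_metadata(write_tmp(pdb_text(), ".pdb"))
  expect_equal(md$resolution, 1.80)
  expect_equal(md$ligand_codes, "STU")  # HOH excluded
  expect_error(parse_pdb_metadata(write_tmp(pdb_text()[-2], ".pdb")),
               "manually")
  na <- pdb_text("REMARK   2 RESOLUTION. NOT APPLICABLE.")
  expect_error(parse_pdb_metadata(write_tmp(na, ".pdb")), "NOT APPLICABLE")
})

test_that("binding record selection follows the Ki > Kd > IC50 hierarchy", {
  ki <- binding_record("Ki", 12); kd <- binding_record("Kd", 3)
  ic <- binding_record("IC50", 40)
  expect_equal(select_binding_record(list(ic, kd, ki))$measure, "Ki")
  expect_equal(select_binding_record(list(ic, kd))$measure, "Kd")
  expect_equal(select_binding_record(list(ic))$measure, "IC50")
  expect_null(select_binding_record(list()))
  # invariant to input order
  recs <- list(ki, kd, ic, binding_record("Ki", 5))
  picked <- lapply(1:5, function(s)
    select_binding_record(withr::with_seed(s, sample(recs))))
  for (p in picked) expect_equal(p$value, 5)
})

test_that("resolution filtering is strict, order-preserving and idempotent", {
  lig <- co_molecule()
  cx <- lapply(c(a = 1.7, b = 1.8, c = 1.9), function(r)
    reference_complex("1ABC", r, "stu", lig))
  kept <- filter_by_resolution(cx, 1.8)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$resolution, 1.7)  # 1.8 itself excluded
  expect_length(filter_by_resolution(cx, 0.1), 0)
  expect_equal(filter_by_resolution(cx, Inf), cx)
  expect_equal(filter_by_resolution(kept, 1.8), kept)
})

test_that("output names follow the lig-PDB-protocol scheme and parse back", {
  expect_equal(format_output_name("07s", "3TKH", "GOLD-plp"),
               "07s-3TKH-GOLD-plp")
  expect_equal(format_output_name("STU", "1NVR", "VINA-std"),
               "stu-1NVR-VINA-std")
  expect_error(format_output_name("a/b", "1ABC", "VINA-std"), "separator")
  expect_error(format_output_name("", "1ABC", "VINA-std"), "non-empty")
  for (p in dock_protocols()$abbreviation) {
    parts <- parse_output_name(format_output_name("ym7", "2YM7", p))
    expect_equal(parts,
                 list(ligand_code = "ym7", pdb_id = "2YM7",
                      protocol_abbrev = p))
  }
})

test_that("missing docking outputs are detected as failures", {
  expected <- expand.grid(structure = c("1ABC", "2DEF"),
                          protocol = c("VINA-std", "GOLD-plp"),
                          stringsAsFactors = FALSE)
  found <- c("lig-1ABC-VINA-std.sdf", "lig-2DEF-VINA-std.sdf",
             "lig-1ABC-GOLD-plp.sdf")
  fails <- detect_missing_outputs(expected, found)
  expect_equal(nrow(fails), 1)
  expect_equal(fails$structure, "2DEF")
  expect_equal(fails$protocol, "GOLD-plp")
  expect_equal(nrow(detect_missing_outputs(expected, c(found,
               "lig-2DEF-GOLD-plp.sdf"))), 0)
  # extras are ignored (with a message), not errors
  expect_message(
    res <- detect_missing_outputs(expected,
                                  c(found, "lig-2DEF-GOLD-plp.sdf",
                                    "stray-file.sdf")),
    "ignored")
  expect_equal(nrow(res), 0)
})
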