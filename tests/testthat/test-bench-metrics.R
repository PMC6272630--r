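test_that("the protocol registry holds the 17 protocols, alphabetically", {
  reg <- dock_protocols()
  expect_equal(nrow(reg), 17)
  expect_equal(reg$abbreviation, sort(reg$abbreviation))
  expect_equal(reg$abbreviation[1], "AUTODOCK-ga")
  gs <- reg[reg$abbreviation == "GOLD-goldscore", ]
  expect_equal(gs$program, "GOLD 5.2")
  expect_equal(gs$search_algorithm, "Genetic Algorithm")
  expect_equal(gs$scoring_function, "Goldscore")
  expect_equal(sort(unique(protocol_program(
    reg$abbreviation[reg$licensed]))), c("GLIDE", "GOLD", "MOE"))
  expect_setequal(unique(protocol_program(
    reg$abbreviation[!reg$licensed])),
    c("AUTODOCK", "VINA", "PLANTS", "RDOCK"))
  expect_true(all(reg$score_direction %in%
                    c("lower_better", "higher_better")))
})

test_that("n_below_resolution counts strictly below R", {
  expect_equal(n_below_resolution(c(1.7, 1.8, 1.9), 1.8), 1)
  expect_equal(n_below_resolution(c(2, 3, 4), 1.8), 0)
  expect_error(n_below_resolution(c(1), -1), "positive")
  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(50, 0, 4))
    R <- withr::with_seed(seed + 50, runif(1, 0.5, 3))
    cnt <- 0
    for (x in v) if (x < R) cnt <- cnt + 1  # loop oracle
    expect_equal(n_below_resolution(v, R), cnt)
    # non-decreasing in R
    expect_gte(n_below_resolution(v, R + 0.5), n_below_resolution(v, R))
  }
})

test_that("protocol score enumerates to {0,1,1,1,2,2,2,3} over the rubric", {
  R <- 1.8
  combos <- expand.grid(min_ok = c(TRUE, FALSE), ave_ok = c(TRUE, FALSE),
                        frac_ok = c(TRUE, FALSE))
  scores <- apply(combos, 1, function(cm) {
    stats <- list(
      rmsd_min = if (cm[["min_ok"]]) 0.5 else 2.5,
      rmsd_ave = if (cm[["ave_ok"]]) 1.0 else 3.0,
      n_below_R = if (cm[["frac_ok"]]) 10L else 3L,
      n_poses = 20L)
    protocol_score(stats, R)
  })
  expect_equal(sort(scores), c(0, 1, 1, 1, 2, 2, 2, 3))
  expect_equal(max(scores), 3)
  expect_equal(min(scores), 0)
})

test_that("protocol score is monotone in each statistic", {
  R <- 1.8
  base <- list(rmsd_min = 1.9, rmsd_ave = 2.5, n_below_R = 5L, n_poses = 20L)
  s0 <- protocol_score(base, R)
  better_min <- modifyList(base, list(rmsd_min = 1.0))
  better_ave <- modifyList(base, list(rmsd_ave = 1.0))
  better_n <- modifyList(base, list(n_below_R = 15L))
  expect_gte(protocol_score(better_min, R), s0)
  expect_gte(protocol_score(better_ave, R), s0)
  expect_gte(protocol_score(better_n, R), s0)
  # rubric boundary: exactly half the poses satisfies the fraction criterion
  half <- list(rmsd_min = 3, rmsd_ave = 3, n_below_R = 10L, n_poses = 20L)
  expect_equal(protocol_score(half, R), 1)
  expect_equal(protocol_score(modifyList(half, list(n_below_R = 9L)), R), 0)
})

test_that("evaluate_cell derives the per-cell statistics", {
  ref_mol <- make_reference_ligand(12, seed = 11)
  ref <- reference_complex("S001", 1.8, "l01", ref_mol)
  ps <- make_pose_set(ref_mol, c(0.5, 1.0, 1.5), seed = 12,
                      structure_id = "S001", ligand_code = "l01",
                      protocol_abbrev = "VINA-std")
  cell <- evaluate_cell(ref, ps)
  expect_equal(cell$rmsd_min, 0.5, tolerance = 1e-9)
  expect_equal(cell$rmsd_max, 1.5, tolerance = 1e-9)
  expect_equal(cell$rmsd_ave, 1.0, tolerance = 1e-9)
  expect_equal(cell$n_below_R, 3L)
  expect_false(cell$failed)
  # 20 poses all below R gives the ceiling count
  ps20 <- make_pose_set(ref_mol, seq(0.2, 1.5, length.out = 20), seed = 13,
                        structure_id = "S001", protocol_abbrev = "VINA-std")
  expect_equal(evaluate_cell(ref, ps20)$n_below_R, 20L)
})

test_that("empty or non-corresponding pose sets yield failed cells", {
  ref_mol <- make_reference_ligand(12, seed = 11)
  ref <- reference_complex("S001", 1.8, "l01", ref_mol)
  empty <- pose_set("S001", "l01", "VINA-std", list())
  cell <- evaluate_cell(ref, empty)
  expect_true(cell$failed)
  expect_true(is.na(cell$rmsd_min) && is.na(cell$score))
  other <- make_reference_ligand(9, seed = 99)
  bad <- pose_set("S001", "l01", "VINA-std",
                  list(perturb_to_rmsd(other, 1, seed = 1)))
  cell2 <- evaluate_cell(ref, bad)
  expect_true(cell2$failed)
  expect_match(cell2$reason, "correspondence")
})

test_that("adding a pose can only widen the min/max envelope", {
  ref_mol <- make_reference_ligand(10, seed = 21)
  ref <- reference_complex("S001", 1.5, "l01", ref_mol)
  ps3 <- make_pose_set(ref_mol, c(1.2, 0.9, 2.0), seed = 22)
  ps4 <- pose_set(ps3$structure_id, ps3$ligand_code, ps3$protocol_abbrev,
                  c(ps3$poses, list(perturb_to_rmsd(ref_mol, 3, seed = 23))))
  c3 <- evaluate_cell(ref, ps3); c4 <- evaluate_cell(ref, ps4)
  expect_lte(c4$rmsd_min, c3$rmsd_min)
  expect_gte(c4$rmsd_max, c3$rmsd_max)
})

test_that("the benchmark grid is complete and sized |structures| x |protocols|", {
  res <- c(S001 = 1.5, S002 = 1.2)
  targets <- list(
    S001 = list(`AUTODOCK-ga` = c(0.5, 0.7), `VINA-std` = c(2.5, 3.0)),
    S002 = list(`AUTODOCK-ga` = c(0.4, 0.6), `VINA-std` = c(1.0, 1.1)))
  m <- toy_matrix(targets, res)
  expect_equal(nrow(m), 4)
  expect_s3_class(m, "benchmark_matrix")
  # dropping a cell is an error
  expect_error(benchmark_matrix(m[-1, ], structures = names(res),
                                protocols = c("AUTODOCK-ga", "VINA-std")),
               "incomplete")
  # duplicating one too
  expect_error(benchmark_matrix(rbind(m, m[1, ])), "duplicate")
})

test_that("protocol and protein ranks sort by score sums with alphabetical ties", {
  res <- c(S001 = 1.8, S002 = 1.8)
  targets <- list(
    S001 = list(A = c(0.5, 0.6), B = c(2.5, 2.6)),   # A scores 3, B 0
    S002 = list(A = c(0.5, 0.6), B = c(0.5, 3.5, 3.6, 3.7)))  # A 3, B 1
  m <- toy_matrix(targets, res)
  rp <- rank_protocols(m)
  expect_equal(rp$name, c("A", "B"))
  expect_equal(rp$score_sum, c(6, 1))
  rs <- rank_proteins(m)
  expect_equal(rs$name[1], "S002")  # 4 > 3
  # grand-total conservation
  expect_equal(sum(rp$score_sum), sum(rs$score_sum))
  # alphabetical tie-break
  tied <- toy_matrix(list(
    S001 = list(B = c(0.5, 0.6), A = c(0.5, 0.6))), c(S001 = 1.8))
  expect_equal(rank_protocols(tied)$name, c("A", "B"))
})

test_that("failed cells contribute zero to rank sums", {
  res <- c(S001 = 1.8)
  targets <- list(S001 = list(A = c(0.5, 0.6), B = c(0.5, 0.6)))
  m <- toy_matrix(targets, res)
  ref <- reference_complex("S001", 1.8, "lig",
                           make_reference_ligand(10, seed = 1))
  failed_cell <- evaluate_cell(ref, pose_set("S001", "lig", "B", list()))
  cells <- rbind(m[m$protocol_abbrev == "A", ], failed_cell)
  m2 <- benchmark_matrix(cells, structures = "S001",
                         protocols = c("A", "B"))
  rp <- rank_protocols(m2)
  expect_equal(rp$score_sum[rp$name == "B"], 0)
})

test_that("summary files round trip the matrix exactly", {
  res <- c(S001 = 1.5, S002 = 1.2)
  targets <- list(
    S001 = list(`AUTODOCK-ga` = c(0.5, 0.7, 1.3), `VINA-std` = c(2.5, 3.0)),
    S002 = list(`AUTODOCK-ga` = c(0.4, 0.6), `VINA-std` = c(1.0, 1.1)))
  m <- toy_matrix(targets, res)
  # plant one failure
  ref <- reference_complex("S003", 1.1, "lig",
                           make_reference_ligand(10, seed = 5))
  extra <- rbind(
    evaluate_cell(ref, make_pose_set(ref$ligand, c(0.5, 0.9), seed = 6,
                                     structure_id = "S003",
                                     protocol_abbrev = "AUTODOCK-ga")),
    evaluate_cell(ref, pose_set("S003", "lig", "VINA-std", list())))
  m <- benchmark_matrix(rbind(as.data.frame(m), extra),
                        structures = c("S001", "S002", "S003"),
                        protocols = c("AUTODOCK-ga", "VINA-std"))
  f <- tempfile(fileext = ".tsv")
  write_summary(m, f)
  lines <- readLines(f)
  expect_length(lines, nrow(m) + 1)  # header + one line per cell
  failed_line <- grep("TRUE", lines, value = TRUE)
  expect_length(failed_line, 1)
  expect_false(grepl("[0-9]\\.[0-9]", failed_line))  # no statistics
  back <- read_summary(f)
  expect_equal(back$rmsd_min, m$rmsd_min)
  expect_equal(back$rmsd_ave, m$rmsd_ave)
  expect_equal(back$n_below_R, m$n_below_R)
  expect_equal(back$score, m$score)
  expect_equal(back$failed, m$failed)
})
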