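test_that("variant tables parse, drop synonymous rows, and keep last duplicates", {
  path <- write_lines_tmp(c(
    "protein\tvariant\tscore",
    "P000\tA1V\t0.9",
    "P000\tA1G\t0.5",
    "P000\tA1A\t0.3",
    "P000\tA1G\t0.6"
  ))
  expect_message(
    expect_warning(tab <- read_variant_table(path), "duplicate"),
    "synonymous"
  )
  expect_equal(nrow(tab), 2)
  expect_equal(tab$score[tab$alt_aa == "G"], 0.6)  # last wins
  expect_equal(score_protein_id(tab), "P000")
  expect_equal(score_orientation(tab), "pathogenic_high")
})

test_that("malformed variant rows are rejected with their location", {
  bad_var <- write_lines_tmp(c("protein\tvariant\tscore", "P0\tA1\t0.5"))
  expect_error(read_variant_table(bad_var), "row 1")
  bad_score <- write_lines_tmp(c("protein\tvariant\tscore", "P0\tA1V\t1.5"))
  expect_error(read_variant_table(bad_score), "\\[0, 1\\]")
})

test_that("matrix tables keep the 19 non-synonymous cells per row", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  header <- paste(c("pos", "ref", aa), collapse = "\t")
  row1 <- paste(c("1", "A", rep("0.05", 20)), collapse = "\t")
  tab <- read_matrix_table(write_lines_tmp(c(header, row1)),
                           orientation = "pathogenic_low")
  expect_equal(nrow(tab), 19)
  expect_false("A" %in% tab$alt_aa)
  expect_true(all(tab$score == 0.05))
  expect_equal(score_orientation(tab), "pathogenic_low")

  # an empty cell drops that substitution ("all available" rule)
  row2 <- paste(c("2", "C", rep("0.10", 10), "", rep("0.10", 9)),
                collapse = "\t")
  tab2 <- read_matrix_table(write_lines_tmp(c(header, row1, row2)))
  expect_equal(sum(tab2$position == 2), 18)

  bad <- paste(c("3", "X", rep("0.10", 20)), collapse = "\t")
  expect_error(read_matrix_table(write_lines_tmp(c(header, bad))), "header")
})

test_that("matrix entry counts equal 19 per position minus blanked cells", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(5)
  n_pos <- 50
  refs <- sample(aa, n_pos, replace = TRUE)
  blanks <- 0
  rows <- vapply(seq_len(n_pos), function(i) {
    vals <- sprintf("%.3f", runif(20, 0, 1))
    drop <- sample(20, sample(0:3, 1))
    # blanks on the self cell do not reduce the count
    blanks <<- blanks + sum(aa[drop] != refs[i])
    vals[drop] <- ""
    paste(c(i, refs[i], vals), collapse = "\t")
  }, character(1))
  header <- paste(c("pos", "ref", aa), collapse = "\t")
  tab <- read_matrix_table(write_lines_tmp(c(header, rows)))
  expect_equal(nrow(tab), 19 * n_pos - blanks)
})

test_that("score tables round-trip through every writer dialect", {
  spec <- cohort_spec(n_proteins = 1, n_residues = 40, n_rings = 1, seed = 4)
  st <- make_structure(spec, 1)$structure
  tab <- make_scores(spec, st, 1)
  for (dialect in c("variant", "matrix", "transcript")) {
    path <- tempfile(fileext = ".tsv")
    write_score_table(tab, path, dialect = dialect)
    back <- switch(dialect,
                   variant = read_variant_table(path),
                   matrix = read_matrix_table(path,
                                              orientation = "pathogenic_high"),
                   transcript = read_transcript_table(path))
    a <- dplyr::arrange(tibble::as_tibble(tab), position, alt_aa)
    b <- dplyr::arrange(tibble::as_tibble(back), position, alt_aa)
    expect_equal(a$score, b$score, tolerance = 1e-9)
    expect_equal(a$ref_aa, b$ref_aa)
    expect_equal(a$alt_aa, b$alt_aa)
  }
})

test_that("per-residue means follow the availability rule", {
  path <- write_lines_tmp(c(
    "protein\tvariant\tscore",
    "TOY\tA1V\t0.2", "TOY\tA1G\t0.4", "TOY\tA1L\t0.6",
    "TOY\tF3W\t0.8"
  ))
  tab <- read_variant_table(path)
  st <- read_structure(system.file("extdata", "toy_agf_hem.pdb",
                                   package = "tunnelgrad"))
  rm_ <- residue_means(tab, st)
  expect_equal(rm_$mean_score[rm_$resno == 1], 0.4)
  expect_equal(rm_$n_substitutions[rm_$resno == 1], 3L)
  # position 2 has no entries: missing marker, zero substitutions
  expect_true(is.na(rm_$mean_score[rm_$resno == 2]))
  expect_equal(rm_$n_substitutions[rm_$resno == 2], 0L)
})

test_that("reference mismatches are reported but not dropped", {
  path <- write_lines_tmp(c(
    "protein\tvariant\tscore",
    "TOY\tG1V\t0.2"  # structure position 1 is A, table says G
  ))
  tab <- read_variant_table(path)
  st <- read_structure(system.file("extdata", "toy_agf_hem.pdb",
                                   package = "tunnelgrad"))
  expect_message(rm_ <- residue_means(tab, st), "disagrees")
  expect_equal(rm_$mean_score[rm_$resno == 1], 0.2)
  mism <- attr(rm_, "mismatches")
  expect_equal(nrow(mism), 1)
  expect_equal(mism$table_aa, "G")
})

test_that("synthetic residue means equal the planted values to machine precision", {
  spec <- cohort_spec(n_proteins = 1, n_residues = 60, n_rings = 2, seed = 8)
  st <- make_structure(spec, 1)$structure
  tab <- make_scores(spec, st, 1)
  rm_ <- residue_means(tab, st)
  planted <- attr(tab, "planted")
  expect_equal(rm_$mean_score, planted$planted_mean, tolerance = 1e-12)
  expect_true(all(rm_$n_substitutions == 19))
})
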