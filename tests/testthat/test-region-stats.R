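mk_means <- function(scores) {
  tibble::tibble(chain = "A", resno = seq_along(scores), ins = "",
                 aa = rep(c("L", "F", "R", "G"), length.out = length(scores)),
                 mean_score = scores,
                 n_substitutions = ifelse(is.na(scores), 0L, 19L))
}

mk_set <- function(region, resno, aa = NULL) {
  tibble::tibble(region = region, chain = "A", resno = resno, ins = "",
                 aa = aa %||% rep(c("L", "F", "R", "G"),
                                  length.out = max(resno, 1))[resno],
                 dist = NA_real_, source = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("region summaries average the right residues", {
  rm_ <- mk_means(c(0.1, 0.2, 0.3, 0.4))
  sets <- dplyr::bind_rows(mk_set("protein", 1:4), mk_set("tunnel", 3:4))
  s <- region_summaries(rm_, sets, protein_id = "P1")
  expect_equal(s$mean_score[s$region == "protein"], 0.25)
  expect_equal(s$mean_score[s$region == "tunnel"], 0.35)
  # subset recomputation: a cofactor set nested in the tunnel set
  sets2 <- dplyr::bind_rows(sets, mk_set("cofactor", 4))
  s2 <- region_summaries(rm_, sets2, protein_id = "P1")
  expect_equal(s2$mean_score[s2$region == "cofactor"],
               mean(rm_$mean_score[4]))
})

test_that("missing scores are counted and excluded from the mean", {
  rm_ <- mk_means(c(0.2, NA, 0.6, NA))
  sets <- mk_set("protein", 1:4)
  s <- region_summaries(rm_, sets, protein_id = "P1")
  expect_equal(s$mean_score, 0.4)
  expect_equal(s$n_missing, 2L)
  # fully missing region: NA mean, all counted missing
  s0 <- region_summaries(mk_means(c(NA, NA)), mk_set("protein", 1:2), "P1")
  expect_true(is.na(s0$mean_score))
  expect_equal(s0$n_missing, s0$n_residues)
})

test_that("amino-acid frequency profiles count and normalise", {
  set <- mk_set("tunnel", 1:4, aa = c("L", "L", "F", "R"))
  prof <- aa_frequency_profile(set)
  expect_equal(prof$percent[prof$aa == "L"], 50)
  expect_equal(prof$percent[prof$aa == "F"], 25)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
  expect_equal(nrow(prof), 20)
  expect_error(aa_frequency_profile(mk_set("tunnel", integer(0))), "empty")
})

test_that("frequency profile of a synthetic bundle matches its composition", {
  spec <- cohort_spec(n_proteins = 1, n_residues = 150, n_rings = 2, seed = 2)
  st <- make_structure(spec, 1)$structure
  prof <- aa_frequency_profile(protein_set(st))
  want <- table(factor(st$residues$aa, levels = sort(unique(prof$aa))))
  expect_equal(prof$n[match(names(want), prof$aa)], as.integer(want))
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
})

test_that("per-amino-acid group means match a brute-force group-by", {
  rm_ <- mk_means(runif(40))
  sets <- dplyr::bind_rows(mk_set("protein", 1:40), mk_set("tunnel", 5:12),
                           mk_set("cofactor", 9:11))
  got <- per_aa_group_means(rm_, sets)
  joined <- merge(sets, rm_[, c("resno", "mean_score")], by = "resno")
  for (i in seq_len(nrow(got))) {
    sub <- joined$mean_score[joined$region == got$region[i] &
                               joined$aa == got$aa[i]]
    if (length(sub) == 0) {
      expect_true(is.na(got$mean_score[i]))
    } else {
      expect_equal(got$mean_score[i], mean(sub))
    }
  }
  # absent combination: tryptophan never occurs in these sets
  expect_true(all(is.na(got$mean_score[got$aa == "W"])))
})

test_that("score histograms conserve counts and close the last bin", {
  rm_ <- mk_means(c(0, 0.05, 0.1, 0.95, 1.0))
  sets <- mk_set("protein", 1:5)
  h <- score_frequency_heatmap(rm_, sets, bins = 10)
  expect_equal(sum(h$n), 5)               # conservation
  expect_true(any(h$bin == 10 & h$n > 0)) # mean of exactly 1 in last bin
  expect_true(all(h$bin >= 1 & h$bin <= 10))
  # exhaustive recount on random data
  rm2 <- mk_means(runif(200))
  sets2 <- dplyr::bind_rows(mk_set("protein", 1:200), mk_set("tunnel", 1:50))
  h2 <- score_frequency_heatmap(rm2, sets2, bins = 10)
  for (reg in c("protein", "tunnel")) {
    n_reg <- sum(h2$n[h2$region == reg])
    expect_equal(n_reg, sum(sets2$region == reg))
  }
  breaks <- seq(0, 1, 0.1)
  recount <- table(findInterval(rm2$mean_score[1:50], breaks,
                                rightmost.closed = TRUE))
  got <- h2[h2$region == "tunnel", ] |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = sum(n))
  expect_equal(got$n[match(as.integer(names(recount)), got$bin)],
               as.integer(recount))
})

adh_summaries <- function(mat) {
  # mat: proteins x 3 (protein, tunnel, cofactor)
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    tibble::tibble(protein_id = sprintf("P%02d", i), region = REGIONS3,
                   mean_score = mat[i, ], n_residues = 10L, n_missing = 0L)
  })
}
REGIONS3 <- c("protein", "tunnel", "cofactor")

test_that("adherence counts strict monotone units with orientation handling", {
  one <- adh_summaries(matrix(c(0.3, 0.5, 0.7), 1))
  a <- adherence(one, orientation = "pathogenic_high")
  expect_equal(a$rate, 100)
  a_low <- adherence(one, orientation = "pathogenic_low")
  expect_equal(a_low$rate, 0)

  # planted: 9 of 10 proteins monotone increasing, one inverted
  mat <- rbind(matrix(rep(c(0.2, 0.4, 0.6), 9), ncol = 3, byrow = TRUE),
               c(0.6, 0.4, 0.2))
  a9 <- adherence(adh_summaries(mat), orientation = "pathogenic_high")
  expect_equal(a9$n_total, 10)
  expect_equal(a9$n_adhering, 9)
  expect_equal(a9$rate, 90)

  # a protein with a missing region mean is excluded from the denominator
  s <- adh_summaries(mat)
  s$mean_score[s$protein_id == "P01" & s$region == "tunnel"] <- NA
  a_mis <- adherence(s, orientation = "pathogenic_high")
  expect_equal(a_mis$n_total, 9)
  expect_equal(a_mis$n_excluded, 1)
})

test_that("adherence is exactly invariant under score inversion", {
  set.seed(77)
  mat <- matrix(runif(60), ncol = 3)
  s_high <- adh_summaries(mat)
  s_low <- adh_summaries(1 - mat)
  a1 <- adherence(s_high, orientation = "pathogenic_high")
  a2 <- adherence(s_low, orientation = "pathogenic_low")
  expect_identical(a1$n_adhering, a2$n_adhering)
  expect_identical(a1$rate, a2$rate)
  expect_identical(tidy(a1)$adheres, tidy(a2)$adheres)
})

test_that("adherence chance rate under exchangeable region means is about 1/6", {
  set.seed(123)
  n <- 4000
  mat <- matrix(runif(3 * n), ncol = 3)  # iid means: all orderings equally likely
  a <- adherence(adh_summaries(mat), orientation = "pathogenic_high")
  expect_equal(a$rate / 100, 1 / 6, tolerance = 0.12)
})

test_that("per-amino-acid adherence counts amino-acid types as units", {
  gm <- tidyr::expand_grid(region = REGIONS3, aa = c("L", "F", "W"))
  gm$mean_score <- c(0.2, 0.2, 0.6, 0.4, 0.5, 0.4, 0.6, 0.7, NA)
  # L: 0.2 < 0.4 < 0.6 adheres; F: 0.2 < 0.5 < 0.7 adheres; W: missing
  a <- adherence(gm, orientation = "pathogenic_high", level = "per_aa")
  expect_equal(a$n_total, 2)
  expect_equal(a$n_adhering, 2)
  expect_equal(a$n_excluded, 1)
})

test_that("paired t statistics follow the closed form and star tiers", {
  s <- adh_summaries(rbind(c(0.1, 1.1, 0), c(0.1, 2.1, 0), c(0.1, 3.1, 0)))
  res <- paired_tests(s, comparisons = list(c("protein", "tunnel")))
  expect_equal(res$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  # degenerate: all differences zero
  s0 <- adh_summaries(rbind(c(0.2, 0.2, 0.4), c(0.5, 0.5, 0.6)))
  r0 <- paired_tests(s0, comparisons = list(c("protein", "tunnel")))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$stars, "ns")

  expect_error(paired_tests(adh_summaries(matrix(c(0.1, 0.2, 0.3), 1))),
               "fewer than 2")

  expect_equal(tunnelgrad:::assign_stars(c(0.04, 0.004, 0.0004, 0.2)),
               c("**", "***", "****", "ns"))
})

test_that("paired p-values match the reference implementation", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    a <- runif(n); b <- runif(n)
    s <- purrr::map_dfr(seq_len(n), function(j) {
      tibble::tibble(protein_id = sprintf("P%03d", j),
                     region = c("protein", "tunnel"),
                     mean_score = c(a[j], b[j]),
                     n_residues = 5L, n_missing = 0L)
    })
    got <- paired_tests(s, comparisons = list(c("protein", "tunnel")))
    want <- t.test(b, a, paired = TRUE)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-10)
    expect_equal(got$t_statistic, unname(want$statistic), tolerance = 1e-10)
  }
})
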