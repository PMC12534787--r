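test_that("synthetic structures are deterministic and geometrically sound", {
  spec <- cohort_spec(n_proteins = 2, n_residues = 120, seed = 5)
  gen <- make_structure(spec, 1)
  st <- gen$structure
  expect_equal(nrow(st$residues), 120)

  # cofactor centroid buried: at least 6 A from every protein atom
  cen <- cofactor_centroid(st)
  pa <- protein_atoms(st)
  dmin <- min(sqrt((pa$x - cen[1])^2 + (pa$y - cen[2])^2 + (pa$z - cen[3])^2))
  expect_gte(dmin, 6)

  # channel axis points clear all protein atoms by at least the true radius
  for (ch in gen$channels) {
    for (i in seq_len(nrow(ch$nodes))) {
      d <- sqrt((pa$x - ch$nodes[i, 1])^2 + (pa$y - ch$nodes[i, 2])^2 +
                  (pa$z - ch$nodes[i, 3])^2)
      expect_gte(min(d), ch$radius - 1e-9)
    }
    expect_gte(ch$radius, spec$channel_radius)
  }

  # byte-identical PDB for the same (seed, index)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_structure(st, p1)
  write_structure(make_structure(spec, 1)$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different index gives a different sequence
  expect_false(make_structure(spec, 2)$structure$sequence == st$sequence)
})

test_that("planted score model hits its degenerate cases exactly", {
  base <- 0.4
  spec0 <- cohort_spec(n_proteins = 1, n_residues = 60, n_rings = 1,
                       gradient = 0, noise_sd = 0, base_score = base, seed = 3)
  st <- make_structure(spec0, 1)$structure
  rm0 <- residue_means(make_scores(spec0, st, 1), st)
  expect_equal(rm0$mean_score, rep(base, 60), tolerance = 1e-12)

  # g = 0.3, sigma = 0: mean = b + 0.3 * exp(-d / lambda) exactly
  specg <- cohort_spec(n_proteins = 1, n_residues = 60, n_rings = 1,
                       gradient = 0.3, noise_sd = 0, base_score = base,
                       decay_length = 8, seed = 3)
  tab <- make_scores(specg, st, 1)
  d <- residue_point_distances(st, cofactor_centroid(st))$dist
  rmg <- residue_means(tab, st)
  expect_equal(rmg$mean_score, base + 0.3 * exp(-d / 8), tolerance = 1e-12)

  # inverse orientation emits 1 - s
  specl <- cohort_spec(n_proteins = 1, n_residues = 60, n_rings = 1,
                       gradient = 0.3, noise_sd = 0, base_score = base,
                       orientation = "pathogenic_low", seed = 3)
  rml <- residue_means(make_scores(specl, st, 1), st)
  expect_equal(rml$mean_score, 1 - rmg$mean_score, tolerance = 1e-12)
})

test_that("planted channels round-trip through the MOLE-style JSON", {
  spec <- cohort_spec(n_proteins = 1, n_residues = 100, seed = 6)
  gen <- make_structure(spec, 1)
  path <- tempfile(fileext = ".json")
  make_mole_json(gen$channels, path)
  tun <- read_mole_tunnels(path)
  expect_equal(length(unique(tun$tunnel_id)), length(gen$channels))
  t1 <- tun[tun$tunnel_id == 1, ]
  expect_equal(cbind(t1$x, t1$y, t1$z), gen$channels[[1]]$nodes,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(min(t1$radius), min(gen$channels[[1]]$radii))
  # empty channel list parses to an empty collection
  p0 <- tempfile(fileext = ".json")
  make_mole_json(list(), p0)
  expect_equal(nrow(read_mole_tunnels(p0)), 0)
})

test_that("cohort-level region contrast matches the analytic expectation", {
  spec <- cohort_spec(n_proteins = 30, n_residues = 120, n_rings = 2, seed = 9)
  diffs <- vapply(seq_len(spec$n_proteins), function(i) {
    gen <- make_structure(spec, i)
    st <- gen$structure
    rm_ <- residue_means(make_scores(spec, st, i), st)
    sets <- dplyr::bind_rows(protein_set(st), cofactor_proximal_set(st))
    s <- region_summaries(rm_, sets, protein_id = st$id)
    s$mean_score[s$region == "cofactor"] - s$mean_score[s$region == "protein"]
  }, numeric(1))
  # analytic expectation from the generator's own geometry (identical across
  # proteins: only residue identities and noise vary with the index)
  gen <- make_structure(spec, 1)
  st <- gen$structure
  d <- residue_point_distances(st, cofactor_centroid(st))
  cset <- cofactor_proximal_set(st)
  e_all <- mean(spec$gradient * exp(-d$dist / spec$decay_length))
  in_c <- paste(d$chain, d$resno) %in% paste(cset$chain, cset$resno)
  e_cof <- mean(spec$gradient * exp(-d$dist[in_c] / spec$decay_length))
  expected <- e_cof - e_all
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * se + 1e-6)
})

test_that("materialised cohorts are consumable through the manifest", {
  spec <- cohort_spec(n_proteins = 2, n_residues = 60, n_rings = 1, seed = 11)
  dir <- file.path(tempdir(), "cohort-test")
  cfg <- make_cohort(spec, dir, dialect = "matrix")
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_length(cfg$proteins, 2)
  expect_true(all(file.exists(vapply(cfg$proteins, `[[`, "", "structure"))))
  cfg2 <- read_run_config(file.path(dir, "manifest.yaml"))
  expect_equal(cfg2$dialect, "matrix")
  expect_length(cfg2$proteins, 2)
  unlink(dir, recursive = TRUE)
})
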