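#' Specification of a synthetic validation cohort
#'
#' Describes a cohort of toy structures with a buried pseudo-cofactor, a
#' planted exit channel, and substitution score tables carrying a planted
#' monotone pathogenicity gradient toward the cofactor. The per-residue
#' planted mean is `base_score + gradient * exp(-d / decay_length)` plus
#' Gaussian noise, where `d` is the residue's minimum atom distance to the
#' cofactor centroid; for `orientation = "pathogenic_low"` all scores are
#' inverted as `1 - s`.
#'
#' @param n_proteins Number of proteins in the cohort.
#' @param n_residues Protein residues per structure (after channel carving).
#' @param n_helices Helices in the innermost ring of the bundle; outer rings
#'   hold proportionally more.
#' @param n_rings Concentric helix rings (default 3, giving a bundle roughly
#'   60 A across, the size class of a mid-sized globular enzyme, so that
#'   most residues sit far from the buried cofactor).
#' @param cofactor_atoms Atoms in the pseudo-cofactor group.
#' @param gradient Gradient amplitude g, score units in \[0, 1\].
#' @param decay_length Spatial decay length lambda, Angstrom.
#' @param noise_sd Residue-level Gaussian noise SD sigma, score units.
#' @param base_score Baseline score b far from the cofactor.
#' @param sub_jitter_sd SD of the (exactly mean-zero) per-substitution
#'   jitter around each residue's planted value.
#' @param channel_radius Planted channel clearance, Angstrom.
#' @param n_channels 1 (default) or 2 planted channels (the second exits on
#'   the opposite face, exercising multi-tunnel unions).
#' @param orientation Scale orientation of the emitted score tables.
#' @param composition Named amino-acid sampling weights (defaults to an
#'   average globular composition).
#' @param seed Integer master seed; every generated artefact is a pure
#'   function of `(seed, index)`.
#' @return A validated `tg_cohort_spec` list.
#' @export
cohort_spec <- function(n_proteins = 30, n_residues = 240, n_helices = 6,
                        n_rings = 4, cofactor_atoms = 8, gradient = 0.2,
                        decay_length = 8, noise_sd = 0.05, base_score = 0.35,
                        sub_jitter_sd = 0.03, channel_radius = 2,
                        n_channels = 2, orientation = "pathogenic_high",
                        composition = AA_BACKGROUND, seed = 1) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  stopifnot(
    n_proteins >= 1, n_residues >= 20, n_helices >= 3, n_rings >= 1,
    cofactor_atoms >= 1,
    gradient >= 0, gradient <= 1, decay_length > 0, noise_sd >= 0,
    base_score >= 0, base_score <= 1, sub_jitter_sd >= 0, channel_radius > 0,
    n_channels %in% 1:2
  )
  if (!all(AA_CODES %in% names(composition))) {
    stop("`composition` must name all 20 standard amino acids", call. = FALSE)
  }
  structure(
    list(n_proteins = n_proteins, n_residues = n_residues,
         n_helices = n_helices, n_rings = n_rings,
         cofactor_atoms = cofactor_atoms,
         gradient = gradient, decay_length = decay_length,
         noise_sd = noise_sd, base_score = base_score,
         sub_jitter_sd = sub_jitter_sd, channel_radius = channel_radius,
         n_channels = n_channels, orientation = orientation,
         composition = composition[AA_CODES], seed = as.integer(seed)),
    class = "tg_cohort_spec"
  )
}

# ideal-helix constants: 1.5 A rise and 100 degrees of turn per residue,
# backbone radius 2.3 A; two pseudo side-chain atoms extend radially
HELIX_RISE <- 1.5
HELIX_TURN <- 100 * pi / 180
HELIX_RADIUS <- 2.3
SIDECHAIN_RADII <- c(3.3, 4.3)
CAVITY_CLEARANCE <- 6.2
RING_GAP <- 7          # radial spacing between helix rings, A
CORRIDOR_HALF_DEG <- 20  # half-angle of the thin-wall exit corridor
SURFACE_CLEARANCE <- 5   # tunnel ends where axis clearance reaches this, A

#' Generate one synthetic structure with a planted channel
#'
#' Builds an idealised alpha-helix bundle (Calpha plus two dummy side-chain
#' atoms per residue) arranged around a central cavity, places a
#' pseudo-cofactor (HET code `HEM`) at the cavity center, and carves one or
#' two straight channels from the cavity to the surface by omitting every
#' residue with an atom closer than `channel_radius` to the channel axis.
#' Helix ends farthest from the cavity midplane are trimmed so exactly
#' `n_residues` remain, renumbered 1..n. Deterministic given
#' `(spec$seed, index)`.
#'
#' @param spec A [cohort_spec()].
#' @param index Protein index within the cohort (1-based).
#' @return A list:
#'   \describe{
#'     \item{structure}{the `tg_structure` (id `"SYN<index>"`)}
#'     \item{channels}{list of planted channels, each with `axis` (unit
#'       direction), `nodes` (matrix of axis points, 1 A apart), `radii`
#'       (true clearance at each node, A) and `radius` (the channel
#'       bottleneck, i.e. minimum clearance)}
#'   }
#' @export
make_structure <- function(spec, index = 1) {
  stopifnot(inherits(spec, "tg_cohort_spec"))
  n_res <- spec$n_residues
  r1 <- CAVITY_CLEARANCE + max(SIDECHAIN_RADII)
  ring_r <- r1 + RING_GAP * (seq_len(spec$n_rings) - 1)
  # helices per ring scale with circumference; helix length scales with ring
  # radius, so shell mass grows roughly quadratically with radius, as in a
  # globular protein around a buried active site
  ring_n <- pmax(spec$n_helices, round(spec$n_helices * ring_r / r1))

  # channel directions: +x (and -x for the two-channel mode); helix angles
  # are offset by half a sector so the corridors pass between helices
  dirs <- list(c(1, 0, 0), c(-1, 0, 0))[seq_len(spec$n_channels)]
  dir_angles <- c(0, pi)[seq_len(spec$n_channels)]

  # outer rings (3+) leave a thin-wall corridor around each channel
  # direction, so the tunnel meets the surface shortly after the core rings
  keep_helix <- function(ring, phi) {
    if (ring_r[ring] <= r1 + 1.5 * RING_GAP) return(TRUE)
    ang <- vapply(dir_angles, function(a) {
      d <- abs(((phi - a + pi) %% (2 * pi)) - pi)
      d
    }, numeric(1))
    all(ang >= CORRIDOR_HALF_DEG * pi / 180)
  }

  buffer <- max(16, ceiling(0.1 * n_res))
  capacity <- function(q) {
    per <- pmax(2, ceiling(q * ring_r / r1))
    tot <- 0
    for (ring in seq_len(spec$n_rings)) {
      nh <- sum(vapply(seq_len(ring_n[ring]), function(h) {
        keep_helix(ring, 2 * pi * (h - 0.5) / ring_n[ring])
      }, logical(1)))
      tot <- tot + nh * per[ring]
    }
    tot
  }
  q <- 2
  while (capacity(q) < n_res + buffer && q < 200) q <- q + 1
  per_ring <- pmax(2, ceiling(q * ring_r / r1))

  res_list <- list()
  ridx <- 0
  hel <- 0
  for (ring in seq_len(spec$n_rings)) {
    per_helix <- per_ring[ring]
    height <- HELIX_RISE * (per_helix - 1)
    for (h in seq_len(ring_n[ring])) {
      phi <- 2 * pi * (h - 0.5) / ring_n[ring]
      if (!keep_helix(ring, phi)) next
      hel <- hel + 1
      ax <- ring_r[ring] * c(cos(phi), sin(phi))
      for (i in seq_len(per_helix)) {
        ridx <- ridx + 1
        theta <- HELIX_TURN * (i - 1) + phi
        zc <- HELIX_RISE * (i - 1) - height / 2
        u <- c(cos(theta), sin(theta))
        ca <- c(ax + HELIX_RADIUS * u, zc)
        sc1 <- c(ax + SIDECHAIN_RADII[1] * u, zc)
        sc2 <- c(ax + SIDECHAIN_RADII[2] * u, zc)
        res_list[[ridx]] <- list(helix = hel, idx = i, z = zc,
                                 rel_z = if (height > 0) abs(zc) / (height / 2) else 0,
                                 xyz = rbind(ca, sc1, sc2))
      }
    }
  }

  ray_clear <- function(xyz, dir) {
    # distance from atoms to the half-line {t * dir : t >= 0}
    t_par <- xyz %*% dir
    perp2 <- rowSums(xyz^2) - pmax(t_par, 0)^2
    sqrt(pmax(perp2, 0))
  }
  blocked <- vapply(res_list, function(r) {
    any(vapply(dirs, function(d) any(ray_clear(r$xyz, d) < spec$channel_radius),
               logical(1)))
  }, logical(1))
  keep <- res_list[!blocked]
  if (length(keep) < n_res) {
    stop("channel carving removed too many residues; increase n_helices or ",
         "reduce channel_radius", call. = FALSE)
  }
  # trim helix ends down to n_res, by relative height so every ring sheds
  # proportionally; deterministic tie-break
  ord <- order(vapply(keep, function(r) r$rel_z, numeric(1)),
               vapply(keep, function(r) r$helix, numeric(1)),
               vapply(keep, function(r) r$idx, numeric(1)))
  keep <- keep[sort(ord[seq_len(n_res)])]

  # pseudo-cofactor: a flat ring of atoms around the cavity center, wide the
  # way a porphyrin is wide, so different cofactor atoms face different
  # patches of the cavity wall
  k <- spec$cofactor_atoms
  cof_r <- if (k == 1) 0 else min(1.1 * sqrt(k), CAVITY_CLEARANCE - 2.5)
  ang <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
  cof <- cbind(cof_r * cos(ang), cof_r * sin(ang), 0)
  min_protein <- min(vapply(keep, function(r) min(sqrt(rowSums(r$xyz^2))),
                            numeric(1)))
  if (min_protein < cof_r + 2) {
    stop("cavity too small for a cofactor of ", k, " atoms", call. = FALSE)
  }

  aa <- with_local_seed(spec$seed + 7919L * index, {
    sample(AA_CODES, n_res, replace = TRUE,
           prob = spec$composition / sum(spec$composition))
  })

  n_at <- 3L * n_res
  atoms <- tibble::tibble(
    serial = seq_len(n_at + k),
    name = c(rep(c("CA", "CB", "CG"), n_res), sprintf("C%d", seq_len(k))),
    element = c(rep("C", n_at), rep("C", k)),
    chain = "A",
    resno = c(rep(seq_len(n_res), each = 3), rep(n_res + 1L, k)),
    ins = "",
    aa = c(rep(aa, each = 3), rep(NA_character_, k)),
    x = unname(c(unlist(lapply(keep, function(r) r$xyz[, 1])), cof[, 1])),
    y = unname(c(unlist(lapply(keep, function(r) r$xyz[, 2])), cof[, 2])),
    z = unname(c(unlist(lapply(keep, function(r) r$xyz[, 3])), cof[, 3])),
    is_cofactor = c(rep(FALSE, n_at), rep(TRUE, k))
  )
  residues <- tibble::tibble(chain = "A", resno = seq_len(n_res), ins = "",
                             aa = aa)
  st <- new_structure(id = sprintf("SYN%03d", index), atoms = atoms,
                      residues = residues)
  attr(st, "cofactor_resid") <- "HEM"

  pm <- atom_matrix(protein_atoms(st))
  max_ext <- max(sqrt(rowSums(pm^2)))
  channels <- lapply(dirs, function(d) {
    tt <- seq(1.5, max_ext + 4, by = 1)
    nodes <- outer(tt, d)
    radii <- vapply(seq_along(tt), function(i) {
      min(sqrt(rowSums(sweep(pm, 2, nodes[i, ])^2)))
    }, numeric(1))
    # the tunnel ends at the molecular surface: cut at the first point past
    # the core where the axis clearance reaches bulk-solvent size
    cut <- which(tt > r1 & radii >= SURFACE_CLEARANCE)
    if (length(cut)) {
      nodes <- nodes[seq_len(cut[1]), , drop = FALSE]
      radii <- radii[seq_len(cut[1])]
      tt <- tt[seq_len(cut[1])]
    }
    list(axis = d, nodes = nodes, radii = radii, radius = min(radii))
  })
  list(structure = st, channels = channels)
}

#' Generate a planted score table for a synthetic structure
#'
#' Per residue, the planted mean is
#' `clip(base_score + gradient * exp(-d / decay_length) + N(0, noise_sd))`
#' with `d` the residue's minimum atom distance to the cofactor centroid.
#' The 19 non-synonymous substitutions at each position are jittered around
#' the residue value with an exactly mean-zero perturbation (rescaled if
#' needed to stay inside \[0, 1\]), so each residue's mean over its
#' substitutions equals its planted value to machine precision. For
#' `orientation = "pathogenic_low"` every score is emitted as `1 - s`.
#'
#' @param spec A [cohort_spec()].
#' @param structure The matching `tg_structure` from [make_structure()].
#' @param index Protein index (decorrelates the noise stream from other
#'   proteins of the cohort).
#' @param center Cofactor centroid (default: computed from the structure).
#' @return A `tg_scores` table (19 entries per position). The planted
#'   per-residue means, after orientation, are attached as
#'   `attr(x, "planted")` (tibble `resno`, `dist`, `planted_mean`).
#' @export
make_scores <- function(spec, structure, index = 1,
                        center = cofactor_centroid(structure)) {
  stopifnot(inherits(spec, "tg_cohort_spec"),
            inherits(structure, "tg_structure"))
  res <- structure$residues
  d <- residue_point_distances(structure, center)$dist
  n <- nrow(res)

  out <- with_local_seed(spec$seed + 104729L * index + 13L, {
    planted <- spec$base_score +
      spec$gradient * exp(-d / spec$decay_length) +
      stats::rnorm(n, 0, spec$noise_sd)
    planted <- pmin(pmax(planted, 0), 1)
    jit <- matrix(stats::rnorm(19L * n, 0, spec$sub_jitter_sd), nrow = n)
    list(planted = planted, jit = jit)
  })
  planted <- out$planted
  jit <- out$jit - rowMeans(out$jit)
  # shrink jitter where needed so all 19 values stay inside [0, 1] without
  # moving the mean
  hi <- jit[, 1]; lo <- jit[, 1]
  for (j in 2:ncol(jit)) {
    hi <- pmax(hi, jit[, j]); lo <- pmin(lo, jit[, j])
  }
  fac <- pmin(1,
              ifelse(hi > 0, (1 - planted) / hi, 1),
              ifelse(lo < 0, -planted / lo, 1))
  scores <- planted + jit * fac

  entries <- tibble::tibble(
    position = rep(res$resno, each = 19),
    ref_aa = rep(res$aa, each = 19),
    alt_aa = as.vector(ALT_TABLE[, res$aa]),
    score = as.vector(t(scores))
  )
  if (spec$orientation == "pathogenic_low") {
    entries$score <- 1 - entries$score
    planted <- 1 - planted
  }
  tab <- new_score_table(entries, protein_id = structure$id,
                         orientation = spec$orientation)
  attr(tab, "planted") <- tibble::tibble(resno = res$resno, dist = d,
                                         planted_mean = planted)
  tab
}

#' Emit planted channels as a MOLE-style JSON document
#'
#' Writes the planted channel axes as tunnel centerline profiles (nodes 1 A
#' apart, radii equal to the true clearance from the axis to the protein
#' atoms), in the JSON layout consumed by [read_mole_tunnels()].
#'
#' @param channels The `channels` element returned by [make_structure()]
#'   (may be an empty list).
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) when written, else the JSON string.
#' @export
make_mole_json <- function(channels, path = NULL) {
  doc <- list(Tunnels = purrr::imap(channels, function(ch, i) {
    list(
      Id = i,
      Profile = purrr::map(seq_len(nrow(ch$nodes)), function(j) {
        list(X = ch$nodes[j, 1], Y = ch$nodes[j, 2], Z = ch$nodes[j, 3],
             FreeRadius = ch$radii[j])
      })
    )
  }))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Generate a slab fixture with planted cylindrical channels
#'
#' A rectangular lattice block of pseudo-atoms with a spherical central
#' cavity holding a pseudo-cofactor, and optional straight channels of known
#' clearance from the cavity to a face: the primary channel along +z and an
#' optional second channel along +x. Used to validate the grid tunnel
#' finder against known geometry.
#'
#' @param radius Primary channel clearance (A); `NULL` for a closed block.
#' @param second_radius Optional second channel clearance (A).
#' @param half_xy,half_z Block half-extents (A).
#' @param lattice Atom lattice spacing (A).
#' @param cavity_radius Central cavity radius (A).
#' @return A list with `structure` (a `tg_structure`) and the channel
#'   radii.
#' @export
make_channel_slab <- function(radius = 2, second_radius = NULL,
                              half_xy = 10, half_z = 6, lattice = 0.8,
                              cavity_radius = 4) {
  g <- seq(-half_xy, half_xy, by = lattice)
  gz <- seq(-half_z, half_z, by = lattice)
  pts <- as.matrix(expand.grid(x = g, y = g, z = gz))
  keep <- sqrt(rowSums(pts^2)) >= cavity_radius
  if (!is.null(radius)) {
    keep <- keep & !(pts[, 3] >= 0 & sqrt(pts[, 1]^2 + pts[, 2]^2) < radius)
  }
  if (!is.null(second_radius)) {
    keep <- keep &
      !(pts[, 1] >= 0 & sqrt(pts[, 2]^2 + pts[, 3]^2) < second_radius)
  }
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  cof <- cbind(c(0.8, -0.8, 0, 0), c(0, 0, 0.8, -0.8), c(0, 0, 0, 0))
  atoms <- tibble::tibble(
    serial = seq_len(n + 4L),
    name = c(rep("CA", n), sprintf("C%d", 1:4)),
    element = "C",
    chain = "A",
    resno = c(seq_len(n), rep(n + 1L, 4)),
    ins = "",
    aa = c(rep("G", n), rep(NA_character_, 4)),
    x = c(pts[, 1], cof[, 1]), y = c(pts[, 2], cof[, 2]),
    z = c(pts[, 3], cof[, 3]),
    is_cofactor = c(rep(FALSE, n), rep(TRUE, 4))
  )
  residues <- tibble::tibble(chain = "A", resno = seq_len(n), ins = "",
                             aa = "G")
  st <- new_structure("SLAB", atoms, residues)
  attr(st, "cofactor_resid") <- "HEM"
  list(structure = st, radius = radius, second_radius = second_radius)
}

#' Materialise a synthetic cohort on disk
#'
#' Writes, for each protein of the cohort, a PDB structure, a MOLE-style
#' tunnel JSON for the planted channels, and a score table in the chosen
#' dialect, plus a YAML manifest; the directory is directly consumable by
#' [run_pipeline()].
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param dialect Score-table dialect to write.
#' @return A [run_config()] pointing at the written files.
#' @export
make_cohort <- function(spec, dir, dialect = c("variant", "matrix",
                                               "transcript")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spec, "tg_cohort_spec"))
  for (d in c("structures", "tunnels", "scores")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  ext <- if (dialect == "matrix") "matrix.tsv" else paste0(dialect, ".tsv")
  proteins <- purrr::map(seq_len(spec$n_proteins), function(i) {
    gen <- make_structure(spec, i)
    id <- gen$structure$id
    pdb <- file.path(dir, "structures", paste0(id, ".pdb"))
    jsn <- file.path(dir, "tunnels", paste0(id, ".json"))
    tsv <- file.path(dir, "scores", paste0(id, ".", ext))
    write_structure(gen$structure, pdb)
    make_mole_json(gen$channels, jsn)
    write_score_table(make_scores(spec, gen$structure, i), tsv,
                      dialect = dialect)
    list(id = id, structure = pdb, tunnels = jsn, scores = tsv)
  })
  cfg <- run_config(
    proteins = proteins, dialect = dialect, orientation = spec$orientation,
    cofactor_code = "HEM", seed = spec$seed
  )
  yaml::write_yaml(unclass(cfg), file.path(dir, "manifest.yaml"))
  cfg
}
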