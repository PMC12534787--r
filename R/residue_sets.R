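#' Resample a tunnel centerline at regular arc-length spacing
#'
#' Places sample points at arc-length multiples of `spacing` from the
#' tunnel's first (cofactor-side) point, by linear interpolation between
#' profile points. The first and last centerline points are always included.
#' `spacing = 0` returns the native profile nodes unchanged.
#'
#' @param tunnel Centerline tibble rows of a single tunnel (columns `x`,
#'   `y`, `z`, `arc_length`).
#' @param spacing Sample spacing in Angstrom (default 0.5).
#' @return A numeric matrix of sample points, one row per point, columns
#'   x, y, z.
#' @export
sample_centerline <- function(tunnel, spacing = 0.5) {
  stopifnot(nrow(tunnel) >= 2, spacing >= 0)
  xyz <- cbind(tunnel$x, tunnel$y, tunnel$z)
  if (spacing == 0) return(xyz)
  s <- tunnel$arc_length
  total <- s[length(s)]
  at <- seq(0, total, by = spacing)
  if (total - at[length(at)] > 1e-9) at <- c(at, total)
  out <- matrix(NA_real_, nrow = length(at), ncol = 3)
  for (d in 1:3) {
    out[, d] <- stats::approx(s, xyz[, d], xout = at, ties = "ordered")$y
  }
  out
}

# for each query point (rows of `pts`), the n_atoms nearest protein atoms,
# ties broken by (distance, serial); returns one tibble row per recruited
# (point, residue) pair after per-point residue deduplication
nearest_atom_residues <- function(pts, atoms, n_atoms, source_label) {
  n_take <- min(n_atoms, nrow(atoms))
  if (n_take < n_atoms) {
    message("structure has only ", nrow(atoms), " protein atoms; using all")
  }
  am <- atom_matrix(atoms)
  ord_serial <- order(atoms$serial)
  purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    d <- sqrt((am[, 1] - pts[i, 1])^2 + (am[, 2] - pts[i, 2])^2 +
                (am[, 3] - pts[i, 3])^2)
    # stable tie-break: distance, then atom serial
    o <- order(d, atoms$serial)[seq_len(n_take)]
    tibble::tibble(
      source = source_label[i],
      chain = atoms$chain[o], resno = atoms$resno[o], ins = atoms$ins[o],
      aa = atoms$aa[o], dist = d[o]
    ) %>%
      dplyr::group_by(.data$source, .data$chain, .data$resno, .data$ins,
                      .data$aa) %>%
      dplyr::summarise(dist = min(.data$dist), .groups = "drop")
  })
}

# collapse recruited (source, residue) pairs to the non-redundant union,
# keeping the closest recruiting source per residue as provenance
dedupe_members <- function(recruited, region) {
  out <- recruited %>%
    dplyr::arrange(.data$dist, .data$source) %>%
    dplyr::distinct(.data$chain, .data$resno, .data$ins, .data$aa,
                    .keep_all = TRUE) %>%
    dplyr::arrange(.data$chain, .data$resno, .data$ins) %>%
    dplyr::mutate(region = region) %>%
    dplyr::select("region", "chain", "resno", "ins", "aa", "dist", "source")
  per_source <- recruited %>% dplyr::count(.data$source, name = "n_residues")
  attr(out, "per_source") <- per_source
  out
}

#' Tunnel-lining residue set
#'
#' Samples every tunnel centerline at regular points and assigns, to each
#' sample point, the `n_atoms` closest protein heavy atoms; these map to
#' between 1 and `n_atoms` parent residues per point. The returned set is the
#' deduplicated union over all points of all tunnels. Provenance (which
#' sample point recruited each residue, and at what distance) is kept, with
#' the per-point residue counts available as `attr(x, "per_source")`.
#'
#' @param structure A `tg_structure`.
#' @param tunnels Centerline tibble ([read_mole_tunnels()]/[find_tunnels()]).
#' @param spacing Centerline sample spacing, A (0 = native profile nodes).
#' @param n_atoms Number of closest atoms per sample point (default 5).
#' @return A residue-set tibble: `region` (`"tunnel"`), `chain`, `resno`,
#'   `ins`, `aa`, `dist` (closest recruiting distance, A), `source`
#'   (recruiting sample point label). Empty tunnel input gives a zero-row
#'   set.
#' @export
tunnel_lining_set <- function(structure, tunnels, spacing = 0.5, n_atoms = 5) {
  stopifnot(inherits(structure, "tg_structure"), n_atoms >= 1)
  if (is.null(tunnels) || nrow(tunnels) == 0) {
    return(dedupe_members(
      tibble::tibble(source = character(), chain = character(),
                     resno = integer(), ins = character(), aa = character(),
                     dist = double()),
      region = "tunnel"
    ))
  }
  pa <- protein_atoms(structure)
  recruited <- tunnels %>%
    dplyr::group_split(.data$tunnel_id) %>%
    purrr::map_dfr(function(tun) {
      pts <- sample_centerline(tun, spacing)
      labels <- sprintf("t%d.p%d", tun$tunnel_id[1], seq_len(nrow(pts)))
      nearest_atom_residues(pts, pa, n_atoms, labels)
    })
  dedupe_members(recruited, region = "tunnel")
}

#' Cofactor-proximal residue set
#'
#' For each cofactor atom, finds the `n_atoms` closest protein heavy atoms
#' and maps them to their parent residues; the set is the non-redundant
#' union over all cofactor atoms, with the closest recruiting cofactor atom
#' kept as provenance.
#'
#' @inheritParams tunnel_lining_set
#' @param n_atoms Number of closest protein atoms per cofactor atom
#'   (default 5).
#' @return A residue-set tibble with `region = "cofactor"` (columns as in
#'   [tunnel_lining_set()]).
#' @export
cofactor_proximal_set <- function(structure, n_atoms = 5) {
  stopifnot(inherits(structure, "tg_structure"), n_atoms >= 1)
  ca <- cofactor_atoms(structure)
  if (nrow(ca) == 0) stop("structure has no cofactor atoms", call. = FALSE)
  pts <- atom_matrix(ca)
  labels <- sprintf("cof.%d", ca$serial)
  recruited <- nearest_atom_residues(pts, protein_atoms(structure), n_atoms,
                                     labels)
  dedupe_members(recruited, region = "cofactor")
}

#' Whole-protein residue set
#'
#' The baseline region: every protein residue. With
#' `complement = TRUE` the tunnel and cofactor members passed in `exclude`
#' are removed instead (off by default; the standard analysis compares the
#' tunnel and cofactor regions against the entire protein).
#'
#' @param structure A `tg_structure`.
#' @param complement If `TRUE`, drop the residues listed in `exclude`.
#' @param exclude Residue-set tibble(s) to subtract when `complement = TRUE`.
#' @return A residue-set tibble with `region = "protein"`.
#' @export
protein_set <- function(structure, complement = FALSE, exclude = NULL) {
  stopifnot(inherits(structure, "tg_structure"))
  out <- structure$residues %>%
    dplyr::mutate(region = "protein", dist = NA_real_,
                  source = NA_character_) %>%
    dplyr::select("region", "chain", "resno", "ins", "aa", "dist", "source")
  if (complement && !is.null(exclude) && nrow(exclude) > 0) {
    out <- dplyr::anti_join(out, exclude, by = c("chain", "resno", "ins"))
  }
  out
}

#' All three residue sets of a structure
#'
#' Convenience wrapper binding the whole-protein, tunnel-lining and
#' cofactor-proximal sets into one tibble keyed by `region`.
#'
#' @inheritParams tunnel_lining_set
#' @return A residue-set tibble with regions `protein`, `tunnel`,
#'   `cofactor`.
#' @export
residue_sets <- function(structure, tunnels, spacing = 0.5, n_atoms = 5) {
  dplyr::bind_rows(
    protein_set(structure),
    tunnel_lining_set(structure, tunnels, spacing = spacing,
                      n_atoms = n_atoms),
    cofactor_proximal_set(structure, n_atoms = n_atoms)
  )
}
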