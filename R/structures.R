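#' Read a protein structure with a single cofactor group from a PDB file
#'
#' Parses a PDB file, keeps heavy atoms only, and partitions them into
#' protein atoms (standard amino-acid residues) and cofactor atoms (all atoms
#' of residues whose HET code equals `cofactor_code`). Waters and any other
#' HET groups are discarded. Only the first model of a multi-model file is
#' read; alternate locations are resolved by highest occupancy, then first
#' listed.
#'
#' @param path Path to a PDB file.
#' @param cofactor_code Three-character HET code of the cofactor group
#'   (default `"HEM"`, the iron-porphyrin cofactor of cytochromes P450).
#' @param id Protein identifier recorded on the returned object; defaults to
#'   the file name without extension.
#'
#' @return A `tg_structure`: a list with
#'   \describe{
#'     \item{id}{protein identifier}
#'     \item{atoms}{tibble of heavy atoms: `serial`, `name`, `element`,
#'       `chain`, `resno`, `ins`, `aa` (one-letter code, `NA` for the
#'       cofactor), `x`, `y`, `z`, `is_cofactor`}
#'     \item{residues}{tibble of protein residues in author order:
#'       `chain`, `resno`, `ins`, `aa`}
#'     \item{sequence}{one-letter sequence string of the protein residues}
#'   }
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy_agf_hem.pdb", package = "tunnelgrad")
#' s <- read_structure(pdb)
#' s$sequence
read_structure <- function(path, cofactor_code = "HEM", id = NULL) {
  stopifnot(is.character(path), length(path) == 1)
  if (!nzchar(cofactor_code) || nchar(cofactor_code) > 3) {
    stop("`cofactor_code` must be a 1-3 character HET code", call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("cannot parse PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) stop("cannot parse PDB file '", path, "': no atoms", call. = FALSE)

  at$ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  # heavy atoms only (hydrogen/deuterium excluded everywhere downstream)
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]
  # alternate locations: highest occupancy wins, ties to the first listed
  at$o[is.na(at$o)] <- 1
  at <- at %>%
    dplyr::mutate(.row = dplyr::row_number()) %>%
    dplyr::arrange(.data$chain, .data$resno, .data$ins, .data$elety,
                   dplyr::desc(.data$o), .data$.row) %>%
    dplyr::distinct(.data$chain, .data$resno, .data$ins, .data$elety,
                    .keep_all = TRUE) %>%
    dplyr::arrange(.data$.row)

  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  is_protein <- at$type == "ATOM" & aa1 %in% AA_CODES
  is_cof <- at$resid == toupper(cofactor_code)

  if (!any(is_cof)) {
    stop("no residue with cofactor code '", cofactor_code, "' in '", path, "'",
         call. = FALSE)
  }
  if (!any(is_protein)) {
    stop("no protein residues in '", path, "'", call. = FALSE)
  }

  sel <- is_protein | is_cof
  atoms <- tibble::tibble(
    serial = at$eleno[sel],
    name = at$elety[sel],
    element = toupper(at$elesy[sel]),
    chain = at$chain[sel],
    resno = as.integer(at$resno[sel]),
    ins = at$ins[sel],
    aa = ifelse(is_protein[sel], aa1[sel], NA_character_),
    x = at$x[sel], y = at$y[sel], z = at$z[sel],
    is_cofactor = is_cof[sel]
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("cannot parse PDB file '", path, "': non-finite coordinates", call. = FALSE)
  }

  residues <- atoms %>%
    dplyr::filter(!.data$is_cofactor) %>%
    dplyr::distinct(.data$chain, .data$resno, .data$ins, .data$aa)

  new_structure(
    id = id %||% sub("\\.[^.]*$", "", basename(path)),
    atoms = atoms,
    residues = residues
  )
}

new_structure <- function(id, atoms, residues) {
  structure(
    list(
      id = id,
      atoms = atoms,
      residues = residues,
      sequence = paste(residues$aa, collapse = "")
    ),
    class = "tg_structure"
  )
}

#' @export
print.tg_structure <- function(x, ...) {
  cat("<tg_structure> ", x$id, "\n", sep = "")
  cat("  protein residues: ", nrow(x$residues),
      "  protein atoms: ", sum(!x$atoms$is_cofactor),
      "  cofactor atoms: ", sum(x$atoms$is_cofactor), "\n", sep = "")
  invisible(x)
}

#' Protein and cofactor atom accessors
#'
#' @param structure A `tg_structure`.
#' @return A tibble of atoms (the protein or the cofactor partition).
#' @export
protein_atoms <- function(structure) {
  stopifnot(inherits(structure, "tg_structure"))
  dplyr::filter(structure$atoms, !.data$is_cofactor)
}

#' @rdname protein_atoms
#' @export
cofactor_atoms <- function(structure) {
  stopifnot(inherits(structure, "tg_structure"))
  dplyr::filter(structure$atoms, .data$is_cofactor)
}

#' Centroid of the cofactor group
#'
#' @param structure A `tg_structure`.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
cofactor_centroid <- function(structure) {
  ca <- cofactor_atoms(structure)
  if (nrow(ca) == 0) stop("structure has no cofactor atoms", call. = FALSE)
  c(mean(ca$x), mean(ca$y), mean(ca$z))
}

#' Write a structure back to PDB
#'
#' Writes protein atoms as ATOM records and cofactor atoms as HETATM records,
#' in the stored order. Used by the synthetic-cohort generator and for
#' round-trip checks.
#'
#' @param structure A `tg_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "tg_structure"))
  a <- structure$atoms
  resid3 <- rep("HEM", nrow(a))
  resid3[!is.na(a$aa)] <- bio3d::aa123(a$aa[!is.na(a$aa)])
  # synthetic cofactors keep their authored residue name if recorded
  if (!is.null(attr(structure, "cofactor_resid"))) {
    resid3[a$is_cofactor] <- attr(structure, "cofactor_resid")
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = ifelse(a$is_cofactor, "HETATM", "ATOM"),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = resid3, eleno = a$serial, elety = a$name,
    chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Minimum atom distance from each residue to a point
#'
#' For every protein residue, the minimum Euclidean distance from any of its
#' heavy atoms to `point`. Used for planting score gradients relative to the
#' cofactor and for diagnostics.
#'
#' @param structure A `tg_structure`.
#' @param point Numeric length-3 vector (x, y, z), Angstrom.
#' @return Tibble `chain`, `resno`, `ins`, `aa`, `dist` (Angstrom), one row
#'   per protein residue in author order.
#' @export
residue_point_distances <- function(structure, point) {
  stopifnot(inherits(structure, "tg_structure"), length(point) == 3,
            all(is.finite(point)))
  pa <- protein_atoms(structure)
  if (nrow(pa) == 0) stop("structure has no protein atoms", call. = FALSE)
  d <- sqrt((pa$x - point[1])^2 + (pa$y - point[2])^2 + (pa$z - point[3])^2)
  res <- structure$residues
  gi <- match(paste(pa$chain, pa$resno, pa$ins),
              paste(res$chain, res$resno, res$ins))
  o <- order(gi, d)
  first <- !duplicated(gi[o])
  dist <- rep(NA_real_, nrow(res))
  dist[gi[o][first]] <- d[o][first]
  dplyr::mutate(res, dist = dist)
}

# protein atom coordinates as a plain matrix (n x 3)
atom_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}
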