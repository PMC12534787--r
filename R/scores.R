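# 19 non-synonymous substitute amino acids per reference, one column per ref
ALT_TABLE <- vapply(AA_CODES, function(a) setdiff(AA_CODES, a), character(19))

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

new_score_table <- function(entries, protein_id, orientation) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  entries <- tibble::as_tibble(entries)[, c("position", "ref_aa", "alt_aa",
                                            "score")]
  if (any(entries$score < 0 | entries$score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(entries$ref_aa == entries$alt_aa)) {
    stop("synonymous entries (ref == alt) are not allowed", call. = FALSE)
  }
  attr(entries, "protein_id") <- protein_id
  attr(entries, "orientation") <- orientation
  class(entries) <- c("tg_scores", class(entries))
  entries
}

#' Scale orientation and protein id of a score table
#'
#' Pathogenicity predictors disagree on scale direction: for most tools a
#' high score means pathogenic (`"pathogenic_high"`); SIFT-style tools are
#' inverse (`"pathogenic_low"`, low score = pathogenic). The orientation is
#' carried as metadata and scores are never transformed; direction handling
#' happens only in [adherence()] and interpretation of region means.
#'
#' @param table A `tg_scores` table.
#' @return The orientation string / protein id recorded on the table.
#' @export
score_orientation <- function(table) {
  attr(table, "orientation") %||% "pathogenic_high"
}

#' @rdname score_orientation
#' @export
score_protein_id <- function(table) {
  attr(table, "protein_id") %||% NA_character_
}

parse_variants <- function(variant) {
  m <- stringr::str_match(toupper(variant), "^([A-Z])(\\d+)([A-Z])$")
  tibble::tibble(ref_aa = m[, 2], position = suppressWarnings(as.integer(m[, 3])),
                 alt_aa = m[, 4])
}

pick_column <- function(nms, patterns, fallback) {
  for (p in patterns) {
    hit <- which(grepl(p, nms, ignore.case = TRUE))
    if (length(hit)) return(hit[1])
  }
  fallback
}

#' Read a long-form variant score table
#'
#' Reads delimited text (TSV or CSV by extension) with one row per
#' substitution: a protein identifier, a variant string such as `A123V`, and
#' a score in \[0, 1\]. Column names are matched loosely (`protein`/`uniprot`/
#' `id`, `variant`/`mutation`, `score`/`pathogenicity`), falling back to the
#' first three columns. Synonymous rows (ref equals alt) are dropped with a
#' message; duplicate `(position, ref, alt)` rows keep the last occurrence
#' with a warning.
#'
#' @param path Path to the delimited file.
#' @param orientation Scale orientation, `"pathogenic_high"` (default) or
#'   `"pathogenic_low"` for inverse-scaled tools.
#' @return A `tg_scores` table: tibble `position`, `ref_aa`, `alt_aa`,
#'   `score`, with the protein id and orientation as attributes.
#' @export
read_variant_table <- function(path, orientation = "pathogenic_high") {
  raw <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                           progress = FALSE)
  nms <- names(raw)
  ip <- pick_column(nms, c("^(protein|uniprot|accession)", "\\bid\\b"), 1L)
  iv <- pick_column(nms, c("variant", "mutation", "substitution"), 2L)
  is <- pick_column(nms, c("score", "pathogenic"), 3L)
  protein_id <- as.character(raw[[ip]][1])
  variant <- as.character(raw[[iv]])
  score <- suppressWarnings(as.numeric(raw[[is]]))

  parsed <- parse_variants(variant)
  bad <- which(is.na(parsed$ref_aa) | is.na(parsed$position))
  if (length(bad)) {
    stop("unparseable variant string '", variant[bad[1]], "' at data row ",
         bad[1], " of '", path, "'", call. = FALSE)
  }
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad)) {
    stop("score outside [0, 1] at data row ", bad[1], " of '", path, "'",
         call. = FALSE)
  }
  entries <- dplyr::bind_cols(parsed, tibble::tibble(score = score))
  syn <- entries$ref_aa == entries$alt_aa
  if (any(syn)) {
    message(sum(syn), " synonymous row(s) dropped from '", path, "'")
    entries <- entries[!syn, , drop = FALSE]
  }
  dup <- duplicated(entries[, c("position", "ref_aa", "alt_aa")],
                    fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate substitution row(s) in '", path,
            "'; keeping the last", call. = FALSE)
    entries <- entries[!dup, , drop = FALSE]
  }
  new_score_table(entries, protein_id, orientation)
}

#' Read a position-by-substitution score matrix
#'
#' Reads the matrix dialect used by SIFT-like tools: one row per sequence
#' position with the reference amino acid, and one column per substitute
#' amino acid (20 one-letter columns). The 19 non-synonymous cells of each
#' row become entries; the self-substitution cell is ignored and empty cells
#' are skipped (the "all available substitutions" rule).
#'
#' @inheritParams read_variant_table
#' @param protein_id Identifier recorded on the table (default: file name).
#' @return A `tg_scores` table.
#' @export
read_matrix_table <- function(path, orientation = "pathogenic_low",
                              protein_id = NULL) {
  raw <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                           progress = FALSE)
  nms <- names(raw)
  aa_cols <- nms[toupper(nms) %in% AA_CODES & nchar(nms) == 1]
  if (length(aa_cols) < 19) {
    stop("matrix table '", path, "' must have one-letter amino-acid columns",
         call. = FALSE)
  }
  ipos <- pick_column(nms, c("^pos", "position"), 1L)
  iref <- pick_column(nms, c("^ref", "^aa$", "wild"), 2L)
  position <- as.integer(raw[[ipos]])
  ref_aa <- toupper(as.character(raw[[iref]]))
  bad <- which(!(ref_aa %in% toupper(aa_cols)))
  if (length(bad)) {
    stop("reference amino acid '", ref_aa[bad[1]], "' at data row ", bad[1],
         " of '", path, "' is absent from the column header", call. = FALSE)
  }
  entries <- raw[, aa_cols] %>%
    dplyr::mutate(position = position, ref_aa = ref_aa) %>%
    tidyr::pivot_longer(dplyr::all_of(aa_cols), names_to = "alt_aa",
                        values_to = "score") %>%
    dplyr::mutate(alt_aa = toupper(.data$alt_aa),
                  score = suppressWarnings(as.numeric(.data$score))) %>%
    dplyr::filter(.data$alt_aa != .data$ref_aa, !is.na(.data$score))
  if (any(entries$score < 0 | entries$score > 1)) {
    stop("score outside [0, 1] in '", path, "'", call. = FALSE)
  }
  new_score_table(entries, protein_id %||% sub("\\.[^.]*$", "", basename(path)),
                  orientation)
}

#' Read a transcript-variant score table
#'
#' Reads the transcript dialect: separate columns for a transcript
#' identifier, protein position, reference and alternate amino acids, and a
#' score. Apart from the identifier living in its own column and the variant
#' being pre-split, handling matches [read_variant_table()].
#'
#' @inheritParams read_variant_table
#' @return A `tg_scores` table; the transcript id is stored as the protein
#'   id.
#' @export
read_transcript_table <- function(path, orientation = "pathogenic_high") {
  raw <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                           progress = FALSE)
  nms <- names(raw)
  it <- pick_column(nms, c("transcript", "enst"), 1L)
  ipos <- pick_column(nms, c("^pos", "position"), 2L)
  iref <- pick_column(nms, c("^ref"), 3L)
  ialt <- pick_column(nms, c("^alt"), 4L)
  is <- pick_column(nms, c("score", "pathogenic"), 5L)
  entries <- tibble::tibble(
    position = as.integer(raw[[ipos]]),
    ref_aa = toupper(as.character(raw[[iref]])),
    alt_aa = toupper(as.character(raw[[ialt]])),
    score = suppressWarnings(as.numeric(raw[[is]]))
  )
  bad <- which(is.na(entries$score) | entries$score < 0 | entries$score > 1)
  if (length(bad)) {
    stop("score outside [0, 1] at data row ", bad[1], " of '", path, "'",
         call. = FALSE)
  }
  syn <- entries$ref_aa == entries$alt_aa
  if (any(syn)) {
    message(sum(syn), " synonymous row(s) dropped from '", path, "'")
    entries <- entries[!syn, , drop = FALSE]
  }
  dup <- duplicated(entries[, c("position", "ref_aa", "alt_aa")],
                    fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate substitution row(s) in '", path,
            "'; keeping the last", call. = FALSE)
    entries <- entries[!dup, , drop = FALSE]
  }
  new_score_table(entries, as.character(raw[[it]][1]), orientation)
}

#' Write a score table in a chosen dialect
#'
#' Inverse of the three readers; used by the synthetic-cohort generator and
#' for round-trip tests. The `variant` dialect writes protein id, variant
#' string and score; `matrix` writes one row per position with 20 amino-acid
#' columns (self cell empty); `transcript` writes id, position, ref, alt,
#' score.
#'
#' @param table A `tg_scores` table.
#' @param path Output path (TSV or CSV by extension).
#' @param dialect One of `"variant"`, `"matrix"`, `"transcript"`.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path,
                              dialect = c("variant", "matrix", "transcript")) {
  dialect <- match.arg(dialect)
  pid <- score_protein_id(table)
  df <- tibble::as_tibble(table)
  out <- switch(
    dialect,
    variant = tibble::tibble(
      protein_id = pid,
      variant = paste0(df$ref_aa, df$position, df$alt_aa),
      score = df$score
    ),
    matrix = df %>%
      tidyr::pivot_wider(id_cols = c("position", "ref_aa"),
                         names_from = "alt_aa", values_from = "score") %>%
      dplyr::arrange(.data$position) %>%
      dplyr::select("position", ref_aa = "ref_aa",
                    dplyr::any_of(AA_CODES)),
    transcript = tibble::tibble(
      transcript_id = pid, position = df$position,
      ref_aa = df$ref_aa, alt_aa = df$alt_aa, score = df$score
    )
  )
  if (delim_for(path) == ",") readr::write_csv(out, path, progress = FALSE)
  else readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-residue mean pathogenicity
#'
#' Aggregates a substitution-level score table to residue level: for every
#' protein residue of the structure, the arithmetic mean over all available
#' non-synonymous substitution scores at its sequence position. Residues
#' with no entries get `NA` means (`n_substitutions = 0`) and are excluded
#' from downstream region means. Positions where the table's reference
#' amino acid disagrees with the structure's residue are collected in a
#' mismatch report (`attr(x, "mismatches")`) but are still aggregated.
#'
#' @param table A `tg_scores` table.
#' @param structure A `tg_structure`; positions in `table` refer to its
#'   author residue numbering.
#' @return Tibble `chain`, `resno`, `ins`, `aa`, `mean_score`,
#'   `n_substitutions`, one row per protein residue.
#' @export
residue_means <- function(table, structure) {
  stopifnot(inherits(structure, "tg_structure"))
  df <- tibble::as_tibble(table)
  up <- sort(unique(df$position))
  gi <- match(df$position, up)
  counts <- tabulate(gi, nbins = length(up))
  means <- as.vector(rowsum(df$score, gi)) / counts
  first_ref <- df$ref_aa[match(seq_along(up), gi)]

  res <- structure$residues
  m <- match(res$resno, up)
  out <- dplyr::mutate(
    res,
    mean_score = means[m],
    n_substitutions = ifelse(is.na(m), 0L, counts[m])
  )
  table_ref <- first_ref[m]
  bad <- !is.na(table_ref) & table_ref != res$aa
  mism <- tibble::tibble(chain = res$chain[bad], resno = res$resno[bad],
                         ins = res$ins[bad], structure_aa = res$aa[bad],
                         table_aa = table_ref[bad])
  if (nrow(mism) > 0) {
    message(nrow(mism), " position(s) where the score table reference ",
            "disagrees with the structure for ", structure$id)
  }
  attr(out, "mismatches") <- mism
  attr(out, "protein_id") <- score_protein_id(table)
  out
}
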