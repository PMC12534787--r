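#' Per-region mean pathogenicity summaries
#'
#' Joins per-residue mean scores onto the region residue sets and reduces
#' each region to its mean score, with explicit accounting of residues that
#' have no score (`n_missing`; these are excluded from the mean).
#'
#' @param res_means Per-residue means from [residue_means()].
#' @param sets Residue-set tibble from [residue_sets()] (or any binding of
#'   per-region sets).
#' @param protein_id Identifier stamped on the output rows (default: taken
#'   from `res_means`).
#' @return Tibble `protein_id`, `region`, `mean_score`, `n_residues`,
#'   `n_missing`, one row per region present in `sets`. A region whose set
#'   has no scored residues gets an `NA` mean.
#' @export
region_summaries <- function(res_means, sets, protein_id = NULL) {
  protein_id <- protein_id %||% attr(res_means, "protein_id") %||% NA_character_
  ms <- res_means$mean_score[match(
    paste(sets$chain, sets$resno, sets$ins),
    paste(res_means$chain, res_means$resno, res_means$ins)
  )]
  regions <- REGIONS[REGIONS %in% unique(sets$region)]
  reg <- factor(sets$region, levels = regions)
  n_residues <- tabulate(reg, nbins = length(regions))
  n_missing <- as.vector(tabulate(reg[is.na(ms)], nbins = length(regions)))
  mean_score <- vapply(regions, function(r) {
    v <- ms[!is.na(ms) & sets$region == r]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  tibble::tibble(protein_id = protein_id, region = regions,
                 mean_score = unname(mean_score),
                 n_residues = n_residues, n_missing = n_missing)
}

#' Amino-acid frequency profile of a residue set
#'
#' @param set A residue-set tibble (one region).
#' @return Tibble `aa`, `n`, `percent` covering all 20 standard amino acids
#'   (zero rows included); percentages sum to 100.
#' @export
aa_frequency_profile <- function(set) {
  if (is.null(set) || nrow(set) == 0) {
    stop("cannot profile an empty residue set", call. = FALSE)
  }
  set %>%
    dplyr::count(aa = factor(.data$aa, levels = AA_CODES),
                 .drop = FALSE, name = "n") %>%
    dplyr::mutate(aa = as.character(.data$aa),
                  percent = 100 * .data$n / sum(.data$n))
}

#' Per-amino-acid, per-region mean pathogenicity
#'
#' For each amino-acid type and region, the mean of per-residue mean scores
#' over residues of that type in that region (cohort-wide when the inputs
#' are concatenated over proteins). Combinations absent from the data are
#' reported with `NA` (a residue type can be entirely missing from, e.g.,
#' the cofactor microenvironment).
#'
#' @param res_means Per-residue means, optionally concatenated over proteins.
#' @param sets Matching residue sets (concatenated the same way; when
#'   concatenating, add a `protein_id` column to both so the join stays
#'   per-protein).
#' @return Tibble `region`, `aa`, `mean_score`, `n` for every region x
#'   20-amino-acid combination.
#' @export
per_aa_group_means <- function(res_means, sets) {
  keys <- intersect(c("protein_id", "chain", "resno", "ins"),
                    intersect(names(sets), names(res_means)))
  joined <- sets %>%
    dplyr::left_join(
      dplyr::select(res_means, dplyr::all_of(keys), "mean_score"),
      by = keys
    ) %>%
    dplyr::filter(!is.na(.data$mean_score))
  joined %>%
    dplyr::group_by(region = factor(.data$region, levels = REGIONS),
                    aa = factor(.data$aa, levels = AA_CODES),
                    .drop = FALSE) %>%
    dplyr::summarise(
      mean_score = ifelse(dplyr::n() == 0, NA_real_, mean(.data$mean_score)),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(region = as.character(.data$region),
                  aa = as.character(.data$aa),
                  mean_score = ifelse(is.nan(.data$mean_score), NA_real_,
                                      .data$mean_score)) %>%
    dplyr::filter(.data$region %in% unique(as.character(sets$region)))
}

#' Score-frequency histogram per region and amino acid
#'
#' Counts per-residue mean scores in equal-width bins over \[0, 1\],
#' stratified by region and amino-acid type (the data behind
#' score-frequency heatmaps). Bins are left-closed, with the final bin
#' right-closed so a score of exactly 1 is counted.
#'
#' @inheritParams per_aa_group_means
#' @param bins Number of equal-width bins (default 10).
#' @return Tibble `region`, `aa`, `bin` (index), `bin_lo`, `bin_hi`, `n`.
#'   Total counts per region equal the region's non-missing residue count.
#' @export
score_frequency_heatmap <- function(res_means, sets, bins = 10) {
  stopifnot(bins >= 2)
  breaks <- seq(0, 1, length.out = bins + 1)
  keys <- intersect(c("protein_id", "chain", "resno", "ins"),
                    intersect(names(sets), names(res_means)))
  joined <- sets %>%
    dplyr::left_join(
      dplyr::select(res_means, dplyr::all_of(keys), "mean_score"),
      by = keys
    ) %>%
    dplyr::filter(!is.na(.data$mean_score))
  joined %>%
    dplyr::mutate(bin = findInterval(.data$mean_score, breaks,
                                     rightmost.closed = TRUE)) %>%
    dplyr::count(.data$region, .data$aa, .data$bin, name = "n") %>%
    dplyr::mutate(bin_lo = breaks[.data$bin], bin_hi = breaks[.data$bin + 1])
}

#' Adherence to the monotone pathogenicity pattern
#'
#' A unit (a protein, or an amino-acid type when `level = "per_aa"`) adheres
#' to the pattern when its mean pathogenicity increases strictly from the
#' whole protein, through the tunnel set, to the cofactor set. For
#' inverse-scaled tools (`orientation = "pathogenic_low"`) both inequalities
#' reverse. Units missing any of the three region means are excluded from
#' the denominator and reported.
#'
#' @param x For `level = "per_protein"`: region summaries concatenated over
#'   proteins ([region_summaries()]). For `level = "per_aa"`: a per-amino-
#'   acid group-mean table ([per_aa_group_means()]).
#' @param orientation `"pathogenic_high"` or `"pathogenic_low"`.
#' @param level Unit of adherence counting.
#' @param tolerance Slack subtracted from each inequality (default 0:
#'   strict inequalities).
#' @return A one-row tibble of class `tg_adherence`: `level`, `n_total`,
#'   `n_adhering`, `rate` (percent), `n_excluded`; per-unit results in
#'   `attr(x, "units")`.
#' @export
adherence <- function(x, orientation = "pathogenic_high",
                      level = c("per_protein", "per_aa"), tolerance = 0) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  level <- match.arg(level)
  unit_col <- if (level == "per_protein") "protein_id" else "aa"
  if (!unit_col %in% names(x)) {
    stop("input lacks the '", unit_col, "' column required for level ",
         level, call. = FALSE)
  }
  wide <- x %>%
    dplyr::select(unit = dplyr::all_of(unit_col), "region", "mean_score") %>%
    tidyr::pivot_wider(names_from = "region", values_from = "mean_score")
  for (r in REGIONS) if (!r %in% names(wide)) wide[[r]] <- NA_real_
  complete <- stats::complete.cases(wide[, REGIONS])
  eligible <- wide[complete, , drop = FALSE]
  if (nrow(eligible) == 0) {
    stop("no unit has all three region means; cannot assess adherence",
         call. = FALSE)
  }
  s <- if (orientation == "pathogenic_high") 1 else -1
  units <- eligible %>%
    dplyr::mutate(adheres = s * (.data$tunnel - .data$protein) > tolerance &
                    s * (.data$cofactor - .data$tunnel) > tolerance)
  out <- tibble::tibble(
    level = level,
    n_total = nrow(units),
    n_adhering = sum(units$adheres),
    rate = 100 * sum(units$adheres) / nrow(units),
    n_excluded = sum(!complete)
  )
  attr(out, "units") <- units
  attr(out, "excluded") <- wide$unit[!complete]
  class(out) <- c("tg_adherence", class(out))
  out
}

#' Star annotation tiers for paired tests
#'
#' The tier convention used in the region-comparison figures:
#' `**` for p < .05, `***` for p < .005, `****` for p < .0005, `ns`
#' otherwise.
#'
#' @return Named numeric vector of thresholds (names are the star strings).
#' @export
star_tiers <- function() {
  c("****" = 5e-4, "***" = 5e-3, "**" = 0.05)
}

assign_stars <- function(p, tiers = star_tiers()) {
  tiers <- sort(tiers)
  vapply(p, function(pv) {
    hit <- which(pv < tiers)
    if (length(hit)) names(tiers)[hit[1]] else "ns"
  }, character(1))
}

#' Paired t-tests between region means across proteins
#'
#' Two-sided paired t-tests on per-protein region means, by default for the
#' protein-vs-tunnel and tunnel-vs-cofactor comparisons. For each
#' comparison, proteins with both region means present form the pairs; the
#' statistic is t = mean(d) / (sd(d) / sqrt(n)) on d = regionB - regionA
#' with n - 1 degrees of freedom. When every difference is zero the test is
#' degenerate and reported with p = 1 and no stars.
#'
#' @param summaries Region summaries concatenated over proteins.
#' @param comparisons List of length-2 character vectors of region names.
#' @param tiers Star tiers, see [star_tiers()].
#' @return A tibble of class `tg_paired_tests`: `comparison`, `region_a`,
#'   `region_b`, `n_pairs`, `mean_diff` (B - A), `t_statistic`, `df`,
#'   `p_value`, `stars`, `degenerate`.
#' @export
paired_tests <- function(summaries,
                         comparisons = list(c("protein", "tunnel"),
                                            c("tunnel", "cofactor")),
                         tiers = star_tiers()) {
  wide <- summaries %>%
    dplyr::select("protein_id", "region", "mean_score") %>%
    tidyr::pivot_wider(names_from = "region", values_from = "mean_score")
  out <- purrr::map_dfr(comparisons, function(cmp) {
    a <- cmp[1]; b <- cmp[2]
    if (!a %in% names(wide) || !b %in% names(wide)) {
      stop("comparison regions '", a, "'/'", b, "' absent from summaries",
           call. = FALSE)
    }
    ok <- !is.na(wide[[a]]) & !is.na(wide[[b]])
    d <- wide[[b]][ok] - wide[[a]][ok]
    n <- length(d)
    if (n < 2) {
      stop("comparison ", a, " vs ", b, " has fewer than 2 complete pairs",
           call. = FALSE)
    }
    sdd <- stats::sd(d)
    degenerate <- sdd == 0
    if (degenerate) {
      tstat <- NA_real_; p <- 1
    } else {
      tstat <- mean(d) / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
    tibble::tibble(
      comparison = paste(a, "vs", b), region_a = a, region_b = b,
      n_pairs = n, mean_diff = mean(d), t_statistic = tstat,
      df = n - 1, p_value = p,
      stars = if (degenerate) "ns" else assign_stars(p, tiers),
      degenerate = degenerate
    )
  })
  class(out) <- c("tg_paired_tests", class(out))
  out
}

#' @export
tidy.tg_paired_tests <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.tg_adherence <- function(x, ...) {
  attr(x, "units")
}

#' @export
glance.tg_adherence <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
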