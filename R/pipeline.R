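#' Pipeline run configuration
#'
#' Collects everything a full cohort run needs: the per-protein input
#' manifest, the geometric parameters, and the statistical options. A
#' protein entry names its structure file, its tunnel source (a MOLE-style
#' JSON path, or `"compute"` to run the built-in finder), and its score
#' table. Scale orientation is part of the configuration and never inferred
#' from score distributions.
#'
#' @param proteins List of per-protein entries, each a list with `id`,
#'   `structure` (PDB path), `tunnels` (JSON path or `"compute"`), `scores`
#'   (table path).
#' @param dialect Score-table dialect: `"variant"`, `"matrix"`,
#'   `"transcript"`.
#' @param orientation Scale orientation of the score tables.
#' @param cofactor_code HET code of the cofactor group.
#' @param spacing Centerline sample spacing, A.
#' @param n_atoms Closest-atom count for both residue-set rules.
#' @param tunnel_params A [tunnel_params()] list (used when computing
#'   tunnels).
#' @param adherence_level `"per_protein"` or `"per_aa"`.
#' @param bins Histogram bin count for the score-frequency table.
#' @param seed Integer seed for the tunnel finder.
#' @return A `tg_run_config` list.
#' @export
run_config <- function(proteins, dialect = "variant",
                       orientation = "pathogenic_high",
                       cofactor_code = "HEM", spacing = 0.5, n_atoms = 5,
                       tunnel_params = tunnelgrad::tunnel_params(),
                       adherence_level = "per_protein", bins = 10, seed = 1) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  dialect <- match.arg(dialect, c("variant", "matrix", "transcript"))
  stopifnot(length(proteins) >= 1)
  for (p in proteins) {
    if (is.null(p$structure) || is.null(p$scores)) {
      stop("every protein entry needs `structure` and `scores` paths",
           call. = FALSE)
    }
  }
  structure(
    list(proteins = proteins, dialect = dialect, orientation = orientation,
         cofactor_code = cofactor_code, spacing = spacing, n_atoms = n_atoms,
         tunnel_params = tunnel_params, adherence_level = adherence_level,
         bins = bins, seed = as.integer(seed)),
    class = "tg_run_config"
  )
}

#' Read a run configuration from a YAML manifest
#'
#' @param path Path to a YAML file with the fields of [run_config()].
#' @return A `tg_run_config`.
#' @export
read_run_config <- function(path) {
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  m$proteins <- lapply(m$proteins, function(p) {
    for (f in c("structure", "tunnels", "scores")) {
      if (!is.null(p[[f]]) && p[[f]] != "compute" && !file.exists(p[[f]])) {
        p[[f]] <- file.path(base, p[[f]])
      }
    }
    p
  })
  args <- m[intersect(names(m), names(formals(run_config)))]
  if (!is.null(args$tunnel_params)) {
    args$tunnel_params <- do.call(tunnel_params, args$tunnel_params)
  }
  do.call(run_config, args)
}

read_scores_any <- function(path, dialect, orientation) {
  switch(dialect,
         variant = read_variant_table(path, orientation),
         matrix = read_matrix_table(path, orientation),
         transcript = read_transcript_table(path, orientation))
}

#' Run the full region-pathogenicity pipeline over a cohort
#'
#' For every protein: read the structure, obtain tunnels (from JSON or the
#' built-in finder), build the three residue sets, aggregate substitution
#' scores to residue means, and summarise per region. Cohort-wide, compute
#' amino-acid frequency profiles per region, per-amino-acid group means,
#' score-frequency histogram counts, the adherence rate, and paired t-tests
#' for protein-vs-tunnel and tunnel-vs-cofactor. Proteins without any
#' detected tunnel stay in the run but contribute no tunnel or cofactor
#' statistics and are listed in the report; a protein whose stage fails is
#' skipped with a logged message.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, per-protein and cohort
#'   tables are written as TSV and the report as JSON.
#' @return A `tg_report` list: `summaries`, `residue_sets`,
#'   `residue_means`, `aa_frequencies`, `group_means`, `heatmap_counts`,
#'   `adherence`, `paired_tests`, `proteins_without_tunnels`, `skipped`,
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "tg_run_config"))
  per_protein <- purrr::map(config$proteins, function(p) {
    tryCatch({
      st <- read_structure(p$structure, cofactor_code = config$cofactor_code,
                           id = p$id)
      tun <- if (is.null(p$tunnels) || identical(p$tunnels, "compute")) {
        find_tunnels(st, params = config$tunnel_params, seed = config$seed)
      } else {
        read_mole_tunnels(p$tunnels)
      }
      has_tunnel <- nrow(tun) > 0
      sets <- dplyr::bind_rows(
        protein_set(st),
        if (has_tunnel) {
          tunnel_lining_set(st, tun, spacing = config$spacing,
                            n_atoms = config$n_atoms)
        },
        if (has_tunnel) cofactor_proximal_set(st, n_atoms = config$n_atoms)
      )
      tab <- read_scores_any(p$scores, config$dialect, config$orientation)
      rm_ <- residue_means(tab, st)
      list(
        id = st$id, has_tunnel = has_tunnel,
        sets = dplyr::mutate(sets, protein_id = st$id),
        means = dplyr::mutate(rm_, protein_id = st$id),
        summary = region_summaries(rm_, sets, protein_id = st$id)
      )
    }, error = function(e) {
      message("skipping protein '", p$id %||% p$structure, "': ",
              conditionMessage(e))
      NULL
    })
  })
  per_protein <- purrr::compact(per_protein)
  if (length(per_protein) == 0) {
    stop("no protein survived the pipeline; empty cohort", call. = FALSE)
  }

  summaries <- purrr::map_dfr(per_protein, "summary")
  all_sets <- purrr::map_dfr(per_protein, "sets")
  all_means <- purrr::map_dfr(per_protein, "means")
  no_tunnel <- purrr::map_chr(purrr::keep(per_protein,
                                          ~ !.x$has_tunnel), "id")

  aa_freq <- all_sets %>%
    dplyr::group_by(.data$region) %>%
    dplyr::group_modify(~ aa_frequency_profile(.x)) %>%
    dplyr::ungroup()
  group_means <- per_aa_group_means(all_means, all_sets)
  heat <- score_frequency_heatmap(all_means, all_sets, bins = config$bins)
  adh <- adherence(
    if (config$adherence_level == "per_protein") summaries else group_means,
    orientation = config$orientation, level = config$adherence_level
  )
  tests <- paired_tests(summaries)

  report <- structure(
    list(summaries = summaries, residue_sets = all_sets,
         residue_means = all_means, aa_frequencies = aa_freq,
         group_means = group_means, heatmap_counts = heat,
         adherence = adh, paired_tests = tests,
         proteins_without_tunnels = no_tunnel,
         skipped = setdiff(purrr::map_chr(config$proteins,
                                          ~ .x$id %||% .x$structure),
                           purrr::map_chr(per_protein, "id")),
         config = config),
    class = "tg_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$summaries, file.path(out_dir, "region_summaries.tsv"))
  readr::write_tsv(report$residue_sets, file.path(out_dir, "residue_sets.tsv"))
  readr::write_tsv(report$residue_means, file.path(out_dir, "residue_means.tsv"))
  readr::write_tsv(report$aa_frequencies, file.path(out_dir, "aa_frequencies.tsv"))
  readr::write_tsv(report$group_means, file.path(out_dir, "group_means.tsv"))
  readr::write_tsv(report$heatmap_counts, file.path(out_dir, "heatmap_counts.tsv"))
  jsonlite::write_json(
    list(
      adherence = as.list(tibble::as_tibble(unclass(report$adherence))),
      paired_tests = tibble::as_tibble(unclass(report$paired_tests)),
      proteins_without_tunnels = report$proteins_without_tunnels,
      skipped = report$skipped,
      n_proteins = length(unique(report$summaries$protein_id))
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.tg_report <- function(x, ...) {
  cat("<tg_report> ", length(unique(x$summaries$protein_id)), " proteins (",
      length(x$proteins_without_tunnels), " without tunnels, ",
      length(x$skipped), " skipped)\n", sep = "")
  cat("  adherence (", x$adherence$level, "): ",
      sprintf("%.1f%% (%d/%d)", x$adherence$rate, x$adherence$n_adhering,
              x$adherence$n_total), "\n", sep = "")
  for (i in seq_len(nrow(x$paired_tests))) {
    cat(sprintf("  %-20s t = %.3f, p = %.3g %s\n",
                x$paired_tests$comparison[i], x$paired_tests$t_statistic[i],
                x$paired_tests$p_value[i], x$paired_tests$stars[i]))
  }
  invisible(x)
}

#' @export
tidy.tg_report <- function(x, ...) {
  x$summaries
}

#' @export
glance.tg_report <- function(x, ...) {
  tibble::tibble(
    n_proteins = length(unique(x$summaries$protein_id)),
    n_without_tunnels = length(x$proteins_without_tunnels),
    n_skipped = length(x$skipped),
    adherence_rate = x$adherence$rate,
    p_protein_tunnel = x$paired_tests$p_value[
      x$paired_tests$comparison == "protein vs tunnel"][1],
    p_tunnel_cofactor = x$paired_tests$p_value[
      x$paired_tests$comparison == "tunnel vs cofactor"][1]
  )
}
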