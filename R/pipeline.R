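# End-to-end workflow: normalize -> impute -> classify/aggregate ->
# evaluate per contrast -> stratified evaluation, plus the report writers
# and the command entry points used by the thin CLI script
# (inst/cli/hpglyco.R).

DEFAULT_CONTRASTS <- list(
  c("control", "early"),
  c("control", "late"),
  c("early", "late"),
  c("control", "hcc")
)

#' Run the full glycopeptide biomarker pipeline
#'
#' Fixed stage order: heavy-standard normalization, minimum-value
#' imputation, glycan classification and feature aggregation, then marker
#' evaluation per contrast over the joint family of glyco-compounds and
#' aggregate features (one BH adjustment per contrast across both), and
#' stratified evaluation. When the metadata carries an `afp` column, AFP is
#' benchmarked per contrast (pairwise-complete, outside the BH family).
#'
#' @param quant Long quant tibble ([read_quant_matrix()] layout).
#' @param heavy Long heavy-standard tibble.
#' @param meta Sample metadata.
#' @param contrasts List of length-2 group contrasts (default: control vs
#'   early, control vs late, early vs late, control vs pooled HCC).
#' @param fdr BH level (default 0.20).
#' @param level Operating-point level (default 0.90).
#' @param strata Metadata columns to stratify on (default `phenotype` and
#'   `cirrhosis`; etiology flags may be added).
#' @param min_stratum_n Minimum patients per group within a stratum
#'   (default 10).
#' @param feature_scope Scope for [aggregate_features()] (default global).
#' @return A list of class `glyco_run`: `markers` (bound `marker_eval`
#'   tables over all contrasts), `features` (aggregated feature matrix),
#'   `afp` (benchmark rows or NULL), `strata` (per-stratum results),
#'   `quant` (processed compound table), and a `manifest` of the run's
#'   decisions.
#' @export
run_glyco_pipeline <- function(quant, heavy, meta,
                               contrasts = DEFAULT_CONTRASTS,
                               fdr = 0.20, level = 0.90,
                               strata = c("phenotype", "cirrhosis"),
                               min_stratum_n = 10L,
                               feature_scope = "global") {
  assert_quant(quant)
  absent <- setdiff(unique(quant$sample_id), meta$sample_id)
  if (length(absent)) {
    rlang::abort(paste0("sample(s) missing from metadata: ",
                        paste(utils::head(absent, 5L), collapse = ", ")),
                 class = "glyco_schema_error")
  }
  norm <- normalize_to_standard(quant, heavy)
  norm_info <- attr(norm, "normalization")
  imputed <- impute_min(norm)
  features <- aggregate_features(imputed, scope = feature_scope)

  marker_data <- dplyr::bind_rows(
    imputed |>
      dplyr::transmute(marker_id = .data$compound_id,
                       sample_id = .data$sample_id, area = .data$area,
                       type = "glyco-compound"),
    features |>
      dplyr::transmute(marker_id = paste0("feature:", .data$feature),
                       sample_id = .data$sample_id, area = .data$area,
                       type = "feature")
  )

  markers <- purrr::map(contrasts, function(ct) {
    evaluate_markers(marker_data, meta, ct, fdr = fdr, level = level)
  })
  names(markers) <- purrr::map_chr(contrasts, paste, collapse = "_vs_")
  markers_all <- dplyr::bind_rows(purrr::map(markers, tibble::as_tibble))

  afp_bench <- NULL
  if ("afp" %in% names(meta)) {
    afp_data <- meta |>
      dplyr::filter(!is.na(.data$afp)) |>
      dplyr::transmute(marker_id = "AFP", sample_id = .data$sample_id,
                       area = .data$afp)
    afp_bench <- purrr::map_dfr(contrasts, function(ct) {
      tibble::as_tibble(evaluate_markers(afp_data, meta, ct, fdr = fdr,
                                         level = level))
    })
    afp_bench$q <- NA_real_  # benchmark, outside the BH family
    afp_bench$significant <- NA
  }

  strata_res <- purrr::map(strata, function(sv) {
    if (!sv %in% names(meta)) return(NULL)
    stratified_evaluate(marker_data, meta, contrasts[[1]], stratum = sv,
                        min_n = min_stratum_n, fdr = fdr, level = level)
  })
  names(strata_res) <- strata

  manifest <- list(
    package_version = as.character(utils::packageVersion("hpglyco")),
    pipeline_order = "normalize -> impute -> aggregate -> evaluate",
    top3_heavy = norm_info$top3_peptides,
    bh_family = "glyco-compounds + aggregate features, jointly per contrast",
    fdr = fdr, operating_level = level,
    auc_orientation = "fixed positive class (case); oriented AUC also reported",
    tie_break = "top-3 heavy ties broken lexicographically by peptide id",
    min_stratum_n = min_stratum_n,
    contrasts = names(markers),
    config_hash = rlang::hash(list(fdr, level, strata, min_stratum_n,
                                   feature_scope, contrasts))
  )
  structure(
    list(markers = markers_all, markers_by_contrast = markers,
         features = features, afp = afp_bench, strata = strata_res,
         quant = imputed, manifest = manifest),
    class = "glyco_run"
  )
}

#' @export
print.glyco_run <- function(x, ...) {
  cat("Glycopeptide biomarker pipeline run\n")
  cat("  contrasts:", paste(x$manifest$contrasts, collapse = ", "), "\n")
  cat("  markers tested per contrast:",
      nrow(x$markers) / length(x$manifest$contrasts), "\n")
  sig <- x$markers |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(significant = sum(.data$significant, na.rm = TRUE),
                     .groups = "drop")
  print(sig)
  invisible(x)
}

#' Write the pipeline's reports to a directory
#'
#' `markers.tsv` (deterministic order: contrast, then q, then marker id),
#' `features.tsv`, `strata.tsv`, `afp.tsv` (when benchmarked) and
#' `manifest.txt` echoing every decision.
#'
#' @param run A [run_glyco_pipeline()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_tsv(
    run$markers, file.path(dir, "markers.tsv"),
    comments = c(
      "marker report; areas are heavy-standard-normalized XIC intensities",
      "p/q: two-sided Wilcoxon rank-sum, Benjamini-Hochberg within contrast",
      paste0("BH family: ", run$manifest$bh_family),
      "auc_fixed: case-positive orientation; auc_oriented = max(AUC, 1-AUC)",
      "operating points at the 90% level on empirical thresholds"
    )
  )
  write_report_tsv(run$features, file.path(dir, "features.tsv"),
                   comments = "summed normalized XIC intensity per glycan feature class")
  strata_tbl <- purrr::imap_dfr(run$strata, function(res, sv) {
    if (is.null(res) || !nrow(res$comparison)) return(tibble::tibble())
    dplyr::mutate(res$comparison, stratum_variable = sv)
  })
  write_report_tsv(strata_tbl, file.path(dir, "strata.tsv"),
                   comments = "per-stratum vs whole-cohort oriented AUC (first contrast)")
  if (!is.null(run$afp)) {
    write_report_tsv(run$afp, file.path(dir, "afp.tsv"),
                     comments = "AFP benchmark (pairwise-complete; outside the BH family)")
  }
  manifest_lines <- purrr::imap_chr(run$manifest, function(v, k) {
    paste0(k, ": ", paste(v, collapse = ", "))
  })
  writeLines(manifest_lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Command entry points
#'
#' Thin, file-oriented wrappers used by the CLI script: `cmd_simulate`
#' writes a synthetic cohort, `cmd_analyze` runs the full pipeline on files,
#' `cmd_digest` writes digest and sequon reports for a FASTA. Configuration
#' errors signal condition class `glyco_config_error` /
#' `glyco_schema_error`, which the CLI maps to exit code 2.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config A [cohort_config()].
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, config = cohort_config()) {
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, out_dir)
}

#' @rdname cmd_simulate
#' @param quant_file,heavy_file,meta_file Input TSV paths.
#' @param ... Passed to [run_glyco_pipeline()].
#' @export
cmd_analyze <- function(quant_file, heavy_file, meta_file, out_dir, ...) {
  quant <- read_quant_matrix(quant_file)
  heavy <- read_heavy_table(heavy_file)
  meta <- read_sample_meta(meta_file)
  run <- run_glyco_pipeline(quant, heavy, meta, ...)
  write_run_reports(run, out_dir)
}

#' @rdname cmd_simulate
#' @param fasta_file FASTA path of the target glycoprotein.
#' @param numbering_offset Offset added to sequon labels (for mature-chain
#'   sequences reported in precursor coordinates).
#' @param max_missed Missed-cleavage maximum for the digest report.
#' @export
cmd_digest <- function(fasta_file, out_dir, numbering_offset = 0L,
                       max_missed = 2L) {
  prot <- read_protein_fasta(fasta_file)
  sites <- find_sequons(prot$sequence, numbering_offset = numbering_offset)
  peptides <- digest_protein(prot$sequence, max_missed = max_missed)
  mapping <- map_sites_to_peptides(sites, peptides)
  covered <- mapping |>
    dplyr::filter(.data$covered) |>
    dplyr::group_by(.data$peptide, .data$start, .data$end, .data$missed) |>
    dplyr::summarise(covered_sites = paste(.data$label, collapse = ","),
                     .groups = "drop")
  digest_report <- peptides |>
    dplyr::left_join(covered, by = c("peptide", "start", "end", "missed")) |>
    dplyr::mutate(covered_sites = dplyr::coalesce(.data$covered_sites, ""))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_tsv(digest_report, file.path(out_dir, "digest.tsv"),
                   comments = c(paste0("digest of ", prot$accession),
                                "start/end are 0-based half-open coordinates"))
  write_report_tsv(sites, file.path(out_dir, "sequons.tsv"),
                   comments = "N-X-S/T sequons (X != P); labels 1-based + offset")
  invisible(out_dir)
}
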