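# Quantification-side operations on the long glycopeptide table:
# internal-standard normalization, left-censored imputation, QC CV and
# glycan-feature aggregation.
#
# The central table is long format: one row per (compound, sample) with
# columns compound_id, site, composition, sample_id, area (NA = missing,
# i.e. not identified in that sample).

assert_quant <- function(quant) {
  need <- c("compound_id", "sample_id", "area")
  missing_cols <- setdiff(need, names(quant))
  if (length(missing_cols)) {
    rlang::abort(paste0("quant table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "glyco_schema_error")
  }
  if (any(quant$area < 0, na.rm = TRUE)) {
    rlang::abort("XIC areas must be non-negative", class = "glyco_schema_error")
  }
  invisible(quant)
}

#' Select the top-3 heavy internal-standard peptides
#'
#' The three heavy peptides with the highest mean abundance across all
#' samples, requiring complete observations; ties at the cutoff are broken
#' by peptide id (lexicographic).
#'
#' @param heavy Long tibble with columns `peptide_id`, `sample_id`,
#'   `abundance`.
#' @return Character vector of 3 peptide ids.
#' @export
select_top3_heavy <- function(heavy) {
  complete <- heavy |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$abundance)),
      mean_abundance = mean(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_missing == 0L)
  if (nrow(complete) < 3L) {
    rlang::abort("need at least 3 heavy peptides with complete observations",
                 class = "glyco_schema_error")
  }
  top <- complete |>
    dplyr::arrange(dplyr::desc(.data$mean_abundance), .data$peptide_id) |>
    dplyr::slice_head(n = 3L)
  top$peptide_id
}

#' Normalize XIC areas to the spiked heavy standard
#'
#' Divides every sample's areas by that sample's summed top-3 heavy-peptide
#' abundance T(s), then rescales by the global mean of T(s) so output stays
#' on the input intensity scale:
#' `area'(g, s) = area(g, s) / T(s) * mean(T)`. Missing stays missing.
#' Applying the normalization twice is a no-op (T becomes constant).
#'
#' @param quant Long quant tibble (`compound_id`, `sample_id`, `area`, ...).
#' @param heavy Long heavy-standard tibble (`peptide_id`, `sample_id`,
#'   `abundance`).
#' @return The quant tibble with normalized `area`; the selected heavy
#'   peptides and per-sample factors are attached as attribute
#'   `"normalization"`.
#' @export
normalize_to_standard <- function(quant, heavy) {
  assert_quant(quant)
  top3 <- select_top3_heavy(heavy)
  factors <- heavy |>
    dplyr::filter(.data$peptide_id %in% top3) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(t_s = sum(.data$abundance), .groups = "drop")
  absent <- setdiff(unique(quant$sample_id), factors$sample_id)
  if (length(absent)) {
    rlang::abort(paste0("sample(s) missing from heavy-standard table: ",
                        paste(absent, collapse = ", ")),
                 class = "glyco_schema_error")
  }
  zero <- factors$sample_id[factors$t_s <= 0]
  if (length(zero)) {
    rlang::abort(paste0("heavy-standard abundance is zero in sample(s): ",
                        paste(zero, collapse = ", ")),
                 class = "glyco_schema_error")
  }
  t_mean <- mean(factors$t_s)
  out <- quant |>
    dplyr::left_join(factors, by = "sample_id") |>
    dplyr::mutate(area = .data$area / .data$t_s * t_mean) |>
    dplyr::select(-"t_s")
  attr(out, "normalization") <- list(top3_peptides = top3, factors = factors,
                                     t_mean = t_mean)
  out
}

#' Impute missing areas with the per-glycopeptide minimum
#'
#' For each glyco-compound, missing values are replaced by the minimum
#' observed area of that compound across the whole dataset (all samples, all
#' groups). Observed values are never altered. Compounds observed in no
#' sample carry no information and are dropped with a warning.
#'
#' @param quant Long quant tibble.
#' @return The tibble with no remaining missing `area` among retained
#'   compounds.
#' @export
impute_min <- function(quant) {
  assert_quant(quant)
  obs <- quant |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$area)),
                     row_min = suppressWarnings(min(.data$area, na.rm = TRUE)),
                     .groups = "drop")
  empty <- obs$compound_id[obs$n_obs == 0L]
  if (length(empty)) {
    rlang::warn(paste0("dropping ", length(empty),
                       " all-missing glyco-compound(s): ",
                       paste(utils::head(empty, 5L), collapse = ", "),
                       if (length(empty) > 5L) ", ..." else ""))
    quant <- dplyr::filter(quant, !.data$compound_id %in% empty)
    obs <- dplyr::filter(obs, !.data$compound_id %in% empty)
  }
  quant |>
    dplyr::left_join(obs[, c("compound_id", "row_min")], by = "compound_id") |>
    dplyr::mutate(area = dplyr::coalesce(.data$area, .data$row_min)) |>
    dplyr::select(-"row_min")
}

#' QC coefficient of variation across replicate control measurements
#'
#' CV% = 100 * sd/mean per aggregation level over the designated control
#' samples: at `level = "protein"` the per-sample total (sum over all rows);
#' at `level = "peptide-set"` one CV per supplied row set. A summary (mean
#' and range across sets) is attached as attribute `"summary"`.
#'
#' @param quant Long quant tibble (missing areas treated as 0 in sums).
#' @param control_samples Character vector of at least 2 replicate sample
#'   ids.
#' @param level `"protein"` or `"peptide-set"`.
#' @param row_sets Named list of compound-id vectors (required for
#'   `"peptide-set"`).
#' @return A tibble with `set_id` and `cv_pct` (NA when the mean is 0).
#' @export
qc_cv <- function(quant, control_samples, level = c("protein", "peptide-set"),
                  row_sets = NULL) {
  assert_quant(quant)
  level <- match.arg(level)
  if (length(control_samples) < 2L) {
    rlang::abort("need at least 2 control samples for a CV",
                 class = "glyco_schema_error")
  }
  ctrl <- dplyr::filter(quant, .data$sample_id %in% control_samples)
  sets <- if (level == "protein") {
    list(protein = unique(ctrl$compound_id))
  } else {
    if (is.null(row_sets)) rlang::abort("row_sets required at peptide-set level")
    row_sets
  }
  out <- purrr::imap_dfr(sets, function(ids, set_id) {
    sums <- ctrl |>
      dplyr::filter(.data$compound_id %in% ids) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(total = sum(.data$area, na.rm = TRUE), .groups = "drop")
    m <- mean(sums$total)
    tibble::tibble(set_id = set_id,
                   cv_pct = if (m == 0) NA_real_ else 100 * stats::sd(sums$total) / m)
  })
  attr(out, "summary") <- tibble::tibble(
    mean_cv = mean(out$cv_pct, na.rm = TRUE),
    min_cv = suppressWarnings(min(out$cv_pct, na.rm = TRUE)),
    max_cv = suppressWarnings(max(out$cv_pct, na.rm = TRUE))
  )
  out
}

# Feature-class membership of one classified row: which summed features
# (fucosylation_1..4, sialylation_1..4, antennae_2..4, high_mannose) it
# contributes to. Degrees >= 5 pool into "4" when pool_high is TRUE.
feature_classes <- function(class_row, pool_high = TRUE, include_zero = FALSE) {
  deg <- function(d) if (pool_high) pmin(d, 4L) else d
  out <- character(0)
  fd <- deg(class_row$fucosylation)
  sd_ <- deg(class_row$sialylation)
  if (fd > 0 || include_zero) out <- c(out, paste0("fucosylation_", fd))
  if (sd_ > 0 || include_zero) out <- c(out, paste0("sialylation_", sd_))
  if (class_row$family == "complex" && class_row$antennae >= 2) {
    out <- c(out, paste0("antennae_", class_row$antennae))
  }
  if (class_row$family == "high-mannose") out <- c(out, "high_mannose")
  out
}

#' Aggregate glyco-compound intensities into glycan feature classes
#'
#' Sums intensities of glycans sharing a characteristic -- 1-4 fucoses,
#' 1-4 sialic acids, bi/tri/tetra-antennary branching, high-mannose --
#' either globally or per glycosite. Classification is derived from the
#' `composition` column via [classify_glycans()]. Degrees of 5 or more pool
#' into the "4" class by default.
#'
#' @param quant Long quant tibble with `site` and `composition` columns.
#' @param scope `"global"` or `"per-site"` (feature ids become
#'   `site:feature`).
#' @param pool_high Pool degrees >= 5 into degree 4 (default TRUE).
#' @param include_zero Also emit the degree-0 fucosylation/sialylation
#'   classes (default FALSE; useful for conservation checks).
#' @return Long tibble with `feature`, `sample_id`, `area` (sum over member
#'   rows; a compound missing in a sample contributes 0).
#' @export
aggregate_features <- function(quant, scope = c("global", "per-site"),
                               pool_high = TRUE, include_zero = FALSE) {
  assert_quant(quant)
  scope <- match.arg(scope)
  stopifnot(all(c("site", "composition") %in% names(quant)))
  cls <- classify_glycans(dplyr::distinct(quant, .data$site, .data$composition))
  cls$classes <- purrr::map(seq_len(nrow(cls)), function(i) {
    feature_classes(cls[i, ], pool_high = pool_high, include_zero = include_zero)
  })
  membership <- tidyr::unnest(cls[, c("site", "composition", "classes")],
                              "classes")
  membership$feature <- if (scope == "per-site") {
    paste0(membership$site, ":", membership$classes)
  } else {
    membership$classes
  }
  all_features <- sort(unique(membership$feature))
  quant |>
    dplyr::inner_join(membership[, c("site", "composition", "feature")],
                      by = c("site", "composition"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$feature, .data$sample_id) |>
    dplyr::summarise(area = sum(.data$area, na.rm = TRUE), .groups = "drop") |>
    tidyr::complete(feature = all_features,
                    sample_id = unique(quant$sample_id),
                    fill = list(area = 0))
}
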