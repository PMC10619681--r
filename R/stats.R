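# Differential testing and ROC evaluation. The ROC machinery (AUC by pair
# counting / midranks, empirical operating points) is implemented here; the
# Wilcoxon p-value and BH adjustment are delegated to stats::wilcox.test and
# stats::p.adjust, with the U statistic computed from midranks in-package so
# the U/(n1*n2) = AUC identity can be asserted per marker.

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test of location shift between two samples. The exact null
#' distribution is used when `min(n1, n2) <= 8` and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#' U is computed with midranks (so `U / (n1 * n2)` equals the
#' tie-corrected AUC of x scored against y).
#'
#' @param x,y Numeric vectors (case and control), each of length >= 2.
#' @return A tibble: `p_value`, `statistic` (U for x), `direction` (sign of
#'   the location shift of x relative to y; 0 when balanced).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    p <- 1
  } else {
    use_exact <- min(n1, n2) <= 8L && !ties
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)$p.value
    )
  }
  tibble::tibble(
    p_value = min(p, 1),
    statistic = u,
    direction = sign(u - n1 * n2 / 2)
  )
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up q-values `q_i = min_{j >= rank(i)} m * p_(j) / j` (clipped at 1)
#' and flags at the chosen FDR (default 20%, the study's screening level).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param fdr FDR level (default 0.20).
#' @return A tibble: `p`, `q`, `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.20) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), fdr > 0, fdr < 1)
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = !is.na(q) & q <= fdr)
}

roc_labels <- function(labels, positive) {
  is_case <- labels == positive
  if (!any(is_case) || all(is_case)) {
    rlang::abort("ROC needs at least one case and one control",
                 class = "glyco_schema_error")
  }
  is_case
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = (#{case > control} + 0.5 * #{ties}) / (n_case * n_control)`,
#' computed via midranks. The orientation is fixed: the designated positive
#' class is scored as the case, so a down-regulated marker yields AUC < 0.5
#' (reports additionally carry the auto-oriented `max(AUC, 1 - AUC)`).
#'
#' @param scores Numeric marker values.
#' @param labels Class labels, same length.
#' @param positive The label value counting as case.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(3, 5, 1, 4), c("hcc", "hcc", "ctl", "ctl"), positive = "hcc")
#' @export
roc_auc <- function(scores, labels, positive) {
  is_case <- roc_labels(labels, positive)
  n1 <- sum(is_case); n2 <- sum(!is_case)
  r <- rank(scores)
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Empirical ROC curve
#'
#' Sensitivity/specificity at every empirical threshold (classifier:
#' `score >= threshold` is called positive), including the trivial endpoints
#' (sensitivity 1, specificity 0) and (0, 1).
#'
#' @inheritParams roc_auc
#' @return A tibble of class `glyco_roc`: `threshold`, `sensitivity`,
#'   `specificity`, ordered by decreasing sensitivity.
#' @export
roc_curve <- function(scores, labels, positive) {
  is_case <- roc_labels(labels, positive)
  n1 <- sum(is_case); n2 <- sum(!is_case)
  # counts per unique score, descending, cumulated = calls at score >= t
  tab <- rowsum(cbind(case = as.numeric(is_case), ctrl = as.numeric(!is_case)),
                scores)
  u_desc <- rev(sort(unique(scores)))
  tp <- cumsum(rev(tab[, "case"]))
  fp <- cumsum(rev(tab[, "ctrl"]))
  out <- tibble::tibble(
    threshold = c(Inf, u_desc, -Inf),
    sensitivity = c(0, tp / n1, 1),
    specificity = c(1, 1 - fp / n2, 0)
  )
  class(out) <- c("glyco_roc", class(out))
  attr(out, "positive") <- positive
  out
}

#' Operating point at a fixed sensitivity or specificity
#'
#' With `fix = "specificity"`: the maximum sensitivity over empirical
#' thresholds whose specificity is at least `level` (no interpolation);
#' symmetrically for `fix = "sensitivity"`. The study reports both at the
#' 90% level.
#'
#' @param roc A [roc_curve()] result.
#' @param fix Which metric is held fixed.
#' @param level The fixed level (default 0.90).
#' @return The complementary metric (possibly 0).
#' @export
operating_point <- function(roc, fix = c("specificity", "sensitivity"),
                            level = 0.90) {
  fix <- match.arg(fix)
  if (fix == "specificity") {
    max(roc$sensitivity[roc$specificity >= level], 0)
  } else {
    max(roc$specificity[roc$sensitivity >= level], 0)
  }
}

#' Count markers in AUC performance tiers
#'
#' Both conventions over oriented AUCs: non-nested bands
#' (>0.90, 0.80-0.90, 0.75-0.80, 0.70-0.75] and nested counts
#' (>0.90, >0.80, >0.75, >0.70).
#'
#' @param auc Numeric vector of (oriented) AUCs.
#' @return One-row tibble with banded and nested tier counts.
#' @export
auc_tiers <- function(auc) {
  tibble::tibble(
    band_gt90 = sum(auc > 0.90),
    band_80_90 = sum(auc > 0.80 & auc <= 0.90),
    band_75_80 = sum(auc > 0.75 & auc <= 0.80),
    band_70_75 = sum(auc > 0.70 & auc <= 0.75),
    nested_gt90 = sum(auc > 0.90),
    nested_gt80 = sum(auc > 0.80),
    nested_gt75 = sum(auc > 0.75),
    nested_gt70 = sum(auc > 0.70)
  )
}

#' Evaluate markers for one group contrast
#'
#' For every marker: two-sided Wilcoxon p, BH q over all markers tested in
#' the contrast, fixed-orientation AUC (cases positive), the auto-oriented
#' AUC, and both 90% operating points. Rows are ordered by q then marker id.
#'
#' @param data Long tibble with marker values: columns `marker_id` (or as
#'   named by `marker`), `sample_id`, and the value column.
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param contrast Length-2 character vector `c(control_group, case_group)`;
#'   the special group `"hcc"` pools `early` and `late`.
#' @param fdr BH level (default 0.20).
#' @param level Operating-point level (default 0.90).
#' @param marker,value Tidy-eval columns for marker id and value (defaults
#'   `marker_id`, `area`).
#' @return A tibble of class `marker_eval` with columns `marker`,
#'   `contrast`, `n_case`, `n_control`, `p`, `q`, `significant`,
#'   `auc_fixed`, `auc_oriented`, `sens_at_90spec`, `spec_at_90sens`,
#'   `direction`.
#' @export
evaluate_markers <- function(data, meta, contrast, fdr = 0.20, level = 0.90,
                             marker = marker_id, value = area) {
  stopifnot(length(contrast) == 2L)
  if (contrast[1] == contrast[2]) {
    rlang::abort("contrast must name two distinct groups",
                 class = "glyco_schema_error")
  }
  grp <- resolve_groups(meta, contrast)
  if (!nrow(grp$control) || !nrow(grp$case)) {
    rlang::abort(paste0("empty contrast group in ", paste(contrast, collapse = " vs ")),
                 class = "glyco_schema_error")
  }
  dd <- data |>
    dplyr::transmute(marker = {{ marker }}, sample_id = .data$sample_id,
                     value = {{ value }}) |>
    dplyr::filter(!is.na(.data$value))
  case_ids <- grp$case$sample_id
  control_ids <- grp$control$sample_id

  res <- dd |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(g, key) {
      x <- g$value[g$sample_id %in% case_ids]
      y <- g$value[g$sample_id %in% control_ids]
      if (length(x) < 2L || length(y) < 2L) {
        return(tibble::tibble(n_case = length(x), n_control = length(y),
                              p = NA_real_, auc_fixed = NA_real_,
                              auc_oriented = NA_real_,
                              sens_at_90spec = NA_real_,
                              spec_at_90sens = NA_real_,
                              direction = NA_real_))
      }
      w <- wilcoxon_rank_sum(x, y)
      scores <- c(x, y)
      labels <- rep(c("case", "control"), c(length(x), length(y)))
      auc <- roc_auc(scores, labels, positive = "case")
      rc <- roc_curve(scores, labels, positive = "case")
      # a down-regulated marker discriminates with score < threshold; its
      # operating points are read off the flipped score
      rc_or <- if (auc < 0.5) roc_curve(-scores, labels, "case") else rc
      tibble::tibble(
        n_case = length(x), n_control = length(y),
        p = w$p_value,
        auc_fixed = auc,
        auc_oriented = max(auc, 1 - auc),
        sens_at_90spec = operating_point(rc_or, "specificity", level),
        spec_at_90sens = operating_point(rc_or, "sensitivity", level),
        direction = w$direction
      )
    }) |>
    dplyr::ungroup()

  adj <- bh_adjust(res$p, fdr = fdr)
  res$q <- adj$q
  res$significant <- adj$significant
  res$contrast <- paste(contrast[1], "vs", contrast[2])
  out <- res |>
    dplyr::relocate("marker", "contrast", "n_case", "n_control", "p", "q",
                    "significant") |>
    dplyr::arrange(.data$q, .data$marker)
  class(out) <- c("marker_eval", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "fdr") <- fdr
  attr(out, "level") <- level
  out
}

resolve_groups <- function(meta, contrast) {
  pick <- function(g) {
    if (g == "hcc") dplyr::filter(meta, .data$group %in% c("early", "late"))
    else dplyr::filter(meta, .data$group == g)
  }
  list(control = pick(contrast[1]), case = pick(contrast[2]))
}

#' Stratified marker evaluation
#'
#' Re-runs [evaluate_markers()] within strata (haptoglobin phenotype, an
#' etiology flag, or cirrhosis status). Strata with fewer than `min_n`
#' patients in either contrast group are skipped with a logged reason
#' (message), matching the study's minimum of 10 patients per group. A
#' comparison of per-stratum vs whole-cohort oriented AUC is included.
#'
#' @inheritParams evaluate_markers
#' @param stratum Name of the metadata column to stratify on (`"phenotype"`,
#'   `"cirrhosis"`, or an etiology flag such as `"hbv"`).
#' @param min_n Minimum patients per contrast group within a stratum
#'   (default 10).
#' @return A list: `strata` (named list of `marker_eval` tables),
#'   `skipped` (tibble of skipped strata with reasons), `comparison`
#'   (marker x stratum oriented AUC vs the whole-cohort AUC).
#' @export
stratified_evaluate <- function(data, meta, contrast, stratum, min_n = 10L,
                                fdr = 0.20, level = 0.90,
                                marker = marker_id, value = area) {
  if (!stratum %in% names(meta)) {
    rlang::abort(paste0("stratum column '", stratum, "' not in metadata"),
                 class = "glyco_schema_error")
  }
  whole <- evaluate_markers(data, meta, contrast, fdr = fdr, level = level,
                            marker = {{ marker }}, value = {{ value }})
  levels_ <- sort(unique(stats::na.omit(meta[[stratum]])))
  levels_ <- setdiff(as.character(levels_), "unknown")
  out <- list(); skipped <- list()
  for (lv in levels_) {
    sub <- meta[!is.na(meta[[stratum]]) & as.character(meta[[stratum]]) == lv, ]
    grp <- resolve_groups(sub, contrast)
    n_ctl <- nrow(grp$control); n_case <- nrow(grp$case)
    if (min(n_ctl, n_case) < min_n) {
      msg <- paste0("stratum '", lv, "' skipped: ", n_ctl, " ", contrast[1],
                    " / ", n_case, " ", contrast[2], " patients (min ", min_n,
                    " per group)")
      message(msg)
      skipped[[lv]] <- tibble::tibble(stratum = lv, n_control = n_ctl,
                                      n_case = n_case, reason = msg)
      next
    }
    ev <- evaluate_markers(data, sub, contrast, fdr = fdr, level = level,
                           marker = {{ marker }}, value = {{ value }})
    ev$stratum <- lv
    out[[lv]] <- ev
  }
  comparison <- purrr::imap_dfr(out, function(ev, lv) {
    tibble::tibble(marker = ev$marker, stratum = lv,
                   auc_stratum = ev$auc_oriented)
  })
  if (nrow(comparison)) {
    comparison <- dplyr::left_join(
      comparison,
      tibble::tibble(marker = whole$marker, auc_whole = whole$auc_oriented),
      by = "marker"
    )
    comparison$auc_delta <- comparison$auc_stratum - comparison$auc_whole
  }
  list(
    strata = out,
    skipped = dplyr::bind_rows(skipped),
    comparison = comparison,
    whole = whole
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a marker evaluation table
#'
#' @param x A `marker_eval` object.
#' @param ... Unused.
#' @return A plain tibble of per-marker results.
#' @export
tidy.marker_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' One-row summary of a marker evaluation
#'
#' @param x A `marker_eval` object.
#' @param ... Unused.
#' @return One row: contrast, marker and significance counts, FDR level,
#'   and AUC tier counts (banded and nested) over oriented AUCs.
#' @export
glance.marker_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      contrast = x$contrast[1],
      n_markers = nrow(x),
      n_significant = sum(x$significant, na.rm = TRUE),
      fdr = attr(x, "fdr")
    ),
    auc_tiers(x$auc_oriented[!is.na(x$auc_oriented)])
  )
}
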