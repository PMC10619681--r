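# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: per-site glycoform catalogs (36/42/31/50 at
# N184/N207/N211/N241), ~5 decades of baseline dynamic range, monotone
# disease effects on fucosylated/branched/high-mannose classes, a per-sample
# technical factor shared with the heavy-standard spike (~10% CV), and hard
# left-censoring of low-abundance values. Every designed effect is written
# to a ground-truth ledger for parameter-recovery tests.

#' Default per-group designed-AUC effect map
#'
#' Feature-class effects expressed as designed AUCs versus the control group
#' (binormal scale; 0.5 = null). The defaults encode the study system's
#' qualitative progression -- higher fucosylation, tetra-antennary branching,
#' tetra-sialylation and high-mannose content rising from control through
#' early- to late-stage disease -- with illustrative magnitudes.
#'
#' @return Tibble with columns `class`, `early`, `late`.
#' @export
default_effect_map <- function() {
  tibble::tribble(
    ~class,            ~early, ~late,
    "fucosylation_1",  0.55,   0.68,
    "fucosylation_3",  0.72,   0.82,
    "fucosylation_4",  0.75,   0.85,
    "sialylation_4",   0.70,   0.72,
    "antennae_4",      0.62,   0.72,
    "high_mannose",    0.72,   0.78
  )
}

#' Haptoglobin phenotype proportions per group
#'
#' The clinical cohort's phenotype distribution (fractions of 1-1, 2-1,
#' 2-2 per group; the remainder is "unknown").
#'
#' @return Named list of named numeric vectors.
#' @export
default_phenotype_props <- function() {
  list(
    control = c("1-1" = 0.053, "2-1" = 0.58, "2-2" = 0.35),
    early = c("1-1" = 0.08, "2-1" = 0.32, "2-2" = 0.52),
    late = c("1-1" = 0.063, "2-1" = 0.47, "2-2" = 0.38)
  )
}

#' Cohort generator configuration
#'
#' @param n_control,n_early,n_late Group sizes (defaults 57/50/32, the
#'   clinical cohort).
#' @param site_glycoforms Named integer vector: glycoforms per glycosite
#'   (defaults 36/42/31/50 at N184/N207/N211/N241).
#' @param decades Baseline log10 dynamic range (default 5).
#' @param technical_cv Technical coefficient of variation of the per-sample
#'   factor and per-measurement noise (default 0.10).
#' @param bio_sd Between-subject biological SD on the log10 scale
#'   (default 0.5).
#' @param effect_map Tibble (`class`, `early`, `late`) of designed AUCs; see
#'   [default_effect_map()]. Classes must be valid feature ids.
#' @param censor_quantile Quantile of raw intensities below which values are
#'   censored to missing (default 0.05).
#' @param phenotype_props Per-group phenotype proportions
#'   ([default_phenotype_props()]).
#' @param baseline_log10_min Log10 of the least abundant baseline
#'   (default 3).
#' @param afp_auc Designed AUC of the simulated AFP benchmark for HCC vs
#'   control (default 0.79); `NA` disables AFP simulation.
#' @param n_heavy Number of heavy-standard peptides (default 6).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 57L, n_early = 50L, n_late = 32L,
                          site_glycoforms = c(N184 = 36L, N207 = 42L,
                                              N211 = 31L, N241 = 50L),
                          decades = 5, technical_cv = 0.10, bio_sd = 0.5,
                          effect_map = default_effect_map(),
                          censor_quantile = 0.05,
                          phenotype_props = default_phenotype_props(),
                          baseline_log10_min = 3, afp_auc = 0.79,
                          n_heavy = 6L) {
  if (min(n_control, n_early, n_late) < 2L) {
    rlang::abort("group sizes must be at least 2", class = "glyco_config_error")
  }
  if (decades <= 0 || technical_cv < 0 || bio_sd < 0) {
    rlang::abort("decades must be > 0 and CV/SD >= 0", class = "glyco_config_error")
  }
  valid_classes <- c(paste0("fucosylation_", 1:4), paste0("sialylation_", 1:4),
                     paste0("antennae_", 2:4), "high_mannose")
  bad <- setdiff(effect_map$class, valid_classes)
  if (length(bad)) {
    rlang::abort(paste0("unknown feature class in effect map: ",
                        paste(bad, collapse = ", ")),
                 class = "glyco_config_error")
  }
  if (censor_quantile < 0 || censor_quantile >= 1) {
    rlang::abort("censor_quantile must be in [0, 1)", class = "glyco_config_error")
  }
  for (props in phenotype_props) {
    if (sum(props) > 1 + 1e-9) {
      rlang::abort("phenotype proportions must not sum above 1",
                   class = "glyco_config_error")
    }
  }
  structure(
    list(
      n_control = n_control, n_early = n_early, n_late = n_late,
      site_glycoforms = site_glycoforms, decades = decades,
      technical_cv = technical_cv, bio_sd = bio_sd, effect_map = effect_map,
      censor_quantile = censor_quantile, phenotype_props = phenotype_props,
      baseline_log10_min = baseline_log10_min, afp_auc = afp_auc,
      n_heavy = n_heavy
    ),
    class = "cohort_config"
  )
}

# Master composition catalog: the plausible N-glycan space the generator
# samples per-site glycoforms from (high-mannose Man5-9; hybrids; complex
# bi/tri/tetra-antennary with 0-4 fucoses and up-to-antenna sialic acids,
# plus some bisected species).
master_catalog <- function() {
  high_man <- tibble::tibble(hexnac = 2L, hex = 5:9, fuc = 0L, neuac = 0L)
  hybrid <- tidyr::expand_grid(hexnac = 3L, hex = 5:7, fuc = 0:1, neuac = 0:1)
  complex_ <- purrr::map_dfr(2:4, function(a) {
    tidyr::expand_grid(hexnac = a + 2L, hex = a + 3L, fuc = 0:4, neuac = 0:a)
  })
  bisected <- purrr::map_dfr(2:3, function(a) {
    tidyr::expand_grid(hexnac = a + 3L, hex = a + 3L, fuc = 0:2, neuac = 0:1)
  })
  cat_all <- dplyr::distinct(dplyr::bind_rows(high_man, hybrid, complex_, bisected))
  cat_all$composition <- format_glycan(cat_all$hexnac, cat_all$hex,
                                       cat_all$fuc, cat_all$neuac)
  cat_all
}

# log10-scale technical SD equivalent to a lognormal CV
cv_to_sdlog10 <- function(cv) sqrt(log(1 + cv^2)) / log(10)

#' Generate a synthetic glycopeptide cohort
#'
#' Draws per-compound baselines log10-uniformly over the configured decades,
#' applies the effect map's designed-AUC shifts multiplicatively per group,
#' adds between-subject biological noise, multiplies every row and the heavy
#' standard by a shared per-sample technical factor, adds per-measurement
#' technical noise, and censors intensities below the configured quantile to
#' missing. Identical seeds give identical cohorts.
#'
#' A compound matching several effect classes takes the single strongest
#' class shift per group. Designed AUCs in the truth ledger use the binormal
#' identity `AUC = pnorm(delta / (sigma * sqrt(2)))` with
#' `sigma^2 = bio_sd^2 + technical_sd^2` on the log10 scale (the shared
#' per-sample factor is excluded because normalization removes it).
#'
#' @param config A [cohort_config()].
#' @param seed Integer random seed.
#' @return A list of class `glyco_cohort`: `quant` (long tibble with
#'   missingness), `heavy`, `meta`, and `truth` (list: `compounds` ledger,
#'   `samples` with technical factors, `config`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  groups <- rep(c("control", "early", "late"),
                c(config$n_control, config$n_early, config$n_late))
  n_samples <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # per-site glycoform catalogs
  master <- master_catalog()
  compounds <- purrr::imap_dfr(as.list(config$site_glycoforms), function(k, site) {
    if (k > nrow(master)) {
      rlang::abort("site glycoform count exceeds catalog size",
                   class = "glyco_config_error")
    }
    picked <- master[sample.int(nrow(master), k), ]
    picked$site <- site
    picked
  })
  compounds$compound_id <- paste0(compounds$site, ":", compounds$composition)
  compounds <- classify_glycans(compounds)

  # effect assignment: strongest matching class per group
  tech_sd <- cv_to_sdlog10(config$technical_cv)
  sigma <- sqrt(config$bio_sd^2 + tech_sd^2)
  em <- config$effect_map
  effect_of <- function(i, group_col) {
    classes <- feature_classes(compounds[i, ])
    hits <- em[em$class %in% classes, ]
    if (!nrow(hits)) return(0)
    aucs <- hits[[group_col]]
    delta <- stats::qnorm(aucs) * sigma * sqrt(2)
    delta[which.max(abs(delta))]
  }
  compounds$delta_early <- vapply(seq_len(nrow(compounds)), effect_of,
                                  numeric(1), group_col = "early")
  compounds$delta_late <- vapply(seq_len(nrow(compounds)), effect_of,
                                 numeric(1), group_col = "late")
  compounds$baseline_log10 <- stats::runif(nrow(compounds),
                                           config$baseline_log10_min,
                                           config$baseline_log10_min + config$decades)
  compounds$designed_auc_early <- stats::pnorm(compounds$delta_early / (sigma * sqrt(2)))
  compounds$designed_auc_late <- stats::pnorm(compounds$delta_late / (sigma * sqrt(2)))
  compounds$is_marker <- compounds$delta_early != 0 | compounds$delta_late != 0

  # per-sample technical factor (shared with the heavy standard)
  t_factor_log10 <- stats::rnorm(n_samples, 0, tech_sd)

  delta_mat <- cbind(control = 0, early = compounds$delta_early,
                     late = compounds$delta_late)
  n_comp <- nrow(compounds)
  log10_val <- matrix(compounds$baseline_log10, n_comp, n_samples) +
    delta_mat[, groups, drop = FALSE] +
    matrix(stats::rnorm(n_comp * n_samples, 0, config$bio_sd), n_comp) +
    matrix(t_factor_log10, n_comp, n_samples, byrow = TRUE) +
    matrix(stats::rnorm(n_comp * n_samples, 0, tech_sd), n_comp)
  values <- 10^log10_val

  # hard left-censoring at a global intensity quantile
  if (config$censor_quantile > 0) {
    threshold <- stats::quantile(values, config$censor_quantile, names = FALSE)
    values[values < threshold] <- NA_real_
  } else {
    threshold <- 0
  }

  quant <- tibble::tibble(
    compound_id = rep(compounds$compound_id, times = n_samples),
    site = rep(compounds$site, times = n_samples),
    composition = rep(compounds$composition, times = n_samples),
    sample_id = rep(sample_ids, each = n_comp),
    area = as.vector(values)
  )

  # heavy standard: fixed base abundances x technical factor x noise
  heavy_base <- seq(6.8, by = -0.4, length.out = config$n_heavy)
  heavy_ids <- sprintf("HEAVY_%02d", seq_len(config$n_heavy))
  heavy_log10 <- matrix(heavy_base, config$n_heavy, n_samples) +
    matrix(t_factor_log10, config$n_heavy, n_samples, byrow = TRUE) +
    matrix(stats::rnorm(config$n_heavy * n_samples, 0, tech_sd), config$n_heavy)
  heavy <- tibble::tibble(
    peptide_id = rep(heavy_ids, times = n_samples),
    sample_id = rep(sample_ids, each = config$n_heavy),
    abundance = as.vector(10^heavy_log10)
  )

  meta <- tibble::tibble(sample_id = sample_ids, group = groups)
  meta <- inject_phenotype_structure(meta, config)
  meta <- inject_etiology(meta)
  if (!is.na(config$afp_auc)) meta <- inject_afp(meta, config, sigma = 0.5)

  truth <- list(
    compounds = compounds |>
      dplyr::select("compound_id", "site", "composition", "family", "antennae",
                    "bisecting", "fucosylation", "sialylation",
                    "baseline_log10", "delta_early", "delta_late",
                    "designed_auc_early", "designed_auc_late", "is_marker"),
    samples = tibble::tibble(sample_id = sample_ids, group = groups,
                             technical_factor = 10^t_factor_log10),
    censor_threshold = threshold,
    sigma_log10 = sigma,
    config = config
  )
  structure(list(quant = quant, heavy = heavy, meta = meta, truth = truth),
            class = "glyco_cohort")
}

#' Assign haptoglobin phenotypes to sample metadata
#'
#' Deterministic counts per group (`round(proportion * n)` for 1-1, 2-1 and
#' 2-2; the remainder is "unknown", mirroring the clinical cohort's
#' not-identified samples), assigned in randomized order within the group.
#'
#' @param meta Metadata tibble with `sample_id` and `group`.
#' @param config A [cohort_config()] (uses `phenotype_props`).
#' @return `meta` with a `phenotype` column.
#' @export
inject_phenotype_structure <- function(meta, config = cohort_config()) {
  props <- config$phenotype_props
  meta$phenotype <- NA_character_
  for (g in unique(meta$group)) {
    idx <- which(meta$group == g)
    p <- props[[g]]
    if (is.null(p)) p <- c("1-1" = 0, "2-1" = 0, "2-2" = 0)
    counts <- round(p * length(idx))
    if (sum(counts) > length(idx)) {
      rlang::abort("phenotype proportions produce more samples than the group",
                   class = "glyco_config_error")
    }
    labels <- c(rep(names(counts), counts),
                rep("unknown", length(idx) - sum(counts)))
    meta$phenotype[idx] <- sample(labels)
  }
  meta
}

# Etiology flags and cirrhosis status drawn from per-group probabilities
# approximating the clinical cohort's marginals (illustrative, not a
# reproduction of the patient table's combination categories).
inject_etiology <- function(meta) {
  p_hbv <- c(control = 0.74, early = 0.40, late = 0.47)
  p_hcv <- c(control = 0.23, early = 0.34, late = 0.25)
  p_ash <- c(control = 0.04, early = 0.22, late = 0.19)
  p_nash <- c(control = 0.00, early = 0.02, late = 0.06)
  p_cirr <- c(control = 0.50, early = 0.80, late = 0.81)
  n <- nrow(meta)
  draw <- function(p) stats::runif(n) < p[meta$group]
  meta$hbv <- draw(p_hbv)
  meta$hcv <- draw(p_hcv)
  meta$ash <- draw(p_ash)
  meta$nash <- draw(p_nash)
  meta$cirrhosis <- draw(p_cirr)
  meta
}

# Simulated AFP benchmark: lognormal with a designed AUC for HCC vs control,
# ~5% missing at random.
inject_afp <- function(meta, config, sigma = 0.5) {
  delta <- stats::qnorm(config$afp_auc) * sigma * sqrt(2)
  shift <- ifelse(meta$group == "control", 0, delta)
  afp <- 10^(1 + shift + stats::rnorm(nrow(meta), 0, sigma))
  afp[stats::runif(nrow(meta)) < 0.05] <- NA_real_
  meta$afp <- afp
  meta
}

#' @export
print.glyco_cohort <- function(x, ...) {
  cat("Synthetic glycopeptide cohort\n")
  cat("  samples:   ", nrow(x$meta), " (",
      paste(table(x$meta$group)[c("control", "early", "late")],
            c("control", "early", "late"), collapse = ", "), ")\n", sep = "")
  cat("  compounds: ", nrow(x$truth$compounds), " across ",
      length(unique(x$truth$compounds$site)), " glycosites\n", sep = "")
  cat("  missing:   ", sprintf("%.1f%%", 100 * mean(is.na(x$quant$area))),
      " of XIC areas (left-censored)\n", sep = "")
  cat("  markers:   ", sum(x$truth$compounds$is_marker),
      " with designed non-null effects\n", sep = "")
  invisible(x)
}

#' Write a cohort's tables to a directory
#'
#' Emits the exact tabular formats the readers accept: `quant.tsv`,
#' `heavy.tsv`, `meta.tsv`, plus the `truth_compounds.tsv` /
#' `truth_samples.tsv` ledger.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_quant_matrix(cohort$quant, file.path(dir, "quant.tsv"))
  write_heavy_table(cohort$heavy, file.path(dir, "heavy.tsv"))
  write_sample_meta(cohort$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(cohort$truth$compounds, file.path(dir, "truth_compounds.tsv"))
  readr::write_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"))
  invisible(dir)
}
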