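# Shared fixtures, built in code.

# Minimal long quant table: 3 compounds x 4 samples with one missing cell.
toy_quant <- function() {
  tidyr::expand_grid(
    tibble::tibble(
      compound_id = c("N184:HexNAc(4)Hex(5)Fuc(1)", "N184:HexNAc(4)Hex(5)NeuAc(2)",
                      "N207:HexNAc(2)Hex(8)"),
      site = c("N184", "N184", "N207"),
      composition = c("HexNAc(4)Hex(5)Fuc(1)", "HexNAc(4)Hex(5)NeuAc(2)",
                      "HexNAc(2)Hex(8)")
    ),
    sample_id = paste0("S", 1:4)
  ) |>
    dplyr::mutate(area = c(10, 20, 30, 40,
                           100, 200, 300, 400,
                           5, NA, 2, 8))
}

# Heavy table with constant per-sample totals (normalization no-op).
toy_heavy <- function(t_s = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1)) {
  tidyr::expand_grid(peptide_id = paste0("H", 1:3),
                     sample_id = names(t_s)) |>
    dplyr::mutate(abundance = unname(t_s[sample_id]) / 3)
}

# Small, fast generator configuration for pipeline tests.
small_config <- function(...) {
  cohort_config(
    n_control = 12L, n_early = 12L, n_late = 6L,
    site_glycoforms = c(N184 = 8L, N207 = 8L, N211 = 6L, N241 = 8L),
    ...
  )
}

null_effect_map <- function() {
  dplyr::mutate(default_effect_map(), early = 0.5, late = 0.5)
}

# Brute-force AUC oracle: explicit pair counting.
auc_pairs <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

# Exact two-sided Wilcoxon p by full enumeration of group assignments
# (no ties assumed).
wilcoxon_permutation_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  m <- n1 * n2 / 2
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(i) sum(rank(pooled)[i]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - m) >= abs(u_obs - m))
}
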