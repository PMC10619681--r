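# Glycan composition algebra: parsing/formatting of the
# HexNAc(x)Hex(x)Fuc(x)NeuAc(x) notation, monoisotopic mass arithmetic,
# family classification, and isobaric-ambiguity enumeration.

MONOMER_ORDER <- c("hexnac", "hex", "fuc", "neuac")
MONOMER_DISPLAY <- c(hexnac = "HexNAc", hex = "Hex", fuc = "Fuc", neuac = "NeuAc")

#' Parse glycan composition notation
#'
#' Parses compositions written in the conventional
#' `HexNAc(x)Hex(x)Fuc(x)NeuAc(x)` notation into monomer counts. Monomer
#' tokens may appear in any order and omitted monomers count zero. The
#' returned `composition` column holds the canonical re-formatted string
#' (fixed order HexNAc, Hex, Fuc, NeuAc; zero counts omitted), so
#' `parse_glycan()` is a canonicalizing idempotent map on strings.
#'
#' @param text Character vector of composition strings.
#' @return A tibble with one row per input: `composition` (canonical string),
#'   `hexnac`, `hex`, `fuc`, `neuac` (integer counts).
#' @examples
#' parse_glycan("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)")
#' parse_glycan("NeuAc(2)Hex(5)HexNAc(4)") # order-insensitive
#' @export
parse_glycan <- function(text) {
  stopifnot(is.character(text))
  counts <- purrr::map(text, parse_glycan_one)
  out <- dplyr::bind_rows(counts)
  out$composition <- format_glycan(out$hexnac, out$hex, out$fuc, out$neuac)
  dplyr::relocate(out, "composition")
}

parse_glycan_one <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    rlang::abort("empty glycan composition string", class = "glyco_parse_error")
  }
  x <- trimws(x)
  m <- gregexpr("([A-Za-z]+)\\((-?[0-9]+(?:\\.[0-9]+)?)\\)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, gregexpr("([A-Za-z]+)\\((-?[0-9]+(?:\\.[0-9]+)?)\\)", x, perl = TRUE))[[1]]
  consumed <- if (m[1] == -1) 0L else sum(attr(m, "match.length"))
  if (consumed != nchar(x)) {
    rlang::abort(
      paste0("cannot parse glycan composition: '", x, "'"),
      class = "glyco_parse_error"
    )
  }
  names_raw <- sub("\\(.*$", "", tokens)
  counts_raw <- sub("^.*\\(", "", sub("\\)$", "", tokens))
  keys <- MONOMER_ORDER[match(tolower(names_raw), tolower(MONOMER_DISPLAY))]
  if (anyNA(keys)) {
    bad <- names_raw[is.na(keys)][1]
    rlang::abort(
      paste0("unknown monosaccharide token '", bad, "' in '", x, "'"),
      class = "glyco_parse_error"
    )
  }
  if (anyDuplicated(keys)) {
    rlang::abort(
      paste0("duplicated monosaccharide token in '", x, "'"),
      class = "glyco_parse_error"
    )
  }
  counts_num <- suppressWarnings(as.numeric(counts_raw))
  if (anyNA(counts_num) || any(counts_num < 0) || any(counts_num != floor(counts_num))) {
    rlang::abort(
      paste0("monomer counts must be non-negative integers in '", x, "'"),
      class = "glyco_parse_error"
    )
  }
  full <- stats::setNames(integer(4), MONOMER_ORDER)
  full[keys] <- as.integer(counts_num)
  if (sum(full) == 0L) {
    rlang::abort(
      paste0("glycan composition has no monomers: '", x, "'"),
      class = "glyco_parse_error"
    )
  }
  tibble::as_tibble(as.list(full))
}

#' Format monomer counts as canonical composition notation
#'
#' @param hexnac,hex,fuc,neuac Non-negative integer count vectors (recycled).
#' @return Character vector in canonical `HexNAc(x)Hex(x)Fuc(x)NeuAc(x)` order
#'   with zero-count monomers omitted.
#' @examples
#' format_glycan(4, 5, 0, 2)
#' @export
format_glycan <- function(hexnac, hex, fuc, neuac) {
  counts <- cbind(hexnac = hexnac, hex = hex, fuc = fuc, neuac = neuac)
  apply(counts, 1L, function(cc) {
    keep <- cc > 0
    paste0(MONOMER_DISPLAY[MONOMER_ORDER][keep], "(", cc[keep], ")", collapse = "")
  })
}

# Resolve a composition argument (character notation or a data frame with
# count columns) into an integer count matrix with the canonical 4 columns.
composition_counts <- function(composition) {
  if (is.character(composition)) {
    parsed <- parse_glycan(composition)
    as.matrix(parsed[, MONOMER_ORDER])
  } else if (is.data.frame(composition)) {
    missing_cols <- setdiff(MONOMER_ORDER, names(composition))
    if (length(missing_cols)) {
      rlang::abort(paste0(
        "composition data frame lacks count column(s): ",
        paste(missing_cols, collapse = ", ")
      ))
    }
    as.matrix(composition[, MONOMER_ORDER])
  } else {
    rlang::abort("composition must be a character vector or a data frame of counts")
  }
}

#' Monoisotopic glycan mass
#'
#' Sum of monoisotopic residue masses over the composition's monomer counts.
#' Residue masses are dehydrated, so this is the mass the glycan adds to a
#' peptide; the mass of an all-zero composition is exactly 0. Mass is additive
#' over compositions.
#'
#' @param composition Character vector of composition strings, or a data frame
#'   with columns `hexnac`, `hex`, `fuc`, `neuac`.
#' @return Numeric vector of masses in Da.
#' @examples
#' glycan_mass("HexNAc(2)Hex(3)")
#' glycan_mass("Fuc(2)") - glycan_mass("NeuAc(1)") # the 1.02 Da ambiguity gap
#' @export
glycan_mass <- function(composition) {
  counts <- composition_counts(composition)
  drop(counts %*% monosaccharide_masses()[MONOMER_ORDER])
}

#' Oxonium (B-type) fragment ion m/z
#'
#' m/z of the singly protonated B-type glycan fragment:
#' `glycan_mass(fragment) - water_losses * water + proton`. Residue masses
#' already exclude the glycosidic water, so zero losses gives the intact
#' B ion (e.g. the core-fucose diagnostic Hex+HexNAc+Fuc at m/z 512.20).
#'
#' @param fragment Composition of the fragment (string or count data frame).
#' @param water_losses Number of additional water losses (default 0).
#' @return Numeric m/z vector.
#' @examples
#' oxonium_mz("Hex(1)HexNAc(1)Fuc(1)")       # 512.20, core fucose
#' oxonium_mz("NeuAc(1)", water_losses = 1)  # 274.09, sialic acid
#' @export
oxonium_mz <- function(fragment, water_losses = 0) {
  stopifnot(all(water_losses >= 0))
  m <- glycan_mass(fragment)
  if (any(m <= 0)) {
    rlang::abort("oxonium fragment must be non-empty", class = "glyco_domain_error")
  }
  mz <- m - water_losses * mass_water() + mass_proton()
  if (any(mz <= 0)) {
    rlang::abort("oxonium m/z must be positive", class = "glyco_domain_error")
  }
  mz
}

#' Classify glycan compositions into feature categories
#'
#' Derives the glycan family and the features used for aggregation from the
#' monomer counts alone (no linkage information):
#' * family `high-mannose`: HexNAc 2, Hex 5-9, no Fuc/NeuAc (Man5-Man9);
#' * family `complex`: HexNAc >= 4; `hybrid`: HexNAc 3 with Hex >= 5;
#'   everything else `paucimannose/other`;
#' * antennae (complex only): `min(hexnac - 2, hex - 3)`, capped at 4 -- a
#'   count heuristic that assumes galactosylated antennae;
#' * bisecting flag (complex only): `hexnac - 2 > hex - 3`, i.e. a HexNAc
#'   unaccounted for by galactosylated branches;
#' * fucosylation / sialylation degree: the Fuc and NeuAc counts.
#'
#' The antennarity heuristic mislabels agalactosylated antennae, which is why
#' the bisecting flag is reported as a heuristic rather than a structure call.
#'
#' @param data A data frame with a composition column, or a character vector
#'   of composition strings.
#' @param composition Column holding composition strings (tidy-eval; default
#'   `composition`). Ignored when `data` is a character vector.
#' @return The input with classification columns added (`family`, `antennae`,
#'   `bisecting`, `fucosylation`, `sialylation`), or a tibble when `data` is a
#'   character vector.
#' @examples
#' classify_glycans(c("HexNAc(2)Hex(8)", "HexNAc(4)Hex(5)NeuAc(2)",
#'                    "HexNAc(5)Hex(5)NeuAc(1)"))
#' @export
classify_glycans <- function(data, composition = composition) {
  if (is.character(data)) {
    data <- tibble::tibble(composition = data)
    comp_str <- data$composition
  } else {
    comp_str <- dplyr::pull(data, {{ composition }})
  }
  counts <- composition_counts(comp_str)
  hexnac <- counts[, "hexnac"]; hex <- counts[, "hex"]
  fuc <- counts[, "fuc"]; neuac <- counts[, "neuac"]

  family <- dplyr::case_when(
    hexnac == 2 & hex >= 5 & hex <= 9 & fuc == 0 & neuac == 0 ~ "high-mannose",
    hexnac >= 4 ~ "complex",
    hexnac == 3 & hex >= 5 ~ "hybrid",
    TRUE ~ "paucimannose/other"
  )
  is_complex <- family == "complex"
  antennae <- ifelse(is_complex, pmax(0L, pmin(4L, pmin(hexnac - 2L, hex - 3L))), 0L)
  bisecting <- is_complex & (hexnac - 2L > hex - 3L)

  dplyr::mutate(
    data,
    family = family,
    antennae = as.integer(antennae),
    bisecting = bisecting,
    fucosylation = as.integer(fuc),
    sialylation = as.integer(neuac)
  )
}

#' Enumerate isobaric composition alternatives
#'
#' Finds compositions whose mass differs from the query's by an integer number
#' of C13 isotope spacings within a ppm tolerance at the glycopeptide's mass
#' -- the situation in which an MS1 match cannot be restricted to one glycan
#' (classically 2 Fuc vs 1 NeuAc, a 1.02 Da gap absorbed by a one-isotope
#' monoisotopic-peak misassignment). Candidates are generated by perturbing
#' each monomer count by up to `max_step` with total L1 change up to
#' `max_total`, which covers the Fuc/NeuAc swap and single-monomer slips.
#'
#' @param query Composition string (single).
#' @param reference_mass Neutral mass (Da) of the full glycopeptide at which
#'   the ppm tolerance is evaluated.
#' @param tolerance_ppm Relative match tolerance (default 20 ppm, the usual
#'   MS2 tolerance).
#' @param isotope_errors Integer set of allowed monoisotopic-peak errors
#'   (default -1:1).
#' @param max_step Maximum change of any single monomer count (default 2).
#' @param max_total Maximum total L1 change over all counts (default 4).
#' @return A tibble of alternatives (`composition`, counts, `delta_da`,
#'   `isotope_k`, `residual_da`), always containing the query itself with
#'   delta 0 and isotope 0, ordered by absolute delta.
#' @examples
#' isobaric_alternatives("HexNAc(6)Hex(7)Fuc(3)NeuAc(3)", reference_mass = 4000)
#' @export
isobaric_alternatives <- function(query, reference_mass, tolerance_ppm = 20,
                                  isotope_errors = -1:1,
                                  max_step = 2L, max_total = 4L) {
  stopifnot(length(query) == 1L, tolerance_ppm > 0, reference_mass > 0)
  if (!all(isotope_errors %in% -2:2)) {
    rlang::abort("isotope_errors must be a subset of -2..2")
  }
  q <- composition_counts(query)[1L, ]
  steps <- seq(-max_step, max_step)
  grid <- expand.grid(hexnac = steps, hex = steps, fuc = steps, neuac = steps)
  grid <- grid[rowSums(abs(grid)) <= max_total, , drop = FALSE]
  cand <- sweep(as.matrix(grid), 2L, -q[MONOMER_ORDER])  # q + delta
  ok <- apply(cand >= 0L, 1L, all) & rowSums(cand) > 0L
  cand <- cand[ok, , drop = FALSE]
  delta <- unname(drop(as.matrix(grid[ok, , drop = FALSE]) %*%
                         monosaccharide_masses()[MONOMER_ORDER]))

  tol_da <- tolerance_ppm * reference_mass * 1e-6
  # Best isotope assignment per candidate: the k minimizing |delta - k*spacing|
  resid <- vapply(delta, function(d) {
    min(abs(d - isotope_errors * mass_isotope_spacing()))
  }, numeric(1))
  k_best <- vapply(delta, function(d) {
    isotope_errors[which.min(abs(d - isotope_errors * mass_isotope_spacing()))]
  }, numeric(1))

  is_query <- rowSums(abs(as.matrix(grid[ok, , drop = FALSE]))) == 0L
  keep <- is_query | resid <= tol_da
  cand <- cand[keep, , drop = FALSE]
  out <- tibble::tibble(
    composition = format_glycan(cand[, "hexnac"], cand[, "hex"],
                                cand[, "fuc"], cand[, "neuac"]),
    hexnac = as.integer(cand[, "hexnac"]), hex = as.integer(cand[, "hex"]),
    fuc = as.integer(cand[, "fuc"]), neuac = as.integer(cand[, "neuac"]),
    delta_da = delta[keep],
    isotope_k = as.integer(ifelse(is_query[keep], 0L, k_best[keep])),
    residual_da = ifelse(is_query[keep], 0, resid[keep])
  )
  out$delta_da[out$composition == format_glycan(q["hexnac"], q["hex"], q["fuc"], q["neuac"])] <- 0
  dplyr::arrange(out, abs(.data$delta_da), .data$composition)
}

#' Check a peak list for fucose and sialic-acid diagnostic ions
#'
#' Screens MS2 peaks for the oxonium ions that distinguish fucosylated and
#' sialylated glycopeptides: the core-fucose trisaccharide B ion
#' (Hex+HexNAc+Fuc, m/z 512.20), the NeuAc oxonium pair (m/z 292.10 and its
#' water loss 274.09), and -- when the peptide mass is supplied -- the
#' outer-arm fucose Y ion peptide+2HexNAc+Fuc. Presence requires at least one
#' peak within the ppm tolerance.
#'
#' @param peaks Data frame with columns `mz` and (optionally) `intensity`;
#'   may be empty.
#' @param tolerance_ppm Match tolerance (default 20 ppm).
#' @param peptide_mass Optional neutral peptide mass (Da) enabling the
#'   antennary-fucose check.
#' @return A list of class `diagnostic_evidence`: logical fields
#'   `core_fucose`, `sialic_acid`, `antennary_fucose` (NA when no peptide
#'   mass was given) and a `matches` tibble (`ion`, `target_mz`,
#'   `observed_mz`, `ppm_error`).
#' @examples
#' diagnostic_ion_check(data.frame(mz = c(512.197, 274.092), intensity = 1))
#' @export
diagnostic_ion_check <- function(peaks, tolerance_ppm = 20, peptide_mass = NULL) {
  stopifnot(tolerance_ppm > 0)
  if (is.null(peaks) || nrow(as.data.frame(peaks)) == 0L) {
    mz_obs <- numeric(0)
  } else {
    peaks <- as.data.frame(peaks)
    stopifnot("mz" %in% names(peaks))
    mz_obs <- peaks$mz
  }
  targets <- tibble::tibble(
    ion = c("core_fucose", "sialic_acid", "sialic_acid"),
    target_mz = c(
      oxonium_mz("Hex(1)HexNAc(1)Fuc(1)"),
      oxonium_mz("NeuAc(1)"),
      oxonium_mz("NeuAc(1)", water_losses = 1)
    )
  )
  if (!is.null(peptide_mass)) {
    targets <- dplyr::bind_rows(targets, tibble::tibble(
      ion = "antennary_fucose",
      target_mz = peptide_mass + 2 * monosaccharide_masses()[["hexnac"]] +
        monosaccharide_masses()[["fuc"]] + mass_proton()
    ))
  }
  matches <- purrr::pmap_dfr(targets, function(ion, target_mz) {
    ppm <- (mz_obs - target_mz) / target_mz * 1e6
    hit <- abs(ppm) <= tolerance_ppm
    tibble::tibble(
      ion = ion, target_mz = target_mz,
      observed_mz = mz_obs[hit], ppm_error = ppm[hit]
    )
  })
  evidence <- list(
    core_fucose = "core_fucose" %in% matches$ion,
    sialic_acid = "sialic_acid" %in% matches$ion,
    antennary_fucose = if (is.null(peptide_mass)) NA else "antennary_fucose" %in% matches$ion,
    matches = matches
  )
  structure(evidence, class = "diagnostic_evidence")
}

#' @export
print.diagnostic_evidence <- function(x, ...) {
  cat("Diagnostic ion evidence\n")
  cat("  core fucose:      ", if (x$core_fucose) "present" else "absent", "\n")
  cat("  sialic acid:      ", if (x$sialic_acid) "present" else "absent", "\n")
  cat("  antennary fucose: ",
      if (is.na(x$antennary_fucose)) "not evaluated (no peptide mass)"
      else if (x$antennary_fucose) "present" else "absent", "\n")
  if (nrow(x$matches)) {
    cat("  matched peaks:\n")
    print(x$matches, ...)
  }
  invisible(x)
}
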