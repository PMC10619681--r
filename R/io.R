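# Tabular text I/O. All files are UTF-8 TSV with a header row; lines
# starting with "#" are comments (used for column-unit notes in reports).
# Missing quantitative values are encoded as empty fields or "NA".

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) {
    rlang::abort(paste0(what, " file not found: ", path),
                 class = "glyco_config_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  na = c("", "NA"), progress = FALSE)
}

#' Read a glycopeptide quantification matrix
#'
#' Wide layout: columns `site`, `composition`, then one column per sample
#' holding XIC areas (blank/NA = not identified). Returns the long table the
#' quant operations use; compositions are canonicalized and
#' `compound_id = site:composition` is derived. Duplicate compound rows or
#' negative areas are schema errors reported with row numbers.
#'
#' @param path TSV path.
#' @return Long tibble (`compound_id`, `site`, `composition`, `sample_id`,
#'   `area`).
#' @export
read_quant_matrix <- function(path) {
  wide <- read_tsv_strict(path, "quant matrix")
  need <- c("site", "composition")
  if (!all(need %in% names(wide))) {
    rlang::abort("quant matrix needs 'site' and 'composition' columns",
                 class = "glyco_schema_error")
  }
  wide$composition <- parse_glycan(wide$composition)$composition
  key <- paste(wide$site, wide$composition)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicate glyco-compound at data row(s): ",
                        paste(which(duplicated(key)), collapse = ", ")),
                 class = "glyco_schema_error")
  }
  long <- tidyr::pivot_longer(wide, cols = -dplyr::all_of(need),
                              names_to = "sample_id", values_to = "area")
  if (any(long$area < 0, na.rm = TRUE)) {
    rlang::abort("negative XIC area in quant matrix", class = "glyco_schema_error")
  }
  long$compound_id <- paste0(long$site, ":", long$composition)
  dplyr::relocate(long, "compound_id")
}

#' Write a long quant table as a wide TSV matrix
#'
#' @param quant Long quant tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_quant_matrix <- function(quant, path) {
  wide <- quant |>
    dplyr::select("site", "composition", "sample_id", "area") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "area")
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

#' Read / write the heavy internal-standard table
#'
#' Wide layout: `peptide_id` then one abundance column per sample.
#'
#' @param path TSV path.
#' @return Long tibble (`peptide_id`, `sample_id`, `abundance`).
#' @export
read_heavy_table <- function(path) {
  wide <- read_tsv_strict(path, "heavy-standard table")
  if (!"peptide_id" %in% names(wide)) {
    rlang::abort("heavy table needs a 'peptide_id' column",
                 class = "glyco_schema_error")
  }
  long <- tidyr::pivot_longer(wide, cols = -"peptide_id",
                              names_to = "sample_id", values_to = "abundance")
  if (any(long$abundance <= 0, na.rm = TRUE)) {
    rlang::abort("heavy-standard abundances must be positive",
                 class = "glyco_schema_error")
  }
  long
}

#' @rdname read_heavy_table
#' @param heavy Long heavy tibble.
#' @export
write_heavy_table <- function(heavy, path) {
  wide <- tidyr::pivot_wider(heavy, names_from = "sample_id",
                             values_from = "abundance")
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `group` (control/early/late), `phenotype`
#' (1-1/2-1/2-2/unknown), logical etiology flags (`hbv`, `hcv`, `ash`,
#' `nash`), logical `cirrhosis`, optional numeric `afp`. `group` must be
#' present for every sample.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- read_tsv_strict(path, "sample metadata")
  need <- c("sample_id", "group")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    rlang::abort(paste0("sample metadata lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "glyco_schema_error")
  }
  bad <- which(is.na(meta$group) | !meta$group %in% c("control", "early", "late"))
  if (length(bad)) {
    rlang::abort(paste0("invalid group at metadata row(s): ",
                        paste(utils::head(bad, 5L), collapse = ", ")),
                 class = "glyco_schema_error")
  }
  meta
}

#' @rdname read_sample_meta
#' @param meta Metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path, na = "")
  invisible(path)
}

#' Read a glycan composition catalog
#'
#' Tabular text with columns `site_id`, `composition_string` and an optional
#' `charge`; header row required. Compositions are validated and
#' canonicalized on read.
#'
#' @param path TSV path.
#' @return Tibble (`site_id`, `composition`, optional `charge`).
#' @export
read_catalog <- function(path) {
  cat_tbl <- read_tsv_strict(path, "composition catalog")
  need <- c("site_id", "composition_string")
  if (!all(need %in% names(cat_tbl))) {
    rlang::abort("catalog needs 'site_id' and 'composition_string' columns",
                 class = "glyco_schema_error")
  }
  out <- tibble::tibble(
    site_id = cat_tbl$site_id,
    composition = parse_glycan(cat_tbl$composition_string)$composition
  )
  if ("charge" %in% names(cat_tbl)) out$charge <- cat_tbl$charge
  out
}

# Report writer: TSV preceded by "# " comment lines (units, decisions).
write_report_tsv <- function(data, path, comments = character(0)) {
  body <- readr::format_tsv(data, na = "")
  writeLines(c(if (length(comments)) paste0("# ", comments),
               strsplit(body, "\n", fixed = TRUE)[[1]]),
             path, useBytes = TRUE)
  invisible(path)
}
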