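# In-silico proteolysis (trypsin + Glu-C), N-glycosylation sequon discovery
# and theoretical glycopeptide m/z. Coordinates are 0-based half-open
# internally; user-facing labels are 1-based.

VALID_AA <- names(aa_residue_masses)

#' Read a protein sequence from FASTA
#'
#' Reads a single- or multi-record FASTA and returns one record (the first,
#' unless `id` selects another by accession prefix match). The sequence must
#' use the 20 canonical one-letter residues.
#'
#' @param path Path to a FASTA file.
#' @param id Optional accession (matched against the record names).
#' @return A tibble with columns `accession` and `sequence`.
#' @export
read_protein_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path), class = "glyco_config_error")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    rlang::abort("FASTA file contains no records", class = "glyco_config_error")
  }
  idx <- 1L
  if (!is.null(id)) {
    hit <- grep(id, names(set), fixed = TRUE)
    if (!length(hit)) {
      rlang::abort(paste0("no FASTA record matching id '", id, "'"),
                   class = "glyco_config_error")
    }
    idx <- hit[1L]
  }
  seq <- toupper(as.character(set[[idx]]))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), VALID_AA)
  if (length(bad)) {
    rlang::abort(
      paste0("non-canonical residue(s) in sequence: ", paste(bad, collapse = ", ")),
      class = "glyco_config_error"
    )
  }
  tibble::tibble(accession = names(set)[idx], sequence = seq)
}

#' Find N-glycosylation sequons
#'
#' Scans a protein sequence for the N-X-S/T sequon (X != P). Labels use
#' 1-based numbering of the supplied sequence plus `numbering_offset`, so a
#' mature-chain sequence can still be labelled in precursor coordinates.
#'
#' @param sequence Amino-acid string (one-letter uppercase).
#' @param numbering_offset Integer added to positions in labels (default 0).
#' @return A tibble with `position` (1-based N index), `sequon` (3 residues)
#'   and `label` (e.g. "N184"), ordered by position.
#' @examples
#' find_sequons("AANHSA")
#' @export
find_sequons <- function(sequence, numbering_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  m <- gregexpr("N(?=[^P][ST])", sequence, perl = TRUE)[[1]]
  pos <- if (m[1] == -1) integer(0) else as.integer(m)
  if (!length(pos)) {
    return(tibble::tibble(position = integer(0), sequon = character(0),
                          label = character(0)))
  }
  tibble::tibble(
    position = pos,
    sequon = substring(sequence, pos, pos + 2L),
    label = paste0("N", pos + numbering_offset)
  )
}

#' Protease cleavage rules
#'
#' Returns the built-in cleavage rule set. Trypsin cleaves after K/R unless
#' the next residue is P; Glu-C cleaves after E by default (ammonium
#' bicarbonate buffers can extend its specificity to D, selectable via
#' `gluc_specificity`).
#'
#' @param enzymes Character vector among `"trypsin"`, `"glu-c"`.
#' @param gluc_specificity `"E"` (default) or `"DE"`.
#' @return A list of rules, each with `name`, `after` and `not_before`.
#' @export
cleavage_rules <- function(enzymes = c("trypsin", "glu-c"),
                           gluc_specificity = c("E", "DE")) {
  enzymes <- match.arg(enzymes, several.ok = TRUE)
  gluc_specificity <- match.arg(gluc_specificity)
  rules <- list(
    "trypsin" = list(name = "trypsin", after = c("K", "R"), not_before = "P"),
    "glu-c" = list(
      name = "glu-c",
      after = strsplit(gluc_specificity, "")[[1]],
      not_before = character(0)
    )
  )
  rules[enzymes]
}

#' Digest a protein in silico
#'
#' Fully specific digestion by the union of the supplied rules' cut sites,
#' returning every peptide with at most `max_missed` internal (missed)
#' cleavage sites. The zero-missed peptides concatenate back to the protein.
#'
#' @param sequence Amino-acid string.
#' @param rules A rule list from [cleavage_rules()].
#' @param max_missed Maximum missed cleavages (default 2, the usual search
#'   setting).
#' @return A tibble with `peptide`, `start`, `end` (0-based half-open) and
#'   `missed`, ordered by start then length.
#' @examples
#' digest_protein("AKAE", max_missed = 0)
#' @export
digest_protein <- function(sequence, rules = cleavage_rules(), max_missed = 2L) {
  stopifnot(max_missed >= 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) {
    return(tibble::tibble(peptide = character(0), start = integer(0),
                          end = integer(0), missed = integer(0)))
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% VALID_AA)
  if (length(bad)) {
    rlang::abort(paste0("unknown residue '", res[bad[1]], "' at position ", bad[1]),
                 class = "glyco_config_error")
  }
  cut_after <- rep(FALSE, n)
  for (rule in rules) {
    hits <- res %in% rule$after
    if (length(rule$not_before)) {
      nxt <- c(res[-1], "")  # residue following each position
      hits <- hits & !nxt %in% rule$not_before
    }
    cut_after <- cut_after | hits
  }
  cut_after[n] <- FALSE  # the C-terminus is a boundary, not an internal cut
  bounds <- c(0L, which(cut_after), n)
  nb <- length(bounds)
  out <- purrr::map_dfr(seq_len(nb - 1L), function(i) {
    j_max <- min(nb, i + 1L + max_missed)
    j <- seq(i + 1L, j_max)
    tibble::tibble(
      start = bounds[i],
      end = bounds[j],
      missed = j - i - 1L
    )
  })
  out$peptide <- substring(sequence, out$start + 1L, out$end)
  dplyr::arrange(
    dplyr::relocate(out, "peptide"),
    .data$start, .data$end
  )
}

#' Theoretical glycopeptide m/z
#'
#' `(sum of residue masses + water + nCys * cys_mod + glycan mass +
#' charge * proton) / charge`. Cysteines carry the fixed carbamidomethyl
#' modification by default; methionine oxidation can be added as
#' `extra_mod_da` when needed.
#'
#' @param peptide Character vector of peptide sequences.
#' @param glycan Composition string(s) (recycled), or `NULL` for the bare
#'   peptide.
#' @param charge Positive integer charge state(s).
#' @param cys_mod Fixed cysteine modification mass (default carbamidomethyl,
#'   57.02146 Da).
#' @param extra_mod_da Additional neutral modification mass (default 0).
#' @return Numeric m/z vector.
#' @examples
#' glycopeptide_mz("AK", "HexNAc(2)Hex(3)", charge = 2)
#' @export
glycopeptide_mz <- function(peptide, glycan = NULL, charge = 1L,
                            cys_mod = CYS_CARBAMIDOMETHYL, extra_mod_da = 0) {
  stopifnot(all(charge >= 1))
  pep_mass <- vapply(peptide, peptide_neutral_mass, numeric(1), cys_mod = cys_mod,
                     USE.NAMES = FALSE)
  gly_mass <- if (is.null(glycan)) 0 else glycan_mass(glycan)
  (pep_mass + gly_mass + extra_mod_da + charge * mass_proton()) / charge
}

peptide_neutral_mass <- function(peptide, cys_mod = CYS_CARBAMIDOMETHYL) {
  res <- strsplit(toupper(peptide), "")[[1]]
  bad <- which(!res %in% VALID_AA)
  if (length(bad)) {
    rlang::abort(paste0("unknown residue '", res[bad[1]], "' at position ", bad[1]),
                 class = "glyco_config_error")
  }
  sum(aa_residue_masses[res]) + mass_water() + sum(res == "C") * cys_mod
}

#' Map glycosites onto digest peptides
#'
#' A peptide covers a site when its half-open span contains the sequon's N.
#' Sites covered by no peptide are kept with NA peptide columns and flagged.
#'
#' @param sites Tibble from [find_sequons()].
#' @param peptides Tibble from [digest_protein()] over the same protein.
#' @return A tibble with one row per (site, covering peptide), columns
#'   `label`, `position`, `peptide`, `start`, `end`, `missed`, `covered`.
#' @export
map_sites_to_peptides <- function(sites, peptides) {
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    hit <- peptides[peptides$start <= p - 1L & p - 1L < peptides$end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      tibble::tibble(label = sites$label[i], position = p,
                     peptide = NA_character_, start = NA_integer_,
                     end = NA_integer_, missed = NA_integer_, covered = FALSE)
    } else {
      tibble::tibble(label = sites$label[i], position = p,
                     peptide = hit$peptide, start = hit$start,
                     end = hit$end, missed = hit$missed, covered = TRUE)
    }
  })
}
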