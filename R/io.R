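# FASTA and TSV input/output.

#' Read a protein FASTA file
#'
#' Accepts wrapped or unwrapped multi-record FASTA. Record ids are the
#' first whitespace-delimited token of each header. Stop characters (`*`)
#' are stripped with a warning, lowercase residues are uppercased with a
#' warning, duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "secretr_error_input")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      rlang::abort(paste0("malformed FASTA (", conditionMessage(e), "): ", path),
                   class = "secretr_error_input")
    }
  )
  if (length(set) == 0) {
    rlang::abort(paste0("empty FASTA file: ", path), class = "secretr_error_input")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]),
                 class = "secretr_error_input")
  }
  seqs <- as.character(set)
  if (any(grepl("*", seqs, fixed = TRUE))) {
    rlang::warn("stripping '*' stop characters from sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(grepl("[a-z]", seqs))) {
    rlang::warn("uppercasing lowercase residues")
    seqs <- toupper(seqs)
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write proteins to FASTA
#'
#' @param proteins A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a peptide-evidence table
#'
#' Tab-separated with header columns `protein_id`, `peptide_seq`,
#' `replicate`, `peptide_prob`, `protein_prob`, `is_unique`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of peptide records (possibly with zero rows).
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "secretr_error_input")
  }
  ev <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      peptide_seq = readr::col_character(),
      replicate = readr::col_character(),
      peptide_prob = readr::col_double(),
      protein_prob = readr::col_double(),
      is_unique = readr::col_logical()
    ),
    progress = FALSE
  )
  probs <- readr::problems(ev)
  if (nrow(probs) > 0) {
    rlang::abort(
      paste0("malformed evidence TSV at line ", probs$row[1] + 1, ": ", path),
      class = "secretr_error_input"
    )
  }
  if (nrow(ev) > 0) check_evidence(ev)
  ev
}

#' Write signal-peptide calls to TSV
#'
#' One row per input protein, in input order, with columns `protein_id`,
#' `sp_class`, `cleavage_after`, `sp_sequence`, `lipobox_motif`,
#' `n_charge`, `score`.
#'
#' @param calls An `sp_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  calls |>
    dplyr::select("protein_id", "sp_class", "cleavage_after",
                  "sp_sequence", "lipobox_motif", "n_charge", "score") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Write a frequency matrix to TSV
#'
#' Rows are aligned positions (signal side negative, mature side positive),
#' columns are residues plus the per-position non-gap count, ready for
#' standard logo-drawing tools.
#'
#' @param fm An [frequency_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_freq_matrix_tsv <- function(fm, path) {
  counts <- fm |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  wide <- fm |>
    dplyr::select("position", "residue", "freq") |>
    tidyr::pivot_wider(names_from = "residue", values_from = "freq") |>
    dplyr::left_join(counts, by = "position") |>
    dplyr::arrange(.data$position)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write a protein-quantification table to TSV
#'
#' @param quant A `protein_quant` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(quant, path) {
  rep_str <- purrr::map_chr(quant$rep_counts %||% list(), function(x) {
    paste(paste0(names(x), "=", x), collapse = ";")
  })
  out <- tibble::tibble(
    protein_id = quant$protein_id,
    n_observed = quant$n_observed,
    n_observable = quant$n_observable,
    pai = quant$pai,
    empai = quant$empai,
    accepted_replicate_counts = if (nrow(quant)) rep_str else character(0)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
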