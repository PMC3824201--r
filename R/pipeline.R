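# End-to-end orchestration: FASTA in -> calls, summary, composition,
# optional evidence filtering and emPAI ranking.

#' Percentage with one-decimal half-up rounding
#'
#' `100 * count / total`, rounded half-up to `digits` decimals, matching
#' the reporting convention used throughout the secretome summaries.
#'
#' @param count,total Numerator count and denominator total.
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_of(15, 145, digits = 0) # 10
#' @export
percent_of <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  x <- 100 * count / total
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Run the secretome pipeline
#'
#' Reads a proteome FASTA (or takes a protein tibble), classifies every
#' N-terminus, summarises the predicted secretome, builds the
#' cleavage-aligned frequency matrix over all predicted signal peptides,
#' and - when peptide evidence is supplied - filters identifications and
#' ranks accepted proteins by emPAI. Writes `calls.tsv`, `summary.json`,
#' `freq_matrix.tsv` and (with evidence) `quant.tsv` to `out_dir`.
#'
#' @param proteome Path to a FASTA file, or a data frame with `id` and
#'   `sequence`.
#' @param evidence Optional: path to an evidence TSV, or a peptide-record
#'   data frame.
#' @param out_dir Optional output directory (created if needed); when
#'   `NULL` nothing is written.
#' @param params A [sp_classifier_params()] object.
#' @param filter_params An [evidence_filter_params()] object.
#' @param dparams A [digest_params()] object.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return A list of class `secretome_report` with elements `calls`,
#'   `summary` (named list as written to `summary.json`), `freq_matrix`
#'   (or `NULL`), `quant` (or `NULL`), and `filter_summary` (or `NULL`).
#' @export
run_pipeline <- function(proteome, evidence = NULL, out_dir = NULL,
                         params = sp_classifier_params(),
                         filter_params = evidence_filter_params(),
                         dparams = digest_params(),
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  proteins <- if (is.character(proteome)) read_fasta(proteome) else
    tibble::as_tibble(proteome)
  say("classifying ", nrow(proteins), " proteins")
  calls <- classify_signal_peptides(proteins, params)
  secreted <- calls[calls$sp_class != "NONE", ]

  counts <- as.list(table(factor(calls$sp_class, levels = SP_CLASSES)))
  counts <- lapply(counts, as.integer)
  n <- nrow(calls)
  summary <- list(
    n_proteins = n,
    class_counts = counts,
    class_percent = lapply(counts, percent_of, total = n),
    n_secreted = nrow(secreted),
    pct_secreted = percent_of(nrow(secreted), n)
  )
  if (nrow(secreted) > 0) {
    ls <- length_summary(calls)
    summary$length_summary <- purrr::transpose(as.list(ls))
    part <- partition_by_charge(secreted)
    summary$n_secreted_positive_charge <- nrow(part$positive)
    summary$n_secreted_nonpositive_charge <- nrow(part$nonpositive)
  }

  fm <- NULL
  if (nrow(secreted) > 0 &&
      all(nchar(secreted$sequence) > secreted$cleavage_after)) {
    fm <- frequency_matrix(align_cleavage_windows(secreted))
  }

  quant <- NULL
  filt <- NULL
  if (!is.null(evidence)) {
    ev <- if (is.character(evidence)) read_evidence(evidence) else
      tibble::as_tibble(evidence)
    if (nrow(ev) == 0) {
      say("evidence table is empty; writing header-only quantification")
      quant <- quantify_proteins_empty()
    } else {
      filt <- filter_identifications(ev, filter_params)
      say(sum(filt$accepted), " of ", nrow(filt),
          " proteins pass the identification filter")
      quant <- quantify_proteins(ev, proteins, filter_params, dparams)
      accepted_ids <- quant$protein_id
      predicted_ids <- secreted$protein_id
      summary$n_detected <- length(accepted_ids)
      summary$n_detected_with_sp <- length(intersect(accepted_ids, predicted_ids))
      if (length(predicted_ids) > 0) {
        summary$detected_vs_predicted_pct <-
          percent_of(length(intersect(accepted_ids, predicted_ids)),
                     length(predicted_ids))
      }
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(fm)) {
      write_freq_matrix_tsv(fm, file.path(out_dir, "freq_matrix.tsv"))
    }
    if (!is.null(quant)) {
      write_quant_tsv(quant, file.path(out_dir, "quant.tsv"))
    }
    say("wrote outputs to ", out_dir)
  }

  structure(
    list(calls = calls, summary = summary, freq_matrix = fm,
         quant = quant, filter_summary = filt),
    class = "secretome_report"
  )
}

quantify_proteins_empty <- function() {
  out <- tibble::tibble(
    protein_id = character(), n_observed = integer(),
    n_observable = integer(), pai = numeric(), empai = numeric(),
    rep_counts = list()
  )
  class(out) <- c("protein_quant", class(out))
  out
}

#' @export
print.secretome_report <- function(x, ...) {
  s <- x$summary
  cat("Secretome report:", s$n_proteins, "proteins\n")
  cat("  SPase I:", s$class_counts$SPASE_I,
      " lipoprotein:", s$class_counts$LIPOPROTEIN,
      " class III:", s$class_counts$CLASS_III,
      " none:", s$class_counts$NONE, "\n")
  cat("  predicted secreted:", s$n_secreted,
      paste0("(", s$pct_secreted, "%)"), "\n")
  if (!is.null(s$n_detected)) {
    cat("  evidence-accepted proteins:", s$n_detected,
        "| with signal peptide:", s$n_detected_with_sp, "\n")
  }
  invisible(x)
}
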