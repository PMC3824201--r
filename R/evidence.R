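# Replicate/probability filtering of peptide evidence and emPAI ranking.

check_evidence <- function(evidence) {
  needed <- c("protein_id", "peptide_seq", "replicate",
              "peptide_prob", "protein_prob", "is_unique")
  missing <- setdiff(needed, names(evidence))
  if (length(missing)) {
    rlang::abort(paste0("evidence table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "secretr_error_input")
  }
  if (any(evidence$peptide_prob < 0 | evidence$peptide_prob > 1) ||
      any(evidence$protein_prob < 0 | evidence$protein_prob > 1)) {
    rlang::abort("probabilities must lie in [0, 1]", class = "secretr_error_input")
  }
  invisible(evidence)
}

#' Filter protein identifications by replicate evidence
#'
#' A protein is accepted when its protein-level probability reaches
#' `min_protein_prob` and it has at least `min_unique_per_replicate` unique
#' peptides with peptide probability at or above `min_peptide_prob` in each
#' of `required_replicates` replicates. Raising any threshold can only
#' shrink the accepted set.
#'
#' @param evidence A data frame with columns `protein_id`, `peptide_seq`,
#'   `replicate`, `peptide_prob`, `protein_prob`, `is_unique`.
#' @param params An [evidence_filter_params()] object.
#' @return A tibble with one row per protein: `protein_id`,
#'   `protein_prob`, per-replicate unique-peptide counts (`rep_counts`, a
#'   named-list column), `n_reps_passing` and `accepted`.
#' @export
filter_identifications <- function(evidence, params = evidence_filter_params()) {
  check_evidence(evidence)
  if (nrow(evidence) == 0) {
    rlang::abort("no peptide records supplied", class = "secretr_error_input")
  }
  reps <- sort(unique(as.character(evidence$replicate)))
  if (length(reps) < params$required_replicates) {
    rlang::abort(
      paste0("evidence covers ", length(reps), " replicate(s); ",
             params$required_replicates, " required"),
      class = "secretr_error_input"
    )
  }
  good <- evidence |>
    dplyr::filter(.data$is_unique, .data$peptide_prob >= params$min_peptide_prob) |>
    dplyr::distinct(.data$protein_id, .data$replicate, .data$peptide_seq) |>
    dplyr::count(.data$protein_id, .data$replicate, name = "n_unique")

  evidence |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(protein_prob = max(.data$protein_prob), .groups = "drop") |>
    dplyr::mutate(
      rep_counts = purrr::map(.data$protein_id, function(pid) {
        cnt <- stats::setNames(rep(0L, length(reps)), reps)
        hit <- good[good$protein_id == pid, ]
        cnt[as.character(hit$replicate)] <- hit$n_unique
        cnt
      }),
      n_reps_passing = purrr::map_int(
        .data$rep_counts, ~ sum(.x >= params$min_unique_per_replicate)
      ),
      accepted = .data$protein_prob >= params$min_protein_prob &
        .data$n_reps_passing >= params$required_replicates
    )
}

#' Quantify proteins by emPAI
#'
#' Filters identifications with [filter_identifications()], counts the
#' distinct unique peptide sequences observed for each accepted protein
#' (`n_observed`), computes the observable-peptide count from an in-silico
#' tryptic digest of the protein sequence (`n_observable`), and ranks
#' proteins by emPAI (descending, ties by protein id).
#'
#' @param evidence Peptide evidence (see [filter_identifications()]).
#' @param proteome A data frame with columns `id` and `sequence` covering
#'   every accepted protein.
#' @param filter_params An [evidence_filter_params()] object.
#' @param dparams A [digest_params()] object.
#' @return A tibble of class `protein_quant` with columns `protein_id`,
#'   `n_observed`, `n_observable`, `pai`, `empai`, `rep_counts`.
#' @export
quantify_proteins <- function(evidence, proteome,
                              filter_params = evidence_filter_params(),
                              dparams = digest_params()) {
  summary <- filter_identifications(evidence, filter_params)
  accepted <- summary[summary$accepted, ]
  if (nrow(accepted) == 0) {
    out <- tibble::tibble(
      protein_id = character(), n_observed = integer(),
      n_observable = integer(), pai = numeric(), empai = numeric(),
      rep_counts = list()
    )
    class(out) <- c("protein_quant", class(out))
    return(out)
  }
  missing <- setdiff(accepted$protein_id, proteome$id)
  if (length(missing)) {
    rlang::abort(paste0("accepted protein absent from proteome: ", missing[1]),
                 class = "secretr_error_input")
  }
  obs <- evidence |>
    dplyr::filter(.data$is_unique,
                  .data$peptide_prob >= filter_params$min_peptide_prob,
                  .data$protein_id %in% accepted$protein_id) |>
    dplyr::distinct(.data$protein_id, .data$peptide_seq) |>
    dplyr::count(.data$protein_id, name = "n_observed")

  seqs <- stats::setNames(proteome$sequence, proteome$id)
  out <- accepted |>
    dplyr::left_join(obs, by = "protein_id") |>
    dplyr::mutate(
      n_observed = dplyr::coalesce(.data$n_observed, 0L),
      n_observable = purrr::map_int(
        .data$protein_id, ~ count_observable_peptides(seqs[[.x]], dparams)
      ),
      pai = .data$n_observed / .data$n_observable,
      empai = empai(.data$n_observed, .data$n_observable)
    ) |>
    dplyr::arrange(dplyr::desc(.data$empai), .data$protein_id) |>
    dplyr::select("protein_id", "n_observed", "n_observable",
                  "pai", "empai", "rep_counts")
  attr(out, "filter_params") <- filter_params
  attr(out, "digest_params") <- dparams
  class(out) <- c("protein_quant", class(out))
  out
}

#' @method glance protein_quant
#' @export
glance.protein_quant <- function(x, ...) {
  tibble::tibble(
    n_accepted = nrow(x),
    max_empai = if (nrow(x)) max(x$empai) else NA_real_,
    median_empai = if (nrow(x)) stats::median(x$empai) else NA_real_
  )
}

#' @method tidy protein_quant
#' @export
tidy.protein_quant <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "protein_quant")
  out$rep_counts <- NULL
  tibble::as_tibble(out)
}
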