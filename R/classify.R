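# Rule-based signal-peptide classification.
#
# Precedence, applied to each N-terminus:
#   1. lipobox (Gly-Cys after the hydrophobic core)     -> LIPOPROTEIN
#   2. early glycine after a short basic n-region       -> CLASS_III
#   3. h-region + (-3,-1)-scored SPase I site + net
#      positive N-terminal charge                       -> SPASE_I
#   4. otherwise                                        -> NONE
#
# The classifier only ever reads a bounded N-terminal prefix (one residue
# past the SPase I search window / lipobox window, whichever is larger), so
# appending residues beyond that prefix can never change a call.

SP_CLASSES <- c("SPASE_I", "LIPOPROTEIN", "CLASS_III", "NONE")

classifier_prefix_len <- function(params) {
  max(params$spase1_search_window[2], params$lipobox_window) + 1L
}

#' Scan for a lipobox (Gly-Cys) motif
#'
#' Returns the first position `p` within `lipobox_window` where the residue
#' is glycine, the next residue is cysteine, and `p` lies at or after the
#' end of a valid h-region. Cleavage is after `p`; the cysteine becomes the
#' lipid-anchored first mature residue.
#'
#' @param seq Amino-acid string.
#' @param params A [sp_classifier_params()] object.
#' @return `NULL` when no motif qualifies, otherwise a list with `pos` (the
#'   glycine position) and `motif` (e.g. `"G/CIGG"`).
#' @export
scan_lipobox <- function(seq, params = sp_classifier_params()) {
  n <- nchar(seq)
  if (n < 2) return(NULL)
  h <- find_h_region(seq, params)
  if (is.null(h)) return(NULL)
  res <- split_residues(seq)
  p_max <- min(params$lipobox_window, n - 1L)
  for (p in seq_len(p_max)) {
    if (res[p] == "G" && res[p + 1] == "C" && p >= h$end) {
      motif <- paste0("G/", substr(seq, p + 1, min(p + 4, n)))
      return(list(pos = as.integer(p), motif = motif))
    }
  }
  NULL
}

#' Detect a class III (prepilin-like) cleavage site
#'
#' Looks for a glycine at position `class3_gly_min_pos` to
#' `class3_gly_max_pos` such that the residues between position 2 and the
#' glycine contain no hydrophobic residue but at least one K/R, and the
#' residues after the glycine form a hydrophobic stretch (the h-region is
#' retained in the mature protein). Cleavage is after the glycine.
#'
#' @inheritParams scan_lipobox
#' @return The glycine position (integer) or `NULL`.
#' @export
detect_class3 <- function(seq, params = sp_classifier_params()) {
  n <- nchar(seq)
  if (n < 10) return(NULL)
  res <- split_residues(seq)
  g_max <- min(params$class3_gly_max_pos, n - params$class3_h_run)
  if (g_max < params$class3_gly_min_pos) return(NULL)
  for (g in params$class3_gly_min_pos:g_max) {
    if (res[g] != "G") next
    pre <- res[2:(g - 1)]
    if (any(pre %in% params$class3_forbidden_set)) next
    if (!any(pre %in% c("K", "R"))) next
    run <- res[(g + 1):(g + params$class3_h_run)]
    if (mean(unname(KD_HYDROPATHY[run])) < params$hydropathy_threshold) next
    return(as.integer(g))
  }
  NULL
}

#' Predict an SPase I cleavage site
#'
#' Candidate positions `p` lie in `spase1_search_window`, carry an allowed
#' -1 residue (`minus1_allowed`), and sit at least two residues past the
#' h-region end. Each candidate is scored +1 for alanine at -1, +1 for a
#' preferred -3 residue and -1 for a charged residue at -2. Among
#' candidates scoring at least `spase1_min_score`, the most C-terminal is
#' returned; when none reaches that score the best-scoring candidate is
#' used (ties to the larger position).
#'
#' @param seq Amino-acid string.
#' @param regions A decomposition from [decompose_regions()] (needs a valid
#'   `h_region`).
#' @param params A [sp_classifier_params()] object.
#' @return `NULL`, or a list with `pos` and `score`.
#' @export
predict_spase1_cleavage <- function(seq, regions, params = sp_classifier_params()) {
  if (is.null(regions$h_region)) return(NULL)
  n <- nchar(seq)
  res <- split_residues(seq)
  h_end <- regions$h_region[2]
  lo <- max(params$spase1_search_window[1], h_end + 2L, 3L)
  hi <- min(params$spase1_search_window[2], n)
  if (lo > hi) return(NULL)
  cand <- lo:hi
  cand <- cand[res[cand] %in% params$minus1_allowed]
  if (!length(cand)) return(NULL)
  charged <- c(params$basic_set, params$acidic_set)
  score <- vapply(cand, function(p) {
    s <- 0
    if (res[p] == "A") s <- s + 1
    if (res[p - 2] %in% params$minus3_preferred) s <- s + 1
    if (res[p - 1] %in% charged) s <- s - 1
    s
  }, numeric(1))
  ok <- which(score >= params$spase1_min_score)
  pick <- if (length(ok)) max(ok) else max(which(score == max(score)))
  list(pos = as.integer(cand[pick]), score = score[pick])
}

#' Net charge of an N-terminus
#'
#' Number of basic minus number of acidic residues over the first
#' `window` residues. Histidine is not counted as basic by default.
#'
#' @param seq Amino-acid string.
#' @param params A [sp_classifier_params()] object.
#' @param window Number of residues to consider; defaults to
#'   `params$charge_window` (clipped to the sequence length). When scoring
#'   a predicted signal peptide, pass its length.
#' @return Integer net charge.
#' @export
nterm_net_charge <- function(seq, params = sp_classifier_params(), window = NULL) {
  n <- nchar(seq)
  stopifnot(n >= 1)
  w <- min(if (is.null(window)) params$charge_window else window, n)
  res <- split_residues(substr(seq, 1, w))
  as.integer(sum(res %in% params$basic_set) - sum(res %in% params$acidic_set))
}

classify_one <- function(id, seq, params) {
  n <- nchar(seq)
  prefix <- substr(seq, 1, min(n, classifier_prefix_len(params)))

  none_call <- function() {
    tibble::tibble(
      protein_id = id, sp_class = "NONE", cleavage_after = 0L,
      sp_sequence = "", lipobox_motif = NA_character_,
      n_charge = nterm_net_charge(seq, params),
      score = NA_real_, n_end = NA_integer_,
      h_start = NA_integer_, h_end = NA_integer_, sequence = seq
    )
  }

  lipo <- scan_lipobox(prefix, params)
  if (!is.null(lipo)) {
    h <- find_h_region(prefix, params)
    return(tibble::tibble(
      protein_id = id, sp_class = "LIPOPROTEIN", cleavage_after = lipo$pos,
      sp_sequence = substr(seq, 1, lipo$pos), lipobox_motif = lipo$motif,
      n_charge = nterm_net_charge(seq, params, window = lipo$pos),
      score = NA_real_, n_end = as.integer(h$start - 1),
      h_start = as.integer(h$start), h_end = as.integer(min(h$end, lipo$pos - 1L)),
      sequence = seq
    ))
  }

  g <- detect_class3(prefix, params)
  if (!is.null(g)) {
    return(tibble::tibble(
      protein_id = id, sp_class = "CLASS_III", cleavage_after = g,
      sp_sequence = substr(seq, 1, g), lipobox_motif = NA_character_,
      n_charge = nterm_net_charge(seq, params, window = g),
      score = NA_real_, n_end = g,
      h_start = g + 1L, h_end = g + params$class3_h_run, sequence = seq
    ))
  }

  if (n >= 15) {
    regions <- decompose_regions(prefix, params)
    sp1 <- predict_spase1_cleavage(prefix, regions, params)
    if (!is.null(sp1) &&
        nterm_net_charge(seq, params, window = sp1$pos) >= 1L) {
      return(tibble::tibble(
        protein_id = id, sp_class = "SPASE_I", cleavage_after = sp1$pos,
        sp_sequence = substr(seq, 1, sp1$pos), lipobox_motif = NA_character_,
        n_charge = nterm_net_charge(seq, params, window = sp1$pos),
        score = sp1$score, n_end = regions$h_region[1] - 1L,
        h_start = regions$h_region[1], h_end = regions$h_region[2],
        sequence = seq
      ))
    }
  }
  none_call()
}

#' Classify signal peptides in a set of proteins
#'
#' Applies the rule-based classifier to every protein and returns one call
#' per row, in input order. The returned tibble carries the parameter set
#' as an attribute and has class `sp_calls`, with [generics::glance()] and
#' [generics::tidy()] methods.
#'
#' @param proteins A data frame with columns `id` and `sequence`
#'   (uppercase one-letter residues; `X` allowed for unknowns).
#' @param params A [sp_classifier_params()] object.
#' @return A tibble of class `sp_calls` with columns `protein_id`,
#'   `sp_class` (`SPASE_I`, `LIPOPROTEIN`, `CLASS_III` or `NONE`),
#'   `cleavage_after` (last signal-peptide residue; 0 for `NONE`),
#'   `sp_sequence`, `lipobox_motif`, `n_charge`, `score`, the region bounds
#'   `n_end`/`h_start`/`h_end`, and the input `sequence`.
#' @examples
#' proteins <- tibble::tibble(
#'   id = "PF0119",
#'   sequence = "MKHKAVFLLVVLISGVLASGCIGGETKETQ"
#' )
#' classify_signal_peptides(proteins)
#' @export
classify_signal_peptides <- function(proteins, params = sp_classifier_params()) {
  validate_proteins(proteins)
  calls <- purrr::map2(
    proteins$id, proteins$sequence,
    function(id, seq) classify_one(id, seq, params)
  )
  out <- dplyr::bind_rows(calls)
  attr(out, "params") <- params
  class(out) <- c("sp_calls", class(out))
  out
}

#' Split calls by N-terminal net charge
#'
#' Partitions signal-peptide calls into those with a net positive
#' N-terminal charge and those with zero or negative charge, preserving
#' order within each partition.
#'
#' @param calls An `sp_calls` tibble (or any data frame with an `n_charge`
#'   column).
#' @return A list with elements `positive` (`n_charge >= 1`) and
#'   `nonpositive`.
#' @export
partition_by_charge <- function(calls) {
  stopifnot(nrow(calls) > 0, "n_charge" %in% names(calls))
  list(
    positive = calls[calls$n_charge >= 1, , drop = FALSE],
    nonpositive = calls[calls$n_charge <= 0, , drop = FALSE]
  )
}

#' @method glance sp_calls
#' @export
glance.sp_calls <- function(x, ...) {
  counts <- table(factor(x$sp_class, levels = SP_CLASSES))
  n <- nrow(x)
  n_secreted <- n - unname(counts[["NONE"]])
  tibble::tibble(
    n_proteins = n,
    n_spase_i = unname(counts[["SPASE_I"]]),
    n_lipoprotein = unname(counts[["LIPOPROTEIN"]]),
    n_class_iii = unname(counts[["CLASS_III"]]),
    n_none = unname(counts[["NONE"]]),
    n_secreted = n_secreted,
    pct_secreted = percent_of(n_secreted, n)
  )
}

#' @method tidy sp_calls
#' @export
tidy.sp_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sp_calls")
  attr(out, "params") <- NULL
  tibble::as_tibble(out)
}
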