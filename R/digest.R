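# In-silico tryptic digestion, peptide masses and emPAI.

#' In-silico tryptic digest
#'
#' Cleaves after K or R (not before proline when `proline_rule` is on) and
#' enumerates all peptides with up to `max_miscleavages` internal missed
#' cleavage sites, each with 1-based start/end coordinates. The result is
#' exhaustive and duplicate-free by coordinates; fully cleaved peptides
#' (`n_missed == 0`) tile the protein.
#'
#' @param seq Amino-acid string.
#' @param params A [digest_params()] object.
#' @return A tibble with columns `start`, `end`, `peptide`, `n_missed`.
#' @examples
#' digest_tryptic("AAKCCRDD", digest_params(max_miscleavages = 0))
#' @export
digest_tryptic <- function(seq, params = digest_params()) {
  stopifnot(nzchar(seq))
  res <- split_residues(seq)
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  if (params$proline_rule) {
    cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1, n)] != "P"]
  }
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)
  rows <- list()
  for (i in seq_len(k)) {
    for (m in 0:params$max_miscleavages) {
      j <- i + m
      if (j > k) break
      rows[[length(rows) + 1]] <- c(starts[i], ends[j], m)
    }
  }
  mat <- do.call(rbind, rows)
  tibble::tibble(
    start = as.integer(mat[, 1]),
    end = as.integer(mat[, 2]),
    peptide = substring(seq, mat[, 1], mat[, 2]),
    n_missed = as.integer(mat[, 3])
  )
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, so that
#' `peptide_mass("AB")` equals `peptide_mass("A") + peptide_mass("B")`
#' minus one water. Vectorised over peptides.
#'
#' @param peptides Character vector of peptide sequences (standard residues
#'   only).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("G") # glycine as a free amino acid, 75.032 Da
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    if (is.na(p) || !nzchar(p)) {
      rlang::abort("empty peptide has no mass", class = "secretr_error_input")
    }
    res <- split_residues(p)
    bad <- setdiff(unique(res), names(RESIDUE_MONO_MASS))
    if (length(bad)) {
      rlang::abort(paste0("unknown residue '", bad[1], "' in peptide ", p),
                   class = "secretr_error_alphabet")
    }
    sum(RESIDUE_MONO_MASS[res]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count observable tryptic peptides
#'
#' Number of distinct fully cleaved tryptic peptide sequences whose
#' monoisotopic mass falls inside `params$mass_range` and whose length is
#' at least `params$min_peptide_len`. The count is floored at 1 so it can
#' serve as the emPAI denominator even for degenerate proteins. Peptides
#' containing `X` are treated as unobservable.
#'
#' @inheritParams digest_tryptic
#' @return Integer count (at least 1).
#' @export
count_observable_peptides <- function(seq, params = digest_params()) {
  pep <- digest_tryptic(seq, params)
  pep <- unique(pep$peptide[pep$n_missed == 0L])
  pep <- pep[nchar(pep) >= params$min_peptide_len & !grepl("X", pep, fixed = TRUE)]
  if (!length(pep)) return(1L)
  m <- peptide_mass(pep)
  max(1L, sum(m >= params$mass_range[1] & m <= params$mass_range[2]))
}

#' Exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`. Strictly increasing in
#' `n_observed` at fixed `n_observable`; zero exactly when nothing was
#' observed. Vectorised.
#'
#' @param n_observed Number of distinct observed unique peptides (>= 0).
#' @param n_observable Number of in-silico observable peptides (>= 1).
#' @return Numeric vector of emPAI values.
#' @examples
#' empai(5, 10) # 10^0.5 - 1
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) {
    rlang::abort("n_observable must be at least 1", class = "secretr_error_input")
  }
  if (any(n_observed < 0)) {
    rlang::abort("n_observed must be non-negative", class = "secretr_error_input")
  }
  10^(n_observed / n_observable) - 1
}
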