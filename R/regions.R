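# n/h/c decomposition of protein N-termini.

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy in a centred window; at the termini the
#' window is truncated to the available residues. `X` scores 0.
#'
#' @param seq Amino-acid string.
#' @param window Odd window width (default 5).
#' @return Numeric vector, one score per residue.
#' @export
hydropathy_profile <- function(seq, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  kd <- unname(KD_HYDROPATHY[split_residues(seq)])
  n <- length(kd)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(kd[lo:hi])
  }, numeric(1))
}

# Maximal-mean hydrophobic stretch: among all contiguous stretches of
# length >= h_min_len starting at or before h_start_max, pick the one with
# the highest mean raw hydropathy (ties: longer, then more N-terminal).
# Returns NULL when the best mean is below the threshold or the sequence is
# too short. `limit` truncates the search so the classifier only ever reads
# a bounded N-terminal prefix.
find_h_region <- function(seq, params, limit = nchar(seq)) {
  n <- min(nchar(seq), limit)
  if (n < params$h_min_len) return(NULL)
  kd <- unname(KD_HYDROPATHY[split_residues(substr(seq, 1, n))])
  cs <- c(0, cumsum(kd))
  best <- NULL
  a_max <- min(params$h_start_max, n - params$h_min_len + 1)
  if (a_max < 1) return(NULL)
  for (a in seq_len(a_max)) {
    for (b in seq(a + params$h_min_len - 1, n)) {
      m <- (cs[b + 1] - cs[a]) / (b - a + 1)
      if (is.null(best) ||
          m > best$mean + 1e-9 ||
          (abs(m - best$mean) <= 1e-9 && (b - a) > (best$end - best$start))) {
        best <- list(start = a, end = b, mean = m)
      }
    }
  }
  if (is.null(best) || best$mean < params$hydropathy_threshold) return(NULL)
  best
}

#' Decompose an N-terminus into n/h/c regions
#'
#' Finds the hydrophobic core (h-region) as the maximal-mean hydropathy
#' stretch of at least `h_min_len` residues starting within the first
#' `h_start_max` positions; the n-region is everything before it. The
#' c-region runs from the end of the h-region to the cleavage site and is
#' therefore only delimited once a cleavage site has been predicted.
#'
#' @param seq Amino-acid string of at least 15 residues.
#' @param params A [sp_classifier_params()] object.
#' @return A list with `n_region` and `h_region` (integer `c(start, end)`;
#'   `h_region` is `NULL` when no hydrophobic stretch qualifies, and
#'   `n_region` has zero length when the h-region starts at position 1),
#'   plus the per-residue `hydropathy_profile`.
#' @export
decompose_regions <- function(seq, params = sp_classifier_params()) {
  if (nchar(seq) < 15) {
    rlang::abort("sequence too short for region decomposition",
                 class = "secretr_error_input")
  }
  h <- find_h_region(seq, params)
  profile <- hydropathy_profile(seq, params$hydropathy_window)
  if (is.null(h)) {
    return(list(n_region = NULL, h_region = NULL, c_region = NULL,
                hydropathy_profile = profile))
  }
  list(
    n_region = c(1L, as.integer(h$start - 1)),
    h_region = c(as.integer(h$start), as.integer(h$end)),
    c_region = NULL,
    hydropathy_profile = profile
  )
}
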