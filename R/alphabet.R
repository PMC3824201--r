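# Residue-level constants shared across the package.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes. Sequences may additionally
#' contain `"X"` for an unknown residue: `X` scores 0 on the hydropathy
#' scale, carries no charge and never matches a sequence motif.
#'
#' @format A character vector of length 20.
#' @export
AMINO_ACIDS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy used for h-region detection and for the
#' hydrophobic-stretch checks of the class III rule. `X` is assigned 0.
#'
#' @format Named numeric vector over [AMINO_ACIDS] plus `"X"`.
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0
)

# Monoisotopic residue masses (Da); peptide mass = sum + one water.
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.0105646

# Fixed average amino-acid composition used as the background residue
# distribution of synthetic mature/cytoplasmic segments. A documented
# constant, not fitted to any particular proteome.
BACKGROUND_AA_FREQ <- c(
  A = 0.078, R = 0.051, N = 0.043, D = 0.053, C = 0.019,
  Q = 0.042, E = 0.063, G = 0.072, H = 0.023, I = 0.053,
  L = 0.091, K = 0.059, M = 0.022, F = 0.039, P = 0.052,
  S = 0.068, T = 0.059, W = 0.014, Y = 0.032, V = 0.066
)

split_residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Validate protein sequences
#'
#' Checks that sequences are non-empty and restricted to the 20 standard
#' residues plus `X`. Called by the classifier and the pipeline before any
#' analysis.
#'
#' @param proteins A data frame with columns `id` and `sequence`.
#' @return `proteins`, invisibly, if valid; otherwise an error naming the
#'   offending record and residue.
#' @export
validate_proteins <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0) {
    rlang::abort("no protein records supplied", class = "secretr_error_input")
  }
  if (anyDuplicated(proteins$id)) {
    dup <- proteins$id[duplicated(proteins$id)][1]
    rlang::abort(paste0("duplicate protein id: ", dup), class = "secretr_error_input")
  }
  ok <- c(AMINO_ACIDS, "X")
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    if (is.na(s) || !nzchar(s)) {
      rlang::abort(paste0("empty sequence for record ", proteins$id[i]),
                   class = "secretr_error_alphabet")
    }
    res <- split_residues(s)
    bad <- setdiff(unique(res), ok)
    if (length(bad)) {
      rlang::abort(
        paste0("invalid residue '", bad[1], "' in record ", proteins$id[i]),
        class = "secretr_error_alphabet"
      )
    }
  }
  invisible(proteins)
}
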