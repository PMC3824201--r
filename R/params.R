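# Parameter constructors. Defaults are the package's calibrated values for
# Thermococcales-type signal peptides; every free choice is exposed here.

#' Signal-peptide classifier parameters
#'
#' All tunable parameters of the rule-based classifier. The defaults are
#' calibrated on the experimentally verified *Pyrococcus furiosus*
#' secretome signal peptides bundled with the package and are documented in
#' the methods vignette.
#'
#' @param lipobox_window Last N-terminal position at which the lipobox
#'   glycine may sit (the lipid-anchor cysteine may therefore be one residue
#'   further out). Default 25.
#' @param class3_gly_min_pos,class3_gly_max_pos Allowed positions of the
#'   class III cleavage glycine. Defaults 4 and 6.
#' @param class3_forbidden_set Residues treated as hydrophobic and therefore
#'   disallowed between position 2 and the class III glycine.
#' @param class3_h_run Number of residues after the glycine that must form a
#'   hydrophobic stretch (mean hydropathy above `hydropathy_threshold`).
#' @param spase1_search_window Inclusive range of candidate SPase I cleavage
#'   positions. Default `c(18, 30)`.
#' @param spase1_min_score Minimum (-3,-1) score for a candidate site to be
#'   considered acceptable; among acceptable sites the most C-terminal wins,
#'   and if none is acceptable the best-scoring candidate is used.
#' @param minus1_allowed Residues allowed at the -1 position of an SPase I
#'   site. Default `"A"`.
#' @param minus3_preferred Residues rewarded at the -3 position.
#' @param h_min_len Minimum h-region length (residues). Default 7.
#' @param h_start_max Latest position at which the h-region may start.
#'   Default 12.
#' @param hydropathy_window Sliding-window width of the reported per-residue
#'   hydropathy profile. Default 5.
#' @param hydropathy_threshold Minimum mean Kyte-Doolittle hydropathy of a
#'   stretch counted as hydrophobic. Default 1.0.
#' @param charge_window Number of N-terminal residues used for the net
#'   charge when no signal peptide is predicted. Default 30; when a signal
#'   peptide is called the charge is computed over the signal peptide.
#' @param basic_set,acidic_set Residues counted as basic/acidic for the net
#'   charge. Histidine is deliberately excluded from `basic_set` (the
#'   positivity rule uses K/R only) but is counted as basic by
#'   [basic_residue_usage()].
#' @return A list of class `sp_classifier_params`.
#' @export
sp_classifier_params <- function(lipobox_window = 25,
                                 class3_gly_min_pos = 4,
                                 class3_gly_max_pos = 6,
                                 class3_forbidden_set = c("A", "V", "L", "I", "F", "M", "W", "C"),
                                 class3_h_run = 8,
                                 spase1_search_window = c(18, 30),
                                 spase1_min_score = 1,
                                 minus1_allowed = "A",
                                 minus3_preferred = c("A", "V", "S", "T", "G", "I", "L"),
                                 h_min_len = 7,
                                 h_start_max = 12,
                                 hydropathy_window = 5,
                                 hydropathy_threshold = 1.0,
                                 charge_window = 30,
                                 basic_set = c("K", "R"),
                                 acidic_set = c("D", "E")) {
  stopifnot(
    lipobox_window >= 2, class3_gly_min_pos >= 2,
    class3_gly_max_pos >= class3_gly_min_pos,
    length(spase1_search_window) == 2,
    spase1_search_window[1] <= spase1_search_window[2],
    length(minus1_allowed) >= 1,
    h_min_len >= 1, h_start_max >= 1,
    hydropathy_window >= 1, hydropathy_window %% 2 == 1,
    charge_window >= 1
  )
  structure(
    list(
      lipobox_window = as.integer(lipobox_window),
      class3_gly_min_pos = as.integer(class3_gly_min_pos),
      class3_gly_max_pos = as.integer(class3_gly_max_pos),
      class3_forbidden_set = class3_forbidden_set,
      class3_h_run = as.integer(class3_h_run),
      spase1_search_window = as.integer(spase1_search_window),
      spase1_min_score = spase1_min_score,
      minus1_allowed = minus1_allowed,
      minus3_preferred = minus3_preferred,
      h_min_len = as.integer(h_min_len),
      h_start_max = as.integer(h_start_max),
      hydropathy_window = as.integer(hydropathy_window),
      hydropathy_threshold = hydropathy_threshold,
      charge_window = as.integer(charge_window),
      basic_set = basic_set,
      acidic_set = acidic_set
    ),
    class = "sp_classifier_params"
  )
}

#' Identification-filter parameters
#'
#' Replicate and probability thresholds for accepting a protein
#' identification: a protein is accepted when its protein-level probability
#' reaches `min_protein_prob` and, in each of `required_replicates`
#' replicates, it has at least `min_unique_per_replicate` unique peptides
#' with peptide probability at or above `min_peptide_prob`.
#'
#' @param min_peptide_prob Minimum peptide probability. Default 0.95.
#' @param min_protein_prob Minimum protein probability. Default 0.98.
#' @param min_unique_per_replicate Minimum unique peptides per replicate.
#'   Default 1.
#' @param required_replicates Number of replicates in which the unique
#'   peptide requirement must hold. Default 2.
#' @return A list of class `evidence_filter_params`.
#' @export
evidence_filter_params <- function(min_peptide_prob = 0.95,
                                   min_protein_prob = 0.98,
                                   min_unique_per_replicate = 1,
                                   required_replicates = 2) {
  stopifnot(
    min_peptide_prob >= 0, min_peptide_prob <= 1,
    min_protein_prob >= 0, min_protein_prob <= 1,
    min_unique_per_replicate >= 1, required_replicates >= 1
  )
  structure(
    list(
      min_peptide_prob = min_peptide_prob,
      min_protein_prob = min_protein_prob,
      min_unique_per_replicate = as.integer(min_unique_per_replicate),
      required_replicates = as.integer(required_replicates)
    ),
    class = "evidence_filter_params"
  )
}

#' Tryptic-digest parameters
#'
#' Settings of the in-silico trypsin digest used for the emPAI denominator.
#' The default observable mass window 600-4000 Da is the singly/doubly
#' charged image of an m/z 300-2000 survey-scan range.
#'
#' @param max_miscleavages Maximum internal missed K/R sites. Default 1.
#' @param min_peptide_len Minimum peptide length (residues). Default 1.
#' @param mass_range Observable monoisotopic mass window in Da.
#' @param proline_rule If `TRUE` (default), K/R followed by proline is not
#'   cleaved.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_miscleavages = 1,
                          min_peptide_len = 1,
                          mass_range = c(600, 4000),
                          proline_rule = TRUE) {
  stopifnot(
    max_miscleavages >= 0, min_peptide_len >= 1,
    length(mass_range) == 2, mass_range[1] < mass_range[2]
  )
  structure(
    list(
      max_miscleavages = as.integer(max_miscleavages),
      min_peptide_len = as.integer(min_peptide_len),
      mass_range = as.numeric(mass_range),
      proline_rule = isTRUE(proline_rule)
    ),
    class = "digest_params"
  )
}
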