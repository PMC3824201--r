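# Synthetic labelled proteomes and replicate-structured peptide evidence.
#
# Region residue profiles mirror the features the classifier assumes:
# K/R-enriched n-regions, leucine-dominated h-regions, small-residue
# c-regions ending in alanine, an [S|A]G-C-I-G-G lipobox, and class III
# peptides whose hydrophobic run stays in the mature protein. Mature
# N-termini directly after a cleavage site are drawn charged/polar and
# alanine-poor, as observed for secreted proteins; cytoplasmic N-termini
# are acidic/polar so they lack an N-terminal hydrophobic core.

PROFILE_N_BASIC <- c(K = 0.40, R = 0.25, N = 0.08, S = 0.08, T = 0.07,
                     Q = 0.05, H = 0.04, E = 0.015, D = 0.015, P = 0.02)
PROFILE_N_NEUTRAL <- c(N = 0.25, S = 0.25, T = 0.20, Q = 0.20, H = 0.05, P = 0.05)
PROFILE_H <- c(L = 0.45, A = 0.14, V = 0.12, I = 0.10, F = 0.08,
               M = 0.04, G = 0.03, S = 0.02, T = 0.02)
PROFILE_C <- c(S = 0.30, T = 0.20, G = 0.15, N = 0.10, Q = 0.10,
               A = 0.10, V = 0.05)
PROFILE_MINUS3 <- c(A = 0.5, V = 0.3, S = 0.2)
PROFILE_MINUS2 <- c(S = 0.3, T = 0.25, G = 0.2, N = 0.15, Q = 0.1)
PROFILE_EARLY_MATURE <- c(E = 0.16, D = 0.10, K = 0.12, R = 0.07, Q = 0.12,
                          L = 0.07, Y = 0.05, T = 0.08, S = 0.08, P = 0.06,
                          G = 0.05, N = 0.03, A = 0.01)
PROFILE_CYTO_START <- c(E = 0.16, D = 0.14, S = 0.12, T = 0.10, K = 0.12,
                        N = 0.08, Q = 0.08, G = 0.08, P = 0.06, R = 0.06)

draw_residues <- function(n, profile) {
  if (n <= 0) return(character(0))
  p <- profile / sum(profile)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Synthetic proteome configuration
#'
#' Study-condition defaults for [generate_proteome()]: region-length
#' distributions (uniform), class proportions, mature-protein lengths, the
#' fraction of signal peptides emitted without a net-positive n-region, and
#' the seed. All randomness flows through the single seed.
#'
#' @param n_proteins Number of proteins to generate.
#' @param class_proportions Named proportions over
#'   `SPASE_I`, `LIPOPROTEIN`, `CLASS_III`, `NONE`; must sum to 1.
#' @param n_extra_range Residues in the n-region after the initiator
#'   methionine (uniform; default 2-6).
#' @param h_len_range h-region length (default 8-15).
#' @param c_len_range c-region length for SPase I substrates (default 3-7).
#' @param class3_run_range Length of the retained hydrophobic run of class
#'   III substrates (default 10-20).
#' @param mature_len_range Mature-protein length (default 80-300).
#' @param zero_charge_fraction Fraction of signal peptides emitted with an
#'   uncharged n-region (default 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `proteome_config`.
#' @export
proteome_config <- function(n_proteins = 200,
                            class_proportions = c(SPASE_I = 0.35,
                                                  LIPOPROTEIN = 0.25,
                                                  CLASS_III = 0.15,
                                                  NONE = 0.25),
                            n_extra_range = c(2, 6),
                            h_len_range = c(8, 15),
                            c_len_range = c(3, 7),
                            class3_run_range = c(10, 20),
                            mature_len_range = c(80, 300),
                            zero_charge_fraction = 0,
                            seed = NULL) {
  stopifnot(
    n_proteins >= 1,
    all(names(class_proportions) %in% SP_CLASSES),
    abs(sum(class_proportions) - 1) < 1e-8,
    zero_charge_fraction >= 0, zero_charge_fraction <= 1
  )
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      class_proportions = class_proportions,
      n_extra_range = as.integer(n_extra_range),
      h_len_range = as.integer(h_len_range),
      c_len_range = as.integer(c_len_range),
      class3_run_range = as.integer(class3_run_range),
      mature_len_range = as.integer(mature_len_range),
      zero_charge_fraction = zero_charge_fraction,
      seed = seed
    ),
    class = "proteome_config"
  )
}

runif_int <- function(range) sample(range[1]:range[2], 1)

make_n_region <- function(n_extra, zero_charge) {
  if (zero_charge) {
    return(draw_residues(n_extra, PROFILE_N_NEUTRAL))
  }
  res <- draw_residues(n_extra, PROFILE_N_BASIC)
  # the classifier's positivity rule expects at least two K/R
  force_at <- sample(seq_len(n_extra), min(2, n_extra))
  res[force_at] <- sample(c("K", "R"), length(force_at), replace = TRUE)
  res
}

make_mature <- function(len) {
  early <- draw_residues(min(len, 8), PROFILE_EARLY_MATURE)
  rest <- draw_residues(max(0, len - 8), BACKGROUND_AA_FREQ)
  c(early, rest)
}

#' Generate one labelled preprotein
#'
#' Emits a sequence realising the template of the requested class together
#' with its ground truth (class, cleavage site, region bounds). Uses the
#' current RNG state; see [generate_proteome()] for seeded generation.
#'
#' @param sp_class One of `SPASE_I`, `LIPOPROTEIN`, `CLASS_III`, `NONE`.
#' @param config A [proteome_config()] object.
#' @return A list with `sequence` and a one-row `truth` tibble.
#' @export
generate_preprotein <- function(sp_class, config = proteome_config()) {
  sp_class <- match.arg(sp_class, SP_CLASSES)
  mature_len <- runif_int(config$mature_len_range)
  zero_charge <- sp_class %in% c("SPASE_I", "LIPOPROTEIN") &&
    stats::runif(1) < config$zero_charge_fraction

  if (sp_class == "SPASE_I") {
    # resample region lengths until the signal peptide fits the cleavage
    # search window (observed SPase I signal peptides are 24-28 residues)
    repeat {
      nn <- runif_int(config$n_extra_range)
      hh <- runif_int(config$h_len_range)
      cc <- runif_int(config$c_len_range)
      sp_len <- 1 + nn + hh + cc
      if (sp_len >= 18 && sp_len <= 28) break
    }
    creg <- draw_residues(cc, PROFILE_C)
    creg[cc] <- "A"
    creg[cc - 1] <- draw_residues(1, PROFILE_MINUS2)
    creg[cc - 2] <- draw_residues(1, PROFILE_MINUS3)
    seq <- c("M", make_n_region(nn, zero_charge),
             draw_residues(hh, PROFILE_H), creg, make_mature(mature_len))
    truth <- list(cleavage = sp_len, n_end = 1 + nn,
                  h_start = 2 + nn, h_end = 1 + nn + hh)
  } else if (sp_class == "LIPOPROTEIN") {
    nn <- runif_int(config$n_extra_range)
    hh <- runif_int(config$h_len_range)
    linker <- sample(c("S", "A"), 1, prob = c(0.7, 0.3))
    seq <- c("M", make_n_region(nn, zero_charge),
             draw_residues(hh, PROFILE_H), linker, "G",
             c("C", "I", "G", "G"), make_mature(mature_len))
    truth <- list(cleavage = 3 + nn + hh, n_end = 1 + nn,
                  h_start = 2 + nn, h_end = 1 + nn + hh)
  } else if (sp_class == "CLASS_III") {
    g <- sample(4:6, 1)
    run <- runif_int(config$class3_run_range)
    nreg <- draw_residues(g - 2, PROFILE_N_BASIC[setdiff(names(PROFILE_N_BASIC), c("E", "D"))])
    nreg[sample(seq_len(g - 2), 1)] <- sample(c("K", "R"), 1)
    seq <- c("M", nreg, "G",
             draw_residues(run, PROFILE_H[setdiff(names(PROFILE_H), "G")]),
             make_mature(mature_len))
    truth <- list(cleavage = g, n_end = g,
                  h_start = g + 1, h_end = g + run)
  } else {
    seq <- c("M", draw_residues(9, PROFILE_CYTO_START),
             draw_residues(mature_len, BACKGROUND_AA_FREQ))
    truth <- list(cleavage = 0, n_end = NA_integer_,
                  h_start = NA_integer_, h_end = NA_integer_)
  }

  list(
    sequence = paste(seq, collapse = ""),
    truth = tibble::tibble(
      sp_class = sp_class,
      cleavage_after = as.integer(truth$cleavage),
      n_end = as.integer(truth$n_end),
      h_start = as.integer(truth$h_start),
      h_end = as.integer(truth$h_end),
      zero_charge = zero_charge
    )
  )
}

#' Generate a labelled synthetic proteome
#'
#' Draws `n_proteins` protein classes from `class_proportions` and emits a
#' sequence plus ground truth for each. Reproducible: the same config
#' (including seed) yields byte-identical output; the global RNG state is
#' left untouched.
#'
#' @param config A [proteome_config()] object.
#' @return A list of class `labeled_proteome` with tibbles `proteins`
#'   (`id`, `sequence`) and `truth` (`id`, `sp_class`, `cleavage_after`,
#'   region bounds, `zero_charge`).
#' @export
generate_proteome <- function(config = proteome_config()) {
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  classes <- sample(names(config$class_proportions), config$n_proteins,
                    replace = TRUE, prob = config$class_proportions)
  ids <- sprintf("SYN%04d", seq_len(config$n_proteins))
  gen <- purrr::map(classes, generate_preprotein, config = config)
  out <- list(
    proteins = tibble::tibble(
      id = ids,
      sequence = purrr::map_chr(gen, "sequence")
    ),
    truth = dplyr::bind_rows(purrr::map(gen, "truth")) |>
      dplyr::mutate(id = ids, .before = 1)
  )
  class(out) <- "labeled_proteome"
  out
}

#' Evidence-simulation configuration
#'
#' Settings for [simulate_evidence()]: replicate count, the log-normal
#' abundance distribution, the logistic dependence of per-peptide detection
#' probability on log abundance, probability-score noise, and the fraction
#' of cytoplasmic proteins leaking into the supernatant.
#'
#' @param n_replicates Number of replicates (default 2).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance of
#'   secreted proteins.
#' @param detect_slope,detect_midpoint Per-peptide detection probability is
#'   `plogis(detect_slope * (log(abundance) - detect_midpoint))`.
#' @param peptide_prob_shape Beta shape parameters of peptide probability
#'   scores (default `c(60, 2)`: mostly above 0.95).
#' @param protein_prob_shape Beta shape parameters of protein probability
#'   scores.
#' @param contaminant_fraction Probability that a protein without a signal
#'   peptide leaks into the supernatant (default 0.25).
#' @param contaminant_meanlog Log-mean abundance of leaked proteins.
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `evidence_config`.
#' @export
evidence_config <- function(n_replicates = 2,
                            abundance_meanlog = 0,
                            abundance_sdlog = 1,
                            detect_slope = 1.5,
                            detect_midpoint = 0,
                            peptide_prob_shape = c(60, 2),
                            protein_prob_shape = c(300, 2),
                            contaminant_fraction = 0.25,
                            contaminant_meanlog = -1,
                            seed = NULL) {
  stopifnot(n_replicates >= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      detect_slope = detect_slope,
      detect_midpoint = detect_midpoint,
      peptide_prob_shape = peptide_prob_shape,
      protein_prob_shape = protein_prob_shape,
      contaminant_fraction = contaminant_fraction,
      contaminant_meanlog = contaminant_meanlog,
      seed = seed
    ),
    class = "evidence_config"
  )
}

#' Simulate replicate-structured peptide evidence
#'
#' Assigns each protein an abundance (secreted proteins always present;
#' proteins without a signal peptide leak with probability
#' `contaminant_fraction`), then samples, per replicate, which observable
#' tryptic peptides are detected with an abundance-dependent probability,
#' and attaches peptide/protein probability scores. Peptide uniqueness is
#' computed against the full proteome digest.
#'
#' @param proteome A `labeled_proteome` from [generate_proteome()].
#' @param config An [evidence_config()] object.
#' @param dparams A [digest_params()] object for the observable-peptide
#'   sets.
#' @return A list of class `evidence_sim` with `evidence` (a peptide-record
#'   tibble: `protein_id`, `peptide_seq`, `replicate`, `peptide_prob`,
#'   `protein_prob`, `is_unique`) and `truth` (`id`, `abundance`,
#'   `detect_p`).
#' @export
simulate_evidence <- function(proteome, config = evidence_config(),
                              dparams = digest_params()) {
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  prot <- proteome$proteins
  truth <- proteome$truth
  stopifnot(nrow(prot) > 0)

  secreted <- truth$sp_class != "NONE"
  abundance <- numeric(nrow(prot))
  abundance[secreted] <- stats::rlnorm(sum(secreted),
                                       config$abundance_meanlog,
                                       config$abundance_sdlog)
  leak <- !secreted & stats::runif(nrow(prot)) < config$contaminant_fraction
  abundance[leak] <- stats::rlnorm(sum(leak),
                                   config$contaminant_meanlog,
                                   config$abundance_sdlog)

  observable <- purrr::map(prot$sequence, function(s) {
    pep <- digest_tryptic(s, dparams)
    pep <- unique(pep$peptide[pep$n_missed == 0L])
    m <- peptide_mass(pep[!grepl("X", pep, fixed = TRUE)])
    pep[!grepl("X", pep, fixed = TRUE)][m >= dparams$mass_range[1] &
                                          m <= dparams$mass_range[2]]
  })
  # peptides occurring in more than one protein's observable set are not
  # unique evidence
  pep_owner <- table(unlist(observable))

  detect_p <- ifelse(
    abundance > 0,
    stats::plogis(config$detect_slope * (log(abundance) - config$detect_midpoint)),
    0
  )
  protein_prob <- round(stats::rbeta(nrow(prot),
                                     config$protein_prob_shape[1],
                                     config$protein_prob_shape[2]), 4)

  rows <- list()
  for (i in seq_len(nrow(prot))) {
    if (abundance[i] <= 0 || !length(observable[[i]])) next
    for (r in seq_len(config$n_replicates)) {
      hit <- observable[[i]][stats::runif(length(observable[[i]])) < detect_p[i]]
      if (!length(hit)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = prot$id[i],
        peptide_seq = hit,
        replicate = paste0("R", r),
        peptide_prob = round(stats::rbeta(length(hit),
                                          config$peptide_prob_shape[1],
                                          config$peptide_prob_shape[2]), 4),
        protein_prob = protein_prob[i],
        is_unique = as.logical(pep_owner[hit] == 1L)
      )
    }
  }
  evidence <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(protein_id = character(), peptide_seq = character(),
                   replicate = character(), peptide_prob = numeric(),
                   protein_prob = numeric(), is_unique = logical())
  }
  out <- list(
    evidence = evidence,
    truth = tibble::tibble(id = prot$id, abundance = abundance,
                           detect_p = detect_p)
  )
  class(out) <- "evidence_sim"
  out
}
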