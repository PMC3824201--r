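# Identification filtering and emPAI ranking.

make_records <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(
      protein_id = r[[1]], peptide_seq = r[[2]], replicate = r[[3]],
      peptide_prob = as.numeric(r[[4]]), protein_prob = as.numeric(r[[5]]),
      is_unique = as.logical(r[[6]])
    )
  }))
}

test_that("the replicate/probability filter implements each rejection clause", {
  # a protein seen in only one replicate is rejected
  ev <- make_records(
    list("P1", "AAAK", "R1", 0.99, 0.99, TRUE),
    list("P2", "CCCK", "R1", 0.99, 0.99, TRUE),
    list("P2", "DDDK", "R2", 0.99, 0.99, TRUE)
  )
  out <- filter_identifications(ev)
  expect_false(out$accepted[out$protein_id == "P1"])
  expect_true(out$accepted[out$protein_id == "P2"])

  # peptides below the probability threshold do not count
  ev2 <- make_records(
    list("P1", "AAAK", "R1", 0.94, 0.99, TRUE),
    list("P1", "CCCK", "R2", 0.94, 0.99, TRUE),
    list("P2", "DDDK", "R1", 0.99, 0.99, TRUE),
    list("P2", "EEEK", "R2", 0.99, 0.99, TRUE)
  )
  out2 <- filter_identifications(ev2)
  expect_false(out2$accepted[out2$protein_id == "P1"])

  # protein probability below threshold
  ev3 <- make_records(
    list("P1", "AAAK", "R1", 0.99, 0.97, TRUE),
    list("P1", "CCCK", "R2", 0.99, 0.97, TRUE),
    list("P2", "DDDK", "R1", 0.99, 0.99, TRUE),
    list("P2", "EEEK", "R2", 0.99, 0.99, TRUE)
  )
  out3 <- filter_identifications(ev3)
  expect_false(out3$accepted[out3$protein_id == "P1"])

  # non-unique peptides never count as evidence
  ev4 <- make_records(
    list("P1", "AAAK", "R1", 0.99, 0.99, FALSE),
    list("P1", "CCCK", "R2", 0.99, 0.99, FALSE),
    list("P2", "DDDK", "R1", 0.99, 0.99, TRUE),
    list("P2", "EEEK", "R2", 0.99, 0.99, TRUE)
  )
  expect_false(filter_identifications(ev4)$accepted[1])
})

test_that("the filter errors when fewer replicates exist than required", {
  ev <- make_records(list("P1", "AAAK", "R1", 0.99, 0.99, TRUE))
  expect_error(filter_identifications(ev), "replicate",
               class = "secretr_error_input")
})

test_that("the filter is monotone in its thresholds", {
  withr::local_seed(101)
  ev <- tibble::tibble(
    protein_id = sample(paste0("P", 1:12), 150, replace = TRUE),
    peptide_seq = paste0(
      replicate(150, paste(sample(AMINO_ACIDS, 6, replace = TRUE), collapse = "")),
      "K"
    ),
    replicate = sample(c("R1", "R2"), 150, replace = TRUE),
    peptide_prob = round(runif(150, 0.85, 1), 3),
    protein_prob = 0.99,
    is_unique = runif(150) < 0.8
  )
  base <- filter_identifications(ev)
  accepted_base <- base$protein_id[base$accepted]
  for (p in list(
    evidence_filter_params(min_peptide_prob = 0.99),
    evidence_filter_params(min_protein_prob = 0.999),
    evidence_filter_params(min_unique_per_replicate = 3),
    evidence_filter_params(required_replicates = 2)
  )) {
    out <- filter_identifications(ev, p)
    expect_true(all(out$protein_id[out$accepted] %in% accepted_base))
  }
})

test_that("quantification ranks by emPAI and validates the proteome", {
  proteome <- tibble::tibble(
    id = c("A", "B"),
    # same observable peptide count, different observed counts
    sequence = c("MAAAAAAAKCCCCCCCKDDDDDDDK", "MEEEEEEEKFFFFFFFKGGGGGGGK")
  )
  dp <- digest_params(mass_range = c(0.1, 1e6))
  ev <- make_records(
    list("A", "MAAAAAAAK", "R1", 0.99, 0.99, TRUE),
    list("A", "CCCCCCCK", "R1", 0.99, 0.99, TRUE),
    list("A", "MAAAAAAAK", "R2", 0.99, 0.99, TRUE),
    list("B", "MEEEEEEEK", "R1", 0.99, 0.99, TRUE),
    list("B", "MEEEEEEEK", "R2", 0.99, 0.99, TRUE)
  )
  q <- quantify_proteins(ev, proteome, dparams = dp)
  expect_equal(q$protein_id, c("A", "B"))
  expect_equal(q$n_observed, c(2L, 1L))
  expect_equal(q$empai, 10^(q$n_observed / q$n_observable) - 1)
  expect_true(all(diff(q$empai) <= 0))

  # an accepted protein missing from the proteome is a named error
  expect_error(
    quantify_proteins(ev, proteome[1, ], dparams = dp),
    "B", class = "secretr_error_input"
  )
})

test_that("quantification of evidence with no accepted protein is empty", {
  ev <- make_records(
    list("P1", "AAAK", "R1", 0.5, 0.5, TRUE),
    list("P1", "AAAK", "R2", 0.5, 0.5, TRUE)
  )
  q <- quantify_proteins(ev, tibble::tibble(id = "P1", sequence = "MAAAK"))
  expect_s3_class(q, "protein_quant")
  expect_equal(nrow(q), 0)
})
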