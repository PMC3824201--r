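# Rule-based signal-peptide classification.

test_that("lipobox scan finds the Gly-Cys motif after the hydrophobic core", {
  hit <- scan_lipobox("MKHKAVFLLVVLISGVLASGCIGGETKETQ")
  expect_equal(hit$pos, 20L)
  expect_equal(hit$motif, "G/CIGG")

  # no cysteine anywhere: no motif
  expect_null(scan_lipobox("MKHKAVFLLVVLISGVLASGAIGGETKETQ"))

  # Gly-Cys only beyond the 25-residue window: no motif
  far <- paste0("MKKAVFLLVVLISGVLASGSSSSSSSS", "GC", "IGGETKETQ")
  expect_equal(substr(far, 28, 29), "GC")
  expect_null(scan_lipobox(far))
})

test_that("class III detection accepts verified prepilin-like sites and rejects SPase I ones", {
  expect_equal(detect_class3("MKKGAIGIGTLIVFIAMVLVAAVAAGVLI"), 4L)
  expect_equal(detect_class3("MNKKGLTVLFIAIMLLSVVPVHFVS"), 5L)
  # first early glycine preceded by hydrophobic L/V: not class III
  expect_null(detect_class3("MKRLVGVLIGAFVIFGVFGQVVAAQEQELPREET"))
  # no basic residue before the glycine
  expect_null(detect_class3("MNNGAIGIGTLIVFIAMVLVAAVAAGVLI"))
})

test_that("SPase I site selection prefers the most C-terminal acceptable site", {
  params <- sp_classifier_params()
  pf0190 <- "MRKKLVGILTILVALGMLVSPLLKPVAAEDQKVLKIAM"
  sp1 <- predict_spase1_cleavage(pf0190, decompose_regions(pf0190, params), params)
  # A27 is rejected (-3 = P); A28 wins with -3 = V
  expect_equal(sp1$pos, 28L)

  pf1109 <- "MRRNAQVFAMVLLLVLSGIPKALALYTPTPFSID"
  sp1 <- predict_spase1_cleavage(pf1109, decompose_regions(pf1109, params), params)
  expect_equal(sp1$pos, 24L)

  # no alanine in the search window: no candidate
  noa <- paste0("MKK", strrep("L", 12), strrep("S", 15))
  expect_null(predict_spase1_cleavage(noa, decompose_regions(noa, params), params))
})

test_that("N-terminal net charge counts K/R against D/E", {
  expect_equal(nterm_net_charge("MKKLLLL"), 2L)
  expect_equal(nterm_net_charge("MDELLLL"), -2L)
  expect_equal(nterm_net_charge("MAAAALL"), 0L)
  # histidine is not counted as basic
  expect_equal(nterm_net_charge("MHHLLLL"), 0L)
  expect_equal(nterm_net_charge("MKDKDKD", window = 3), 0L)
})

test_that("the classifier reproduces every verified class and cleavage site", {
  ref <- ref_fragments()
  calls <- ref_calls()
  expect_equal(calls$sp_class, ref$sp_class)
  expect_equal(calls$cleavage_after, ref$cleavage_after)
  expect_equal(calls$protein_id, ref$id)
  # every lipoprotein call carries the expected motif
  expect_true(all(startsWith(
    calls$lipobox_motif[calls$sp_class == "LIPOPROTEIN"], "G/C"
  )))
})

test_that("a lipobox takes precedence over a class III pattern", {
  # PF1408 has both an early-glycine class III pattern and a lipobox
  seq <- "MKKGLLAILLVGVMVLGTFGSGCIGGGTQTQT"
  expect_equal(detect_class3(seq), 4L)
  expect_equal(scan_lipobox(seq)$pos, 22L)
  call <- classify_signal_peptides(tibble::tibble(id = "PF1408", sequence = seq))
  expect_equal(call$sp_class, "LIPOPROTEIN")
  expect_equal(call$cleavage_after, 22L)
})

test_that("an uncharged N-terminus is never called an SPase I substrate", {
  seq <- paste0("M", strrep("A", 40))
  call <- classify_signal_peptides(tibble::tibble(id = "polyA", sequence = seq))
  expect_equal(call$sp_class, "NONE")
  expect_equal(call$cleavage_after, 0L)
})

test_that("invalid residues raise an error naming the offender", {
  bad <- tibble::tibble(id = "bad1", sequence = "MKKLLZLLAAA")
  expect_error(classify_signal_peptides(bad), "'Z'.*bad1",
               class = "secretr_error_alphabet")
})

test_that("classification is deterministic and local to the N-terminal prefix", {
  ref <- ref_proteins()
  c1 <- tidy(classify_signal_peptides(ref))
  c2 <- tidy(classify_signal_peptides(ref))
  expect_identical(c1, c2)

  # appending residues beyond the analysis prefix never changes a call
  withr::local_seed(42)
  tails <- vapply(seq_len(nrow(ref)), function(i) {
    paste(sample(AMINO_ACIDS, 50, replace = TRUE), collapse = "")
  }, character(1))
  ext <- ref
  ext$sequence <- vapply(ext$sequence, function(s) {
    paste0(s, strrep("A", max(0, 31 - nchar(s)))) # pad up to the prefix first
  }, character(1))
  base <- classify_signal_peptides(ext)
  ext2 <- ext
  ext2$sequence <- paste0(ext2$sequence, tails)
  long <- classify_signal_peptides(ext2)
  expect_equal(base$sp_class, long$sp_class)
  expect_equal(base$cleavage_after, long$cleavage_after)
})

test_that("partition_by_charge splits on net charge and preserves order", {
  calls <- tibble::tibble(
    protein_id = c("a", "b", "c"),
    n_charge = c(2L, 0L, -1L)
  )
  part <- partition_by_charge(calls)
  expect_equal(part$positive$protein_id, "a")
  expect_equal(part$nonpositive$protein_id, c("b", "c"))

  allpos <- tibble::tibble(protein_id = c("a", "b"), n_charge = c(1L, 3L))
  expect_equal(nrow(partition_by_charge(allpos)$nonpositive), 0)
})

test_that("glance on calls summarises class counts", {
  g <- glance(ref_calls())
  expect_equal(g$n_spase_i, 7L)
  expect_equal(g$n_lipoprotein, 5L)
  expect_equal(g$n_class_iii, 3L)
  expect_equal(g$n_none, 0L)
  expect_equal(g$pct_secreted, 100)
})
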