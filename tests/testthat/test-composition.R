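# Cleavage-aligned windows, frequency matrices and composition summaries.

test_that("cleavage windows pad exactly to 16 upstream and 10 downstream residues", {
  calls <- ref_calls()

  # PF1774: signal peptide of length 18 -> upstream side holds residues
  # 3..18 unpadded; mature side is the printed decapeptide
  w <- align_cleavage_windows(calls[calls$protein_id == "PF1774", ])
  expect_equal(nchar(w$window), 26)
  expect_equal(substr(w$window, 1, 16), "RAIPVFLLIVLVWISG")
  expect_equal(substr(w$window, 17, 26), "CIGGGTSTIP")

  # a 12-residue signal peptide needs 4 leading pads
  short_sp <- tibble::tibble(
    protein_id = "s1", sp_class = "SPASE_I", cleavage_after = 12L,
    sequence = paste0("MKKLLLLLLLLA", strrep("Q", 12))
  )
  w2 <- align_cleavage_windows(short_sp)
  expect_equal(substr(w2$window, 1, 4), "----")

  # a 6-residue mature fragment needs 4 trailing pads
  short_mat <- tibble::tibble(
    protein_id = "s2", sp_class = "SPASE_I", cleavage_after = 20L,
    sequence = paste0("MKKLLLLLLLLLLLLSSSTA", "QQQQQQ")
  )
  w3 <- align_cleavage_windows(short_mat)
  expect_equal(substr(w3$window, 23, 26), "----")

  # class NONE cannot be aligned
  none <- tibble::tibble(protein_id = "n", sp_class = "NONE",
                         cleavage_after = 0L, sequence = "MAAAA")
  expect_error(align_cleavage_windows(none), class = "secretr_error_input")
})

test_that("windows rebuilt from calls reproduce the printed mature decapeptides", {
  ref <- ref_fragments()
  calls <- ref_calls()
  w <- align_cleavage_windows(calls)
  mature10 <- vapply(seq_len(nrow(ref)), function(i) {
    m <- substr(ref$sequence[i], ref$cleavage_after[i] + 1,
                ref$cleavage_after[i] + 10)
    paste0(m, strrep("-", 10 - nchar(m)))
  }, character(1))
  expect_equal(substr(w$window, 17, 26), mature10)
})

test_that("frequency matrix normalises per position over non-gap residues", {
  calls <- ref_calls()
  lipo <- calls[calls$sp_class == "LIPOPROTEIN", ]
  fm <- frequency_matrix(align_cleavage_windows(lipo))

  # every lipoprotein window reads C at +1 and I at +2
  expect_equal(fm$freq[fm$position == 1 & fm$residue == "C"], 1)
  expect_equal(fm$freq[fm$position == 2 & fm$residue == "I"], 1)

  # per-position frequencies sum to 1 and counts to the non-gap windows
  sums <- tapply(fm$freq, fm$position, sum, na.rm = TRUE)
  expect_true(all(abs(sums - 1) < 1e-9))
  counts <- tapply(fm$count, fm$position, sum)
  expect_true(all(counts <= nrow(lipo)))
  expect_equal(unname(counts[["-1"]]), nrow(lipo))

  # permutation invariance
  w <- align_cleavage_windows(lipo)
  fm2 <- frequency_matrix(w[rev(seq_len(nrow(w))), ])
  expect_equal(tidy(fm), tidy(fm2))

  # degenerate inputs
  one <- frequency_matrix(w[1, ])
  expect_true(all(one$freq[one$count > 0] == 1))
  expect_error(frequency_matrix(w[0, ]), class = "secretr_error_input")
})

test_that("position dominance reports the argmax with tie handling", {
  calls <- ref_calls()
  spi <- calls[calls$sp_class == "SPASE_I", ]
  fm <- frequency_matrix(align_cleavage_windows(spi))
  dom <- position_dominance(fm, -1)
  expect_equal(dom$residue, "A")
  expect_equal(dom$freq, 1)
  expect_equal(dom$count, 7L)
  expect_false(dom$tie)

  # a 50/50 column is flagged as a tie and broken alphabetically
  w2 <- tibble::tibble(
    protein_id = c("x", "y"), sp_class = "SPASE_I",
    window = c(paste0(strrep("A", 16), strrep("L", 10)),
               paste0(strrep("G", 16), strrep("L", 10)))
  )
  dom2 <- position_dominance(frequency_matrix(w2), -5)
  expect_true(dom2$tie)
  expect_equal(dom2$residue, "A")
})

test_that("basic-residue usage favours lysine over arginine in verified n-regions", {
  toy <- tibble::tibble(
    protein_id = c("a", "b"), n_end = c(3L, 3L),
    sequence = c("MKKLLLLLL", "MRRLLLLLL")
  )
  u <- basic_residue_usage(toy)
  expect_equal(u$share[u$residue == "K"], 0.5)
  expect_equal(u$share[u$residue == "R"], 0.5)
  expect_equal(sum(u$share), 1)

  allk <- tibble::tibble(protein_id = "a", n_end = 4L, sequence = "MKKKLLL")
  expect_equal(basic_residue_usage(allk)$share[1], 1)

  u15 <- basic_residue_usage(ref_calls())
  expect_gt(u15$share[u15$residue == "K"], u15$share[u15$residue == "R"])

  nobase <- tibble::tibble(protein_id = "a", n_end = 3L, sequence = "MSSLLLLL")
  expect_error(basic_residue_usage(nobase), class = "secretr_error_input")
})

test_that("signal-peptide length ranges match the verified secretome", {
  ls <- length_summary(ref_calls())
  spi <- ls[ls$sp_class == "SPASE_I", ]
  expect_equal(c(spi$min_len, spi$max_len), c(24, 28))
  lipo <- ls[ls$sp_class == "LIPOPROTEIN", ]
  expect_equal(c(lipo$min_len, lipo$max_len), c(18, 22))

  one <- length_summary(ref_calls()[3, ])
  expect_equal(one$min_len, one$max_len)
  expect_equal(one$min_len, one$mean_len)
})
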