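test_that("binary profile puts one-hot blocks at the hand-derived coordinates", {
  # ranks: A=0 C=1 D=2 E=3 F=4 G=5 H=6 -> 20*i + m, 0-based
  v <- encode_bpf("ACDEFGH")
  expect_equal(which(v == 1) - 1L, c(0L, 21L, 42L, 63L, 84L, 105L, 126L))
  expect_equal(sum(v), 7)

  v <- encode_bpf("AAAAAAAA")            # eighth residue ignored
  expect_equal(which(v == 1) - 1L, seq(0L, 120L, by = 20L))

  v <- encode_bpf("KR")                   # K rank 8, R rank 14
  expect_equal(which(v == 1) - 1L, c(8L, 34L))
  expect_true(all(v[41:140] == 0))
})

test_that("binary profile has exactly min(7, L) ones for random sequences", {
  set.seed(1)
  for (L in c(1, 3, 6, 7, 8, 20, 60)) {
    v <- encode_bpf(random_peptide(L))
    expect_equal(sum(v), min(7, L))
    expect_true(all(v %in% c(0, 1)))
    blocks <- matrix(v, nrow = 20)
    expect_true(all(colSums(blocks) <= 1))
  }
})

test_that("ordinal positional encoding codes rank m at position l as m*40+l", {
  v <- encode_ope("AAAAADAA")            # D (rank 2) at 0-based position 5
  expect_equal(v[6], 2 * 40 + 5)

  v <- encode_ope("A")
  expect_equal(v[1], 0)
  expect_true(all(v[2:40] == -1))

  v <- encode_ope(strrep("K", 45))        # truncated at 40, no padding left
  expect_equal(length(v), 40L)
  expect_false(any(v == -1))

  set.seed(2)
  for (L in c(1, 10, 39, 40, 41)) {
    v <- encode_ope(random_peptide(L))
    expect_true(all(v == -1 | (v >= 0 & v <= 799)))
  }
  expect_equal(encode_ope(paste0(strrep("A", 39), "Y"))[40], 799)
  expect_false(799 %in% encode_ope(paste0(strrep("Y", 39), "A")))
})

test_that("group-pair composition matches hand counts on tiny cases", {
  v <- encode_cksaagp("GF")               # one 0-spaced (G1,G2) pair, L-1 = 1
  k0 <- v[1:25]
  expect_equal(k0[2], 1.0)                # pair (G1,G2) is position 2
  expect_equal(sum(k0), 1.0)
  expect_true(all(v[26:150] == 0))

  v <- encode_cksaagp("GGGG")             # k=2: single pair (1,4), group G1G1
  k2 <- v[51:75]
  expect_equal(k2[1], 1 / (4 - 3))
})

test_that("group-pair composition agrees with the pair-enumeration oracle", {
  set.seed(42)
  for (i in 1:120) {
    s <- random_peptide(sample(2:60, 1))
    expect_equal(encode_cksaagp(s), oracle_cksaagp(s))
  }
  # short sequences: blocks with L <= k+1 are all zero
  expect_equal(encode_cksaagp("K"), rep(0, 150))
})

test_that("each group-pair block with L > k+1 sums to one", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(2:60, 1)
    v <- encode_cksaagp(random_peptide(L))
    for (k in 0:5) {
      block_sum <- sum(v[(25 * k + 1):(25 * k + 25)])
      expect_equal(block_sum, if (L > k + 1) 1 else 0)
    }
  }
})

test_that("amino acid composition is the residue frequency vector", {
  v <- encode_aac("KK")
  expect_equal(v[match("K", AA20)], 1.0)
  expect_equal(sum(v), 1.0)

  v <- encode_aac("ACACACAC")
  expect_equal(v[match("A", AA20)], 0.5)
  expect_equal(v[match("C", AA20)], 0.5)

  set.seed(3)
  for (i in 1:10) {
    s1 <- random_peptide(12)
    s2 <- random_peptide(12)
    expect_equal(encode_aac(paste0(s1, s2)),
                 (encode_aac(s1) + encode_aac(s2)) / 2)
    expect_equal(sum(encode_aac(s1)), 1.0)
  }
})

test_that("positional index features follow the count x 40 contract", {
  tab2 <- toy_index_table(2)
  v <- encode_aaindex_positional("A", tab2)
  expect_length(v, 80L)
  expect_equal(unname(v[1]), tab2["scale01", "A"])
  expect_true(all(v[2:40] == 0))          # padded positions of scale 1
  expect_true(all(v[42:80] == 0))

  const <- as_index_table(matrix(2.5, 2, 20,
                                 dimnames = list(c("c1", "c2"), AA20)))
  v <- encode_aaindex_positional(random_peptide(40), const)
  expect_true(all(v == 2.5))

  big <- as_index_table(matrix(rnorm(531 * 20), 531, 20,
                               dimnames = list(sprintf("s%03d", 1:531), AA20)))
  expect_length(encode_aaindex_positional("KLAK", big), 21240L)
})

test_that("index table readers accept TSV and AAindex flat formats", {
  tab <- default_index_table()
  expect_s3_class(tab, "aa_index_table")
  expect_gte(nrow(tab), 20L)
  expect_equal(colnames(tab), AA20)
  expect_equal(unname(tab["hydropathy_kd", "I"]), 4.5)

  # flat-file values are listed in ARNDCQEGHI / LKMFPSTWYV order
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("H TEST0001", "I  A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V",
               paste(1:10, collapse = "  "), paste(11:20, collapse = "  "),
               "//",
               "H TEST0002", "I  ...",
               paste(rep(0.5, 10), collapse = " "), paste(rep(1.5, 10), collapse = " "),
               "//"), f)
  flat <- read_index_table(f)
  expect_equal(nrow(flat), 2L)
  expect_equal(unname(flat["TEST0001", "A"]), 1)
  expect_equal(unname(flat["TEST0001", "R"]), 2)
  expect_equal(unname(flat["TEST0001", "V"]), 20)
  expect_equal(unname(flat["TEST0002", "Y"]), 1.5)
})

test_that("fitted pipeline freezes the 140/40/150/20/n layout", {
  fx <- toy_features()
  layout <- fx$encoder$layout
  expect_equal(layout$width, c(140L, 40L, 150L, 20L, 50L))
  expect_equal(layout$offset, c(0L, 140L, 180L, 330L, 350L))
  expect_equal(attr(layout, "total_width"), 400L)

  enc10 <- fit_encoder(fx$data, table = toy_index_table(3), n_aaif = 10)
  expect_equal(attr(enc10$layout, "total_width"), 140 + 40 + 150 + 20 + 10)
  expect_error(fit_encoder(fx$data, table = toy_index_table(2), n_aaif = 100),
               "candidate")
})

test_that("encoded vectors satisfy the segment invariants", {
  fx <- toy_features()
  feats <- fx$features
  expect_equal(nrow(feats$x), nrow(fx$data))
  aac <- feats$x[, layout_segment(feats$layout, "AAC"), drop = FALSE]
  expect_true(all(aac >= 0 & aac <= 1))
  expect_equal(unname(rowSums(aac)), rep(1, nrow(aac)))
  bpf <- feats$x[, layout_segment(feats$layout, "BPF"), drop = FALSE]
  expect_true(all(bpf %in% c(0, 1)))

  # concatenation consistency with the standalone encoders
  i <- 3L
  s <- fx$data$sequence[i]
  expect_equal(unname(feats$x[i, 1:140]), encode_bpf(s))
  expect_equal(unname(feats$x[i, 181:330]), encode_cksaagp(s))
  expect_equal(unname(feats$x[i, 331:350]), encode_aac(s))

  # determinism of the fitted state
  expect_identical(encode_sequence(s, fx$encoder), encode_sequence(s, fx$encoder))
})

test_that("encoder state round-trips through its sidecar file", {
  fx <- toy_features()
  f <- withr::local_tempfile(fileext = ".rds")
  save_encoder(fx$encoder, f)
  enc2 <- load_encoder(f)
  s <- fx$data$sequence[1]
  expect_identical(encode_sequence(s, enc2), encode_sequence(s, fx$encoder))
})
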