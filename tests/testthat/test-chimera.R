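test_that("chimera concatenation keeps miRNA as prefix and caps at 110", {
  set.seed(21)
  mirna <- rand_rna(21)
  site <- rand_rna(89)
  chim <- concatenate_chimera(mirna, site)
  expect_identical(nchar(chim), 110L)
  expect_identical(substr(chim, 1, 21), mirna)
  expect_error(concatenate_chimera(rand_rna(22), rand_rna(90)),
               class = "mircnn_chimera_too_long")
  expect_error(concatenate_chimera(mirna, ""))
})

test_that("generated pads never complement the miRNA over 4-mers", {
  set.seed(22)
  expect_identical(generate_pad(rand_rna(21), 0), "")
  for (trial in 1:20) {
    mirna <- rand_rna(21)
    pad <- generate_pad(mirna, 20, seed = 1000L + trial)
    expect_identical(nchar(pad), 20L)
    expect_identical(count_pad_pair_hits(pad, mirna), 0L)
  }
  expect_identical(generate_pad("ACGUACGUACGUACGUACGUA", 30, seed = 9L),
                   generate_pad("ACGUACGUACGUACGUACGUA", 30, seed = 9L))
})

test_that("padding preserves the raw chimera as prefix and hits 110", {
  set.seed(23)
  mirna <- rand_rna(21)
  raw110 <- paste0(mirna, rand_rna(89))
  expect_identical(pad_chimera(raw110, mirna), raw110)
  raw95 <- paste0(mirna, rand_rna(74))
  full <- pad_chimera(raw95, mirna, seed = 4L)
  expect_identical(nchar(full), 110L)
  expect_identical(substr(full, 1, 95), raw95)
  expect_identical(count_pad_pair_hits(substr(full, 96, 110), mirna), 0L)
  expect_error(pad_chimera(rand_rna(111), mirna),
               class = "mircnn_chimera_too_long")
})

test_that("one-hot encoding follows the A,U,G,C convention and inverts", {
  seq1 <- paste0("A", rand_rna(109))
  m <- encode_one_hot(seq1)
  expect_identical(dim(m), c(110L, 4L))
  expect_identical(unname(m[1, ]), c(1L, 0L, 0L, 0L))
  expect_true(all(rowSums(m) == 1L))
  set.seed(24)
  for (i in 1:10) {
    s <- rand_rna(110)
    expect_identical(decode_one_hot(encode_one_hot(s)), s)
  }
  expect_error(encode_one_hot(rand_rna(50)), "110")
})

test_that("encode_batch produces an aligned n x 110 x 4 tensor", {
  tab <- toy_table(5)
  b <- encode_batch(tab)
  expect_identical(dim(b$data), c(5L, 110L, 4L))
  expect_identical(b$labels, tab$label)
  expect_identical(decode_one_hot(matrix(as.integer(b$data[3, , ]),
                                         110, 4)),
                   tab$chimera_seq[3])
})

make_tx_fixture <- function(n_tx = 10, seed = 30) {
  cfg <- synth_config(n_transcripts = n_tx, seed = seed)
  gen_transcripts(cfg)
}

test_that("pseudo-negatives follow the 7:2:1 region ratio exactly", {
  txs <- make_tx_fixture()
  mirnas <- gen_mirnas(synth_config(n_mirnas = 5, seed = 30))
  neg <- sample_negative_sites(txs$records, txs$regions, 10, mirnas,
                               seed = 31)
  expect_identical(as.integer(table(neg$region)[c("UTR3", "UTR5", "ORF")]),
                   c(7L, 2L, 1L))
  expect_identical(nrow(sample_negative_sites(txs$records, txs$regions, 0,
                                              mirnas)), 0L)
  # larger draw: apportionment keeps fractions within 1% of 0.7/0.2/0.1
  neg2 <- sample_negative_sites(txs$records, txs$regions, 1000, mirnas,
                                seed = 32)
  frac <- table(neg2$region)[c("UTR3", "UTR5", "ORF")] / 1000
  expect_true(all(abs(frac - c(0.7, 0.2, 0.1)) <= 0.01))
  expect_true(all(nchar(neg2$full_seq) == 110L))
  expect_true(all(neg2$pad_seq == ""))
  expect_true(all(neg2$label == 0L))
})

test_that("forbidden miRNA:gene pairs are never produced", {
  txs <- make_tx_fixture()
  mirnas <- gen_mirnas(synth_config(n_mirnas = 3, seed = 33))
  forb <- expand.grid(mirna_id = mirnas$id,
                      transcript_id = txs$records$id[1:8],
                      stringsAsFactors = FALSE)
  neg <- sample_negative_sites(txs$records, txs$regions, 50, mirnas,
                               forbidden_pairs = forb, seed = 34)
  made <- paste(neg$mirna_id, neg$transcript_id)
  expect_length(intersect(made, paste(forb$mirna_id, forb$transcript_id)),
                0)
})

test_that("negative generation is deterministic under a seed", {
  txs <- make_tx_fixture()
  mirnas <- gen_mirnas(synth_config(n_mirnas = 5, seed = 30))
  a <- sample_negative_sites(txs$records, txs$regions, 30, mirnas,
                             seed = 35)
  b <- sample_negative_sites(txs$records, txs$regions, 30, mirnas,
                             seed = 35)
  expect_identical(a, b)
})

test_that("train/validation/test split partitions the table", {
  tab <- toy_table(100)
  parts <- split_dataset(tab, c(80, 10, 10), seed = 40)
  expect_identical(vapply(parts, nrow, integer(1)),
                   c(train = 80L, validation = 10L, test = 10L))
  all_rows <- sort(do.call(rbind, parts)$chimera_seq)
  expect_identical(all_rows, sort(tab$chimera_seq))
  parts2 <- split_dataset(tab, c(80, 10, 10), seed = 40)
  expect_identical(parts, parts2)
  # same seed, shuffled input rows: same multiset membership per split
  set.seed(99)
  shuf <- tab[sample.int(100), ]
  rownames(shuf) <- NULL
  expect_setequal(split_dataset(shuf, c(80, 10, 10), seed = 41)$train$chimera_seq,
                  split_dataset(tab, c(80, 10, 10), seed = 41)$train$chimera_seq)
  expect_error(split_dataset(tab, c(80, 10, 5), seed = 1), "summing")
})

test_that("k-fold split gives balanced, exhaustive, disjoint folds", {
  tab <- toy_table(10)
  folds <- kfold_split(tab, 3, seed = 42)
  expect_identical(sort(vapply(folds, nrow, integer(1)),
                        decreasing = TRUE), c(4L, 3L, 3L))
  expect_identical(sort(unlist(lapply(folds, `[[`, "chimera_seq"))),
                   sort(tab$chimera_seq))
  expect_error(kfold_split(tab, 1), "at least 2")
  expect_error(kfold_split(tab, 11), "exceeds")
  strat <- kfold_split(toy_table(40), 4, seed = 43, stratify = TRUE)
  pos_per_fold <- vapply(strat, function(f) sum(f$label), integer(1))
  expect_true(max(pos_per_fold) - min(pos_per_fold) <= 1L)
})
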