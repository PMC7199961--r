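# An untrained model (fresh random weights) is enough for the structural
# scanner properties; classification quality is covered elsewhere.
fresh_model <- function(seed = 1L) {
  arch <- build_architecture()
  set.seed(seed)
  structure(list(arch = arch, weights = mircnn:::init_weights(arch),
                 training_log = NULL, config = training_config(seed = seed),
                 best_epoch = 0L),
            class = "mircnn_model")
}

test_that("candidate enumeration covers the transcript with w-length windows", {
  mirna <- list(id = "m", seq = paste(rep("A", 21), collapse = ""))
  set.seed(801)
  # transcript exactly one window long -> a single full-width candidate
  tx <- list(id = "t1", seq = rand_rna(89))
  c1 <- enumerate_candidates(mirna, tx, step = 10)
  expect_identical(nrow(c1), 1L)
  expect_identical(c(c1$start, c1$end), c(0L, 89L))
  # 200-nt transcript, w = 89, step 10: offsets 0..110 plus final window
  tx2 <- list(id = "t2", seq = rand_rna(200))
  c2 <- enumerate_candidates(mirna, tx2, step = 10)
  expect_identical(nrow(c2), 13L)
  expect_identical(c2$start, c(seq(0L, 110L, 10L), 111L))
  expect_true(all(c2$end - c2$start == 89L))
  expect_identical(c2$end[13], 200L)
  expect_identical(c2$site_seq[5],
                   substr(normalize_sequence(tx2$seq), 41, 129))
  expect_error(enumerate_candidates(mirna, list(id = "t", seq = "ACGU")),
               "too short")
})

test_that("a pairing-free transcript yields no survivors and call FALSE", {
  m <- fresh_model()
  mirna <- list(id = "m", seq = paste(rep(c("A", "A", "G"), 7),
                                      collapse = ""))
  tx <- list(id = "t", seq = paste(rep("A", 150), collapse = ""))
  res <- scan_transcript(m, mirna, tx)
  expect_identical(nrow(res$sites), 0L)
  expect_identical(res$max_score, 0)
  expect_false(res$call)
  expect_gt(res$n_candidates, 0L)
})

test_that("max aggregation and threshold semantics drive the call", {
  m <- fresh_model()
  set.seed(802)
  mirna <- list(id = "m", seq = rand_rna(21))
  site <- revcomp_rna(mirna$seq)
  tx <- list(id = "t", seq = paste0(rand_rna(60), site, rand_rna(60)))
  res <- scan_transcript(m, mirna, tx, step = 5, seed = 3L)
  expect_gt(nrow(res$sites), 0L)
  expect_identical(res$max_score, max(res$sites$score))
  # raising the call threshold above the max flips the call, nothing else
  res_hi <- scan_transcript(m, mirna, tx, step = 5, seed = 3L,
                            call_threshold = res$max_score + 0.01)
  expect_false(res_hi$call)
  expect_identical(res_hi$max_score, res$max_score)
  expect_identical(res$call, res$max_score > 0.5)
})

test_that("denser strides scan a superset of windows (max monotone)", {
  m <- fresh_model()
  set.seed(803)
  mirna <- list(id = "m", seq = rand_rna(21))
  site <- revcomp_rna(mirna$seq)
  tx <- list(id = "t", seq = paste0(rand_rna(45), site, rand_rna(45)))
  r5 <- scan_transcript(m, mirna, tx, step = 5, seed = 4L)
  r1 <- scan_transcript(m, mirna, tx, step = 1, seed = 4L)
  expect_gte(r1$n_candidates, r5$n_candidates)
  expect_gte(r1$max_score, r5$max_score)
})

test_that("tightening the energy filter never adds survivors", {
  m <- fresh_model()
  set.seed(804)
  mirna <- list(id = "m", seq = rand_rna(21))
  tx <- list(id = "t",
             seq = paste0(rand_rna(40), revcomp_rna(mirna$seq),
                          rand_rna(40)))
  loose <- scan_transcript(m, mirna, tx, mfe_threshold = -10, seed = 5L)
  tight <- scan_transcript(m, mirna, tx, mfe_threshold = -30, seed = 5L)
  expect_lte(nrow(tight$sites), nrow(loose$sites))
})

test_that("scan_many reports one row per pair and skips failures", {
  m <- fresh_model()
  set.seed(805)
  mirnas <- data.frame(id = c("m1", "m2"),
                       seq = c(rand_rna(21), rand_rna(21)),
                       stringsAsFactors = FALSE)
  txs <- data.frame(id = c("t1", "t2", "t3"),
                    seq = c(rand_rna(120), rand_rna(150), rand_rna(100)),
                    stringsAsFactors = FALSE)
  res <- scan_many(m, mirnas, txs, seed = 6L)
  expect_identical(nrow(res), 6L)
  expect_identical(res$mirna_id, rep(c("m1", "m2"), each = 3))
  # identical pair repeated gives identical results
  res2 <- scan_many(m, mirnas[c(1, 1), ], txs[1, , drop = FALSE],
                    seed = 6L)
  expect_identical(res2$max_score[1], res2$max_score[2])
  # an unscannable transcript is skipped with a warning, not fatal
  txs_bad <- rbind(txs, data.frame(id = "short", seq = "ACGU"))
  expect_warning(res3 <- scan_many(m, mirnas[1, , drop = FALSE], txs_bad,
                                   seed = 6L),
                 "skipping")
  expect_identical(nrow(res3), 3L)
  expect_identical(nrow(scan_many(m, mirnas, txs[0, , drop = FALSE])), 0L)
})
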