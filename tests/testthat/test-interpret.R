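# Attention attribution and position-wise residue enrichment.

small_fit <- function(ds, d = 12L, epochs = 2L, positional = TRUE) {
  bwr_fit(ds, cfg = small_cfg(d = d, positional = positional),
          embed_dim = d, embed_epochs = 2L, lr = 1e-3, epochs = epochs,
          seed = 11)
}

test_that("attention maps are normalized and near-uniform for an untrained model", {
  ds <- generate_dataset(synth_spec(n_pos = 50, n_neg = 50, seed = 31))
  fit <- small_fit(ds, epochs = 0L)   # epochs = 0 -> weights at initialization
  am2 <- attention_position_weights(fit, ds, channel = 2)
  expect_equal(sum(am2$weights), 1)
  expect_true(all(am2$weights >= 0))
  expect_length(am2$weights, fit$cfg$len2)
  # glorot-scale Q.K products are tiny, so softmax is near-uniform
  expect_lt(max(am2$weights) - min(am2$weights), 0.05)

  am1 <- attention_position_weights(fit, ds, channel = 1)
  expect_equal(sum(am1$weights), 1)
})

test_that("attention reduction errors when the channel's transformers are absent", {
  ds <- generate_dataset(synth_spec(n_pos = 10, n_neg = 10, seed = 32))
  fit <- bwr_fit(ds, cfg = small_cfg(d = 12L, seq2 = "none"),
                 embed_dim = 12L, embed_epochs = 2L, lr = 1e-3, epochs = 1L,
                 seed = 1)
  expect_error(attention_position_weights(fit, ds, channel = 2),
               "no transformer")
})

test_that("attention reduction is permutation-covariant without positional encodings", {
  ds <- generate_dataset(synth_spec(n_pos = 12, n_neg = 12, min_len = 30,
                                    max_len = 30, seed = 33))
  fit <- small_fit(ds, epochs = 0L, positional = FALSE)
  m2 <- fit$embeddings$m2
  enc <- biowords:::encode_for_net(ds$sequence, fit$embeddings$m1, m2,
                                   fit$cfg$len1, fit$cfg$len2)
  # run channel 2 on one sample and on a position-permuted copy
  mha <- biowords:::last_mha(fit$net, 2L)
  mha$capture <- TRUE
  L <- fit$cfg$len2
  x <- biowords:::embed_rows(enc$idx2[1, , drop = FALSE], enc$V2)
  z <- list(x = x, B = 1L, L = L)
  for (ly in fit$net$ch2) z <- biowords:::layer_forward(ly, z, FALSE)
  P_orig <- mha$attn[[1]][[1]]
  set.seed(3)
  perm <- sample(L)
  z <- list(x = x[perm, , drop = FALSE], B = 1L, L = L)
  for (ly in fit$net$ch2) z <- biowords:::layer_forward(ly, z, FALSE)
  P_perm <- mha$attn[[1]][[1]]
  mha$capture <- FALSE
  expect_equal(P_perm, P_orig[perm, perm], tolerance = 1e-10)
})

test_that("attention localizes an always-positioned motif after training", {
  # motif implanted at a fixed window in positives of fixed-length sequences
  set.seed(41)
  n <- 40
  bg <- function() random_peptide(20)
  pos <- vapply(seq_len(n), function(i) {
    s <- bg(); substr(s, 3, 7) <- "KWKLL"; s
  }, character(1))
  neg <- replicate(n, bg())
  ds <- data.frame(id = sprintf("s%d", 1:(2 * n)),
                   sequence = c(pos, neg),
                   label = rep(c(1L, 0L), each = n))
  fit <- bwr_fit(ds, cfg = small_cfg(d = 12L, positional = TRUE),
                 embed_dim = 12L, embed_epochs = 3L, lr = 2e-3, epochs = 6L,
                 max_len = 20L, seed = 17)
  am <- attention_position_weights(fit, ds[ds$label == 1, ], channel = 2)
  # 4mer tokens overlapping the motif window (residues 3-7 -> tokens 3-7 at
  # least partially); compare their mass against the uniform baseline
  motif_tokens <- 3:7
  expect_gt(sum(am$weights[motif_tokens]),
            length(motif_tokens) / length(am$weights))
})

test_that("enrichment on identical classes is exactly null", {
  seqs <- replicate(20, random_peptide(15))
  et <- position_residue_enrichment(seqs, seqs, length = 15)
  expect_true(all(et$diff == 0))
  expect_true(all(et$p == 1))
  expect_length(attr(et, "flagged"), 0L)
})

test_that("a constructed residue bias is detected at the right position", {
  set.seed(51)
  pos <- vapply(1:100, function(i) {
    s <- random_peptide(15)
    substr(s, 2, 2) <- "K"
    s
  }, character(1))
  neg <- replicate(100, random_peptide(15))
  et <- position_residue_enrichment(pos, neg, length = 15)
  k2 <- et[et$position == 2 & et$residue == "K", ]
  expect_equal(k2$freq_pos, 1)
  expect_gt(k2$diff, 0.85)          # 1 - 1/20 in expectation
  expect_lt(k2$p, 1e-6)
  expect_true(2 %in% attr(et, "flagged"))

  # per-position class frequencies each sum to 1
  sums <- tapply(et$freq_pos, et$position, sum)
  expect_equal(as.numeric(sums), rep(1, 15))
  sums_n <- tapply(et$freq_neg, et$position, sum)
  expect_equal(as.numeric(sums_n), rep(1, 15))
})

test_that("label-permuted enrichment keeps false cell flags near the type-I level", {
  set.seed(61)
  all_seqs <- replicate(120, random_peptide(12))
  sig_cells <- 0L
  n_cells <- 0L
  for (rep in 1:3) {
    pick <- sample(120, 60)
    et <- position_residue_enrichment(all_seqs[pick], all_seqs[-pick],
                                      length = 12)
    sig_cells <- sig_cells + sum(et$p < 0.05)
    n_cells <- n_cells + nrow(et)
  }
  # uncorrected per-cell tests at alpha = 0.05 on null data: the significant
  # fraction should sit near alpha (generous 1.5x margin for the normal
  # approximation's discreteness)
  expect_lte(sig_cells, ceiling(1.5 * 0.05 * n_cells))

  # Bonferroni mode is stricter
  et_b <- position_residue_enrichment(all_seqs[1:60], all_seqs[61:120],
                                      length = 12, bonferroni = TRUE)
  et_u <- position_residue_enrichment(all_seqs[1:60], all_seqs[61:120],
                                      length = 12)
  expect_lte(length(attr(et_b, "flagged")), length(attr(et_u, "flagged")))
})

test_that("length mismatches are reported with offending entries", {
  expect_error(position_residue_enrichment(c("ACDEF", "ACD"), "ACDEF", 5),
               "pos\\[2\\]")
  expect_error(position_residue_enrichment(character(0), "ACDEF", 5),
               "non-empty")
})

test_that("feature export taps have the documented shapes", {
  ds <- generate_dataset(synth_spec(n_pos = 8, n_neg = 8, seed = 71))
  fit <- small_fit(ds, epochs = 1L)
  fx <- feature_projection_export(fit, ds, "fusion-dense")
  expect_equal(dim(fx$features),
               c(nrow(ds), fit$cfg$fusion[length(fit$cfg$fusion)]))
  expect_identical(fx$labels, ds$label)
  f1 <- feature_projection_export(fit, ds, "input-1mer")
  expect_equal(dim(f1$features), c(nrow(ds), fit$cfg$len1 * fit$cfg$d))
  f2 <- feature_projection_export(fit, ds, "input-4mer")
  expect_equal(dim(f2$features), c(nrow(ds), fit$cfg$len2 * fit$cfg$d))
  expect_error(feature_projection_export(fit, ds, "nope"))
})
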