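# Architecture: shape calculus, realized models, variants, ablations.

test_that("the default shape plan reproduces the published architecture arithmetic", {
  plan <- shape_plan(channel_config())
  row <- function(stage, layer) plan[plan$stage == stage & plan$layer == layer, ]
  expect_equal(row("channel1", "Conv1D_1")$out_len, 98L)
  expect_equal(row("channel1", "Conv1D_1")$out_dim, 128L)
  expect_equal(row("channel1", "Conv1D_3")$out_len, 94L)
  expect_equal(row("channel1", "Conv1D_3")$out_dim, 256L)
  expect_equal(row("channel1", "MaxPooling1D")$out_len, 92L)
  expect_equal(attr(plan, "flatten1"), 92L * 256L)   # 23552
  expect_equal(attr(plan, "flatten1"), 23552L)
  expect_equal(row("channel2", "Input")$out_len, 97L)
  expect_equal(attr(plan, "flatten2"), 14550L)
  expect_equal(attr(plan, "fused"), 32L + 14550L)    # 14582
  expect_equal(plan[plan$layer == "Output", "out_dim"], 1L)
})

test_that("degenerate configurations error naming the offending layer", {
  expect_error(shape_plan(channel_config(len1 = 100L, conv_kernel = 101L)),
               "Conv1D_1")
  expect_error(shape_plan(channel_config(len1 = 5L, pool_width = 3L)),
               "non-positive|MaxPooling1D")
  expect_error(channel_config(channel1 = FALSE, channel2 = FALSE),
               "at least one channel")
})

test_that("realized layer shapes equal the shape plan for assorted configs", {
  cfgs <- list(tiny_cfg(),
               tiny_cfg(seq1 = "gru", seq2 = "gru", seq_width1 = 5L,
                        seq_width2 = 5L),
               tiny_cfg(seq1 = "tcn", seq2 = "bilstm", seq_width1 = 6L,
                        seq_width2 = 6L),
               tiny_cfg(use_cnn = FALSE),
               tiny_cfg(positional = FALSE))
  for (cfg in cfgs) {
    net <- build_model(cfg, seed = 3)   # build_model self-checks against plan
    realized <- biowords:::realized_shapes(net)
    want <- biowords:::plan_layerwise(net)
    expect_equal(nrow(realized), nrow(want))
    expect_equal(realized$out_dim, want$out_dim)
  }
})

test_that("a zero-input forward pass yields finite probabilities", {
  cfg <- tiny_cfg()
  net <- build_model(cfg, seed = 1)
  x1 <- list(x = matrix(0, 2 * cfg$len1, cfg$d), B = 2L, L = cfg$len1)
  x2 <- list(x = matrix(0, 2 * cfg$len2, cfg$d), B = 2L, L = cfg$len2)
  out <- biowords:::net_forward(net, x1, x2)
  expect_length(out$p, 2L)
  expect_true(all(is.finite(out$p) & out$p >= 0 & out$p <= 1))
})

test_that("builds are deterministic: same seed, same initial predictions", {
  cfg <- tiny_cfg()
  set.seed(31)
  x1 <- list(x = matrix(rnorm(2 * cfg$len1 * cfg$d), ncol = cfg$d), B = 2L,
             L = cfg$len1)
  x2 <- list(x = matrix(rnorm(2 * cfg$len2 * cfg$d), ncol = cfg$d), B = 2L,
             L = cfg$len2)
  p1 <- biowords:::net_forward(build_model(cfg, seed = 5), x1, x2)$p
  p2 <- biowords:::net_forward(build_model(cfg, seed = 5), x1, x2)$p
  p3 <- biowords:::net_forward(build_model(cfg, seed = 6), x1, x2)$p
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("parameter count is stable across rebuilds and positive", {
  n1 <- n_params(build_model(tiny_cfg(), seed = 1))
  n2 <- n_params(build_model(tiny_cfg(), seed = 99))
  expect_identical(n1, n2)
  expect_gt(n1, 0)
})

test_that("analytic gradients of every layer type match finite differences", {
  expect_gradients_match(fd_check_net(tiny_cfg(), per_param = 3))
  expect_gradients_match(fd_check_net(tiny_cfg(seq1 = "lstm", seq2 = "gru",
                                               seq_width1 = 5L,
                                               seq_width2 = 5L),
                                      per_param = 3))
  expect_gradients_match(fd_check_net(tiny_cfg(seq1 = "bigru", seq2 = "tcn",
                                               seq_width1 = 6L,
                                               seq_width2 = 6L),
                                      per_param = 3))
})

test_that("build_variant swaps both sequence modules and rejects unknown kinds", {
  for (kind in c("bilstm", "tcn", "lstm", "gru", "bigru")) {
    net <- build_variant(kind, tiny_cfg(seq_width1 = 6L, seq_width2 = 6L),
                         seed = 2)
    expect_s3_class(net, "bwr_net")
    expect_identical(net$cfg$seq1, kind)
    expect_identical(net$cfg$seq2, kind)
  }
  expect_error(build_variant("cnnx", tiny_cfg()), "bilstm.*tcn.*lstm")
})

test_that("ablation variants realize the six-module grid", {
  cfg <- tiny_cfg()
  # full model: identical to build_model with the same seed
  full <- build_ablation(TRUE, TRUE, TRUE, cfg, seed = 4)
  ref <- build_model(cfg, seed = 4)
  set.seed(77)
  x1 <- list(x = matrix(rnorm(2 * cfg$len1 * cfg$d), ncol = cfg$d), B = 2L,
             L = cfg$len1)
  x2 <- list(x = matrix(rnorm(2 * cfg$len2 * cfg$d), ncol = cfg$d), B = 2L,
             L = cfg$len2)
  expect_identical(biowords:::net_forward(full, x1, x2)$p,
                   biowords:::net_forward(ref, x1, x2)$p)

  # CNN-only: no transformers anywhere, channel 2 reduced to a flatten
  cnn_only <- build_ablation(TRUE, FALSE, FALSE, cfg, seed = 4)
  types2 <- vapply(cnn_only$ch2, function(l) l$type, character(1))
  expect_identical(types2, "flatten")
  expect_false(any(vapply(cnn_only$ch1, function(l) l$type, character(1)) ==
                   "transformer"))

  # channel-2-only: channel 1 absent entirely
  ch2_only <- build_ablation(FALSE, FALSE, TRUE, cfg, seed = 4)
  expect_length(ch2_only$ch1, 0L)
  out <- biowords:::net_forward(ch2_only, NULL, x2)
  expect_true(all(is.finite(out$p)))

  # no CNN: channel-1 transformers consume the raw embedding
  no_cnn <- build_ablation(FALSE, TRUE, TRUE, cfg, seed = 4)
  types1 <- vapply(no_cnn$ch1, function(l) l$type, character(1))
  expect_false(any(types1 %in% c("conv1d", "maxpool")))
  expect_true(any(types1 == "transformer"))

  expect_error(build_ablation(FALSE, FALSE, FALSE, cfg), "all modules disabled")
})

test_that("channel configurations round-trip through the flat key-value file", {
  cfg <- channel_config(d = 32L, conv_filters = c(8L, 8L, 16L),
                        blocks1 = 2L, heads1 = 2L, dropout_dense = 0.25,
                        seq2 = "gru", seq_width2 = 16L, positional = FALSE)
  f <- tempfile(fileext = ".cfg")
  write_channel_config(cfg, f)
  back <- read_channel_config(f)
  expect_equal(back, cfg)
  # the restored config drives the same shape plan
  expect_equal(shape_plan(back), shape_plan(cfg))
})

test_that("any built model can memorize a tiny labeled batch", {
  # capacity smoke test: 16 samples, loss driven well below chance level
  cfg <- tiny_cfg()
  set.seed(50)
  n <- 16L
  enc <- list(idx1 = matrix(sample(0:4, n * cfg$len1, TRUE), n, cfg$len1),
              idx2 = matrix(sample(0:4, n * cfg$len2, TRUE), n, cfg$len2),
              V1 = matrix(rnorm(5 * cfg$d), 5, cfg$d),
              V2 = matrix(rnorm(5 * cfg$d), 5, cfg$d))
  y <- rep(c(1, 0), n / 2)
  for (kind in c("transformer", "gru")) {
    cfg_k <- tiny_cfg(seq1 = kind, seq2 = kind, seq_width1 = 6L,
                      seq_width2 = 6L)
    net <- build_model(cfg_k, seed = 9)
    h <- nn_train(net, enc, y, lr = 1e-2, batch = 8, epochs = 250, seed = 9)
    expect_lt(min(h$loss), 0.05)
    expect_equal(max(h$acc), 1)
  }
})
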