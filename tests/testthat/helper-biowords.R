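# Shared fixtures and independent brute-force oracles used across the suite.

# small network configuration so gradient checks and smoke training stay fast
tiny_cfg <- function(...) {
  channel_config(d = 8, len1 = 12, len2 = 10,
                 conv_filters = c(6L, 6L, 8L), conv_kernel = 3L,
                 pool_width = 3L, blocks1 = 2L, blocks2 = 1L,
                 heads1 = 2L, heads2 = 2L, dense1 = c(10L, 6L),
                 fusion = c(6L, 4L), dropout_dense = 0, dropout_attn = 0,
                 ...)
}

# reduced-but-real configuration for pipeline smoke runs (d kept moderate)
small_cfg <- function(d = 24L, ...) {
  channel_config(d = d, conv_filters = c(16L, 16L, 24L),
                 blocks1 = 1L, blocks2 = 1L, heads1 = 2L, heads2 = 2L,
                 dense1 = c(24L, 12L), fusion = c(12L, 8L), ...)
}

random_peptide <- function(L) paste(sample(biowords:::AA_ALPHABET, L,
                                           replace = TRUE), collapse = "")

# brute-force k-mer enumeration, independent of tokenize_kmers
oracle_kmers <- function(seq, k, stride) {
  out <- character(0)
  i <- 1L
  while (i + k - 1L <= nchar(seq)) {
    out <- c(out, substr(seq, i, i + k - 1L))
    i <- i + stride
  }
  out
}

# O(n^2) pairwise AUROC oracle: fraction of (pos, neg) pairs ordered
# correctly, ties counting one half
oracle_auroc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# direct-formula MCC oracle
oracle_mcc <- function(TP, FP, TN, FN) {
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / den
}

# Finite-difference gradient check of a whole network's parameters against
# the analytic backward pass; samples `per_param` entries per tensor and
# returns the vector of relative errors.  Isolated large errors are expected
# where a ReLU/maxpool kink sits within eps of the evaluation point, so
# callers assert on the error distribution, not the maximum.
fd_check_net <- function(cfg, B = 3, per_param = 4, eps = 1e-6, seed = 5) {
  net <- build_model(cfg, seed = seed)
  set.seed(1234)
  y <- rbinom(B, 1, 0.5)
  x1 <- if (cfg$channel1)
    list(x = matrix(rnorm(B * cfg$len1 * cfg$d), B * cfg$len1, cfg$d),
         B = B, L = cfg$len1)
  x2 <- if (cfg$channel2)
    list(x = matrix(rnorm(B * cfg$len2 * cfg$d), B * cfg$len2, cfg$d),
         B = B, L = cfg$len2)
  loss_fn <- function() {
    out <- biowords:::net_forward(net, x1, x2, training = FALSE)
    biowords:::bce_loss(out$p, y)
  }
  out <- biowords:::net_forward(net, x1, x2, training = FALSE)
  biowords:::net_backward(net, (out$p - y) / B)
  layers <- biowords:::collect_layers(c(net$ch1, net$ch2, net$head))
  errs <- numeric(0)
  for (ly in layers) {
    for (nm in names(ly$params)) {
      P <- ly$params[[nm]]
      G <- ly$grads[[nm]]
      for (i in sample(length(P), min(per_param, length(P)))) {
        p0 <- P[i]
        ly$params[[nm]][i] <- p0 + eps; lp <- loss_fn()
        ly$params[[nm]][i] <- p0 - eps; lm <- loss_fn()
        ly$params[[nm]][i] <- p0
        fd <- (lp - lm) / (2 * eps)
        errs <- c(errs, abs(fd - G[i]) / max(1e-6, abs(fd), abs(G[i])))
      }
    }
  }
  errs
}

expect_gradients_match <- function(errs, tol = 1e-3) {
  expect_lt(stats::median(errs), tol)
  expect_gt(mean(errs < tol), 0.9)
}
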