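# Word2Vec: forward pass, exact-softmax gradients, training behaviour,
# sequence encoding.

test_that("cbow_forward implements the context-average + softmax equations", {
  set.seed(2)
  seqs <- replicate(5, random_peptide(12))
  m <- word2vec(seqs, k = 1, d = 6, epochs = 2, seed = 1)
  nv <- length(m$vocab$words)

  # single context word: hidden vector equals that word's embedding row
  f1 <- cbow_forward(m, 1L)
  expect_equal(f1$h, m$V[1, ])
  # general context: mean of rows
  ctx <- c(1L, 2L, min(3L, nv))
  f <- cbow_forward(m, ctx)
  expect_equal(f$h, colMeans(m$V[ctx, ]))
  # softmax normalization to 1e-9
  expect_lt(abs(sum(f$p) - 1), 1e-9)
  expect_true(all(f$p >= 0))

  # all-zero weights give the uniform distribution
  m0 <- m
  m0$M[] <- 0
  p0 <- cbow_forward(m0, ctx)$p
  expect_equal(p0, rep(1 / nv, nv))

  # softmax is invariant to adding a constant to all logits: adding one
  # fixed row vector to every output vector shifts each logit by delta . h
  mshift <- m
  delta <- rnorm(ncol(m$M))
  mshift$M <- m$M + matrix(delta, nrow(m$M), ncol(m$M), byrow = TRUE)
  expect_equal(cbow_forward(mshift, ctx)$p, f$p)

  expect_error(cbow_forward(m, integer(0)), "empty context")
})

test_that("analytic CBOW and Skip-gram gradients match finite differences", {
  set.seed(3)
  for (method in c("cbow", "skipgram")) {
    nv <- 3L; d <- 4L
    V <- matrix(rnorm(nv * d), nv, d)
    M <- matrix(rnorm(nv * d), nv, d)
    idx <- c(1L, 2L, 3L, 1L, 2L)
    pr <- biowords:::w2v_pairs(idx, t = 2L, method = method)
    A <- Matrix::sparseMatrix(i = pr$i, j = pr$j, x = pr$w,
                              dims = c(max(pr$i), nv))
    g <- biowords:::w2v_batch_grad(V, M, A, pr$target)
    worst <- 0
    for (mat in c("V", "M")) {
      P <- if (mat == "V") V else M
      G <- if (mat == "V") g$dV else g$dM
      for (i in seq_along(P)) {
        eps <- 1e-6
        p0 <- P[i]
        P[i] <- p0 + eps
        lp <- biowords:::w2v_batch_grad(if (mat == "V") P else V,
                                        if (mat == "M") P else M,
                                        A, pr$target, want_grad = FALSE)$ll
        P[i] <- p0 - eps
        lm <- biowords:::w2v_batch_grad(if (mat == "V") P else V,
                                        if (mat == "M") P else M,
                                        A, pr$target, want_grad = FALSE)$ll
        P[i] <- p0
        fd <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(fd - G[i]) / max(1e-8, abs(fd), abs(G[i])))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("mean log-likelihood improves over epochs on a structured corpus", {
  # corpus with strong co-occurrence structure (two residue cliques)
  set.seed(8)
  seqs <- c(replicate(10, paste(sample(c("A", "C", "D"), 15, TRUE), collapse = "")),
            replicate(10, paste(sample(c("K", "L", "R"), 15, TRUE), collapse = "")))
  for (method in c("cbow", "skipgram")) {
    m <- word2vec(seqs, k = 1, d = 8, epochs = 5, method = method, seed = 4)
    expect_gt(m$history[5], m$history[1])
  }
})

test_that("training is bit-deterministic given the seed", {
  set.seed(10)
  seqs <- replicate(8, random_peptide(15))
  m1 <- word2vec(seqs, k = 2, d = 6, epochs = 3, seed = 7)
  m2 <- word2vec(seqs, k = 2, d = 6, epochs = 3, seed = 7)
  expect_identical(m1$V, m2$V)
  expect_identical(m1$M, m2$M)
  m3 <- word2vec(seqs, k = 2, d = 6, epochs = 3, seed = 8)
  expect_false(identical(m1$V, m3$V))
})

test_that("a deterministic bigram corpus recovers the next word", {
  # K and L strictly alternate; with radius 1 the context determines the center
  seqs <- rep(paste(rep(c("K", "L"), 10), collapse = ""), 5)
  m <- word2vec(seqs, k = 1, d = 8, window = 1, epochs = 50, seed = 2)
  iK <- match("K", m$vocab$words); iL <- match("L", m$vocab$words)
  expect_equal(which.max(cbow_forward(m, iK)$p), iL)
  expect_equal(which.max(cbow_forward(m, iL)$p), iK)
})

test_that("words in identical contexts acquire similar embeddings", {
  # A and C are interchangeable within clique 1; K is from clique 2
  set.seed(12)
  seqs <- replicate(30, paste(sample(c("A", "C", "D", "E"), 20, TRUE), collapse = ""))
  seqs <- c(seqs, replicate(30, paste(sample(c("K", "L", "R", "H"), 20, TRUE),
                                      collapse = "")))
  m <- word2vec(seqs, k = 1, d = 12, epochs = 30, seed = 3)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  emb <- function(w) m$V[match(w, m$vocab$words), ]
  expect_gt(cos(emb("A"), emb("C")), cos(emb("A"), emb("K")))
  expect_gt(cos(emb("K"), emb("L")), cos(emb("K"), emb("D")))
})

test_that("sequence_to_matrix produces fixed shapes with zero pad/OOV rows", {
  set.seed(6)
  seqs <- replicate(10, random_peptide(30))
  m4 <- word2vec(seqs, k = 4, d = 9, epochs = 2, seed = 1)
  full <- sequence_to_matrix(random_peptide(100), m4)
  expect_equal(dim(full$values), c(97L, 9L))
  m1 <- word2vec(seqs, k = 1, d = 9, epochs = 2, seed = 1)
  expect_equal(dim(sequence_to_matrix(random_peptide(100), m1)$values),
               c(100L, 9L))

  short <- sequence_to_matrix("ACEKL", m4, target_tokens = 97L)  # 2 words
  expect_equal(short$mask, c(rep(TRUE, 2), rep(FALSE, 95)))
  expect_true(all(short$values[3:97, ] == 0))

  expect_error(sequence_to_matrix("ACXKL", m4), "invalid residues")
})

test_that("a word2vec model survives the text archive round-trip", {
  set.seed(20)
  seqs <- replicate(6, random_peptide(20))
  m <- word2vec(seqs, k = 2, d = 5, epochs = 2, seed = 9)
  f <- tempfile(fileext = ".w2v")
  save_word2vec(m, f)
  back <- load_word2vec(f)
  expect_equal(back$V, m$V)
  expect_equal(back$M, m$M)
  expect_identical(back$vocab$words, m$vocab$words)
  expect_identical(back$k, m$k)
  expect_identical(back$method, m$method)
})

test_that("degenerate vocabularies are rejected", {
  expect_error(word2vec(c("AAAA", "AAA"), k = 1, d = 4, epochs = 1, seed = 1),
               "at least 2")
})
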