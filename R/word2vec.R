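# Word2Vec over biological words, trained from scratch with the exact
# (full) softmax objective.
#
# CBOW maximizes the mean log-probability of each center word given the
# average of its context words' input embeddings:
#   h = (1/C) * sum over context x of V[x, ]          (hidden vector)
#   P(center | context) = softmax(M %*% h)[center]    (output softmax)
# where V (|vocab| x d) is the input weight matrix and M (|vocab| x d here,
# one output vector per row) is the output weight matrix.  Skip-gram flips
# the objective: the center word's embedding predicts each context word.
#
# Both variants reduce to the same computation on (input mixture, target)
# pairs: CBOW rows of the sparse mixing matrix A average the context words,
# Skip-gram rows pick out the center word.  Minibatched exact-softmax
# gradient ascent then runs on dense BLAS products, which keeps desk-scale
# vocabularies (up to tens of thousands of 4mers) tractable.

# -- training-pair construction ------------------------------------------------

# For one encoded sequence (integer indices, 0 = OOV) produce the training
# pairs for the given context radius.  OOV tokens are skipped both as targets
# and as context.  Returns NULL or list(i, j, w, target): sparse triplets
# (pair row, word index, weight) and per-row target word.
w2v_pairs <- function(idx, t, method) {
  n <- length(idx)
  if (n < 2L) return(NULL)
  ii <- jj <- ww <- tt <- vector("list", n)
  row <- 0L
  for (p in seq_len(n)) {
    if (idx[p] == 0L) next
    win <- max(1L, p - t):min(n, p + t)
    ctx <- idx[win[win != p]]
    ctx <- ctx[ctx > 0L]
    if (length(ctx) == 0L) next
    if (method == "cbow") {
      row <- row + 1L
      ii[[p]] <- rep(row, length(ctx)); jj[[p]] <- ctx
      ww[[p]] <- rep(1 / length(ctx), length(ctx)); tt[[p]] <- idx[p]
    } else {  # skipgram: one pair per (center, context word)
      r <- row + seq_along(ctx)
      row <- row + length(ctx)
      ii[[p]] <- r; jj[[p]] <- rep(idx[p], length(ctx))
      ww[[p]] <- rep(1, length(ctx)); tt[[p]] <- ctx
    }
  }
  if (row == 0L) return(NULL)
  list(i = unlist(ii), j = unlist(jj), w = unlist(ww), target = unlist(tt))
}

# Mean log-likelihood and analytic gradients for a pair batch; the reference
# implementation used by both the trainer and the finite-difference tests.
# A: sparse (B x |V|) mixing matrix; target: length-B word indices.
w2v_batch_grad <- function(V, M, A, target, want_grad = TRUE) {
  B <- nrow(A)
  H <- as.matrix(A %*% V)                    # B x d
  U <- tcrossprod(H, M)                      # B x |V| logits
  U <- U - apply(U, 1L, max)                 # logit shift: softmax-invariant
  E <- exp(U)
  P <- E / rowSums(E)
  ll <- mean(log(pmax(P[cbind(seq_len(B), target)], .Machine$double.xmin)))
  if (!want_grad) return(list(ll = ll))
  dU <- -P / B
  dU[cbind(seq_len(B), target)] <- dU[cbind(seq_len(B), target)] + 1 / B
  dM <- crossprod(dU, H)                     # |V| x d
  dH <- dU %*% M                             # B x d
  dV <- as.matrix(Matrix::crossprod(A, dH))  # |V| x d
  list(ll = ll, dV = dV, dM = dM)
}

# -- public fitting interface --------------------------------------------------

#' Train a Word2Vec embedding model on biological words
#'
#' Tokenizes the sequences into overlapping k-mers, builds a vocabulary, and
#' fits CBOW (default) or Skip-gram embeddings by minibatch exact-softmax
#' gradient ascent on the mean log-likelihood of center words given context
#' (or vice versa for Skip-gram).  Training is deterministic given `seed`.
#'
#' @param sequences character vector of peptide sequences (uppercase,
#'   20-letter alphabet).
#' @param k word length in residues.
#' @param d embedding dimension; 150 matches the downstream classifier's
#'   input width.
#' @param window context radius `t`: up to `t` words on each side form the
#'   context, truncated at sequence edges (the 1/C average always divides by
#'   the number of context words actually present).
#' @param epochs passes over all training positions.
#' @param lr length-2 numeric: initial and final learning rate, decayed
#'   linearly per minibatch.
#' @param min_count words below this corpus frequency are dropped from the
#'   vocabulary and treated as out-of-vocabulary.
#' @param method `"cbow"` or `"skipgram"`.
#' @param batch minibatch size in training pairs.
#' @param stride tokenizer stride.
#' @param seed integer seed (initialization and epoch shuffling).
#' @return object of class `word2vec_model`: list with `V` (input embeddings,
#'   one row per vocabulary word), `M` (output vectors, same shape), `vocab`,
#'   `k`, `d`, `window`, `method`, `seed`, and `history` (per-epoch mean
#'   log-likelihood, computed on the fly during each pass).
#' @examples
#' m <- word2vec(c("ACEKLHET", "KLHETACE"), k = 1, d = 8, epochs = 5, seed = 1)
#' dim(m$V)
#' @export
word2vec <- function(sequences, k = 1L, d = 150L, window = 5L, epochs = 100L,
                     lr = c(0.025, 1e-4), min_count = 1L,
                     method = c("cbow", "skipgram"), batch = 256L,
                     stride = 1L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(d >= 1L, window >= 1L, epochs >= 1L, length(lr) == 2L)
  corpus <- lapply(sequences, tokenize_kmers, k = k, stride = stride)
  vocab <- build_vocabulary(corpus, min_count = min_count)
  nv <- length(vocab$words)
  if (nv < 2L) stopf("vocabulary has %d word(s); softmax needs at least 2", nv)
  enc <- lapply(corpus, encode_words, vocab = vocab)

  pairs <- lapply(enc, w2v_pairs, t = window, method = method)
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (length(pairs) == 0L) stopf("no training pairs: sequences too short for window")
  off <- cumsum(c(0L, vapply(pairs, function(p) max(p$i), integer(1))))
  A_all <- Matrix::sparseMatrix(
    i = unlist(lapply(seq_along(pairs), function(s) pairs[[s]]$i + off[s])),
    j = unlist(lapply(pairs, `[[`, "j")),
    x = unlist(lapply(pairs, `[[`, "w")),
    dims = c(off[length(off)], nv))
  target_all <- unlist(lapply(pairs, `[[`, "target"))
  N <- length(target_all)

  with_rng(seed, paste0("w2v-", method), {
    V <- matrix(stats::runif(nv * d, -0.5 / d, 0.5 / d), nv, d)
    M <- matrix(0, nv, d)
    n_batches <- ceiling(N / batch)
    total <- epochs * n_batches
    step <- 0L
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ll_sum <- 0
      for (b in seq_len(n_batches)) {
        rows <- ord[((b - 1L) * batch + 1L):min(b * batch, N)]
        g <- w2v_batch_grad(V, M, A_all[rows, , drop = FALSE], target_all[rows])
        rate <- lr[1] + (lr[2] - lr[1]) * step / max(total - 1L, 1L)
        # sum-gradient update: a first-order stand-in for the classic
        # per-example SGD at this learning rate
        V <- V + rate * length(rows) * g$dV
        M <- M + rate * length(rows) * g$dM
        ll_sum <- ll_sum + g$ll * length(rows)
        step <- step + 1L
      }
      history[ep] <- ll_sum / N
    }
    structure(list(V = V, M = M, vocab = vocab, k = as.integer(k),
                   d = as.integer(d), window = as.integer(window),
                   method = method, seed = as.integer(seed),
                   n_pairs = N, history = history),
              class = "word2vec_model")
  })
}

#' @export
print.word2vec_model <- function(x, ...) {
  cat(sprintf("<word2vec_model> %s, %dmer words, |vocab| = %d, d = %d, window = %d\n",
              toupper(x$method), x$k, length(x$vocab$words), x$d, x$window))
  cat(sprintf("  trained on %d pairs, %d epochs; mean log-lik %.4f -> %.4f\n",
              x$n_pairs, length(x$history), x$history[1],
              x$history[length(x$history)]))
  invisible(x)
}

#' CBOW forward pass for one context
#'
#' Computes the hidden vector `h` (the average of the context words' input
#' embeddings) and the exact-softmax probability vector over the vocabulary.
#'
#' @param model a `word2vec_model`.
#' @param context integer vector of vocabulary indices (>= 1).
#' @return list with `h` (length `d`) and `p` (length `|vocab|`, sums to 1).
#' @export
cbow_forward <- function(model, context) {
  stopifnot(inherits(model, "word2vec_model"))
  if (length(context) == 0L) stopf("empty context")
  if (any(context < 1L | context > nrow(model$V)))
    stopf("context indices out of range 1..%d", nrow(model$V))
  h <- colMeans(model$V[context, , drop = FALSE])
  u <- as.vector(model$M %*% h)
  u <- u - max(u)
  p <- exp(u) / sum(exp(u))
  list(h = h, p = p)
}

#' Embed one peptide as a fixed-shape matrix
#'
#' Tokenizes with the model's word length, encodes through its vocabulary,
#' pads/truncates to `target_tokens`, and stacks the input-embedding rows.
#' Pad and out-of-vocabulary positions embed to the zero vector.
#'
#' @param sequence peptide string (validated against the 20-letter alphabet).
#' @param model a `word2vec_model`.
#' @param target_tokens number of rows of the result; defaults to
#'   `100 - k + 1`, the token count of a maximal-length (100-residue)
#'   peptide.
#' @return list: `values` (`target_tokens x d` matrix) and `mask` (logical,
#'   TRUE where the row is a real word).
#' @export
sequence_to_matrix <- function(sequence, model, target_tokens = NULL) {
  stopifnot(inherits(model, "word2vec_model"))
  if (!is_valid_peptide(sequence))
    stopf("invalid residues in sequence: %s", sequence)
  target_tokens <- target_tokens %||% (100L - model$k + 1L)
  idx <- encode_and_pad(tokenize_kmers(sequence, model$k), model$vocab,
                        target_tokens)
  X <- matrix(0, target_tokens, model$d)
  real <- idx > 0L
  X[real, ] <- model$V[idx[real], , drop = FALSE]
  list(values = X, mask = idx != PAD_INDEX)
}

# Encode many sequences as an index matrix (n x target_tokens) through one
# model's tokenizer+vocabulary; embeddings are materialized batch-wise later.
encode_index_matrix <- function(sequences, model, target_tokens = NULL) {
  target_tokens <- target_tokens %||% (100L - model$k + 1L)
  out <- t(vapply(sequences, function(s)
    encode_and_pad(tokenize_kmers(s, model$k), model$vocab, target_tokens),
    integer(target_tokens)))
  dimnames(out) <- NULL
  out
}

# Materialize embedding rows for a batch of index rows in sample-major layout:
# result row (b-1)*L + t is sample b, token t.
embed_rows <- function(idx_rows, V) {
  L <- ncol(idx_rows)
  vec <- as.vector(t(idx_rows))
  X <- matrix(0, length(vec), ncol(V))
  nz <- vec > 0L
  X[nz, ] <- V[vec[nz], , drop = FALSE]
  X
}

#' Save / load a Word2Vec model as a plain-text archive
#'
#' The archive is a self-describing TSV-style text file: a header with `k`,
#' `d`, `window`, `method`, `seed`, the vocabulary, then the two weight
#' matrices row by row.
#'
#' @param model a `word2vec_model`.
#' @param path file path.
#' @return `path` (save) or the restored `word2vec_model` (load).
#' @export
save_word2vec <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#word2vec\tk=%d\td=%d\twindow=%d\tmethod=%s\tseed=%d\tnv=%d",
                     model$k, model$d, model$window, model$method, model$seed,
                     length(model$vocab$words)), con)
  writeLines(paste(model$vocab$words, model$vocab$counts, sep = "\t"), con)
  utils::write.table(format(model$V, digits = 17), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(format(model$M, digits = 17), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_word2vec
#' @export
load_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#word2vec\t", "", lines[1]), "\t")[[1]]
  kv <- stats::setNames(sub("^[^=]*=", "", hdr), sub("=.*$", "", hdr))
  nv <- as.integer(kv[["nv"]]); d <- as.integer(kv[["d"]])
  vtab <- do.call(rbind, strsplit(lines[2:(1 + nv)], "\t"))
  vocab <- structure(list(words = vtab[, 1], counts = as.integer(vtab[, 2]),
                          k = as.integer(kv[["k"]])), class = "bw_vocabulary")
  num <- function(rows) matrix(as.numeric(unlist(strsplit(rows, "\t"))),
                               nrow = length(rows), byrow = TRUE)
  V <- num(lines[(2 + nv):(1 + 2 * nv)])
  M <- num(lines[(2 + 2 * nv):(1 + 3 * nv)])
  structure(list(V = V, M = M, vocab = vocab, k = as.integer(kv[["k"]]),
                 d = d, window = as.integer(kv[["window"]]),
                 method = kv[["method"]], seed = as.integer(kv[["seed"]]),
                 n_pairs = NA_integer_, history = numeric(0)),
            class = "word2vec_model")
}
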