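# The central fitting function: biological-word embeddings + dual-channel
# classifier, wrapped as a classed model object with the usual methods.

#' Fit a biological-word peptide classifier
#'
#' Trains one Word2Vec embedding model per word size on the training
#' sequences only, encodes every peptide as two fixed-shape embedding
#' matrices (`(max_len - k + 1) x d` each, zero rows for padding and
#' out-of-vocabulary words), and trains the dual-channel network on them.
#'
#' @param data labeled data.frame with columns `id`, `sequence`, `label`
#'   (1 = active class).
#' @param k_channel1,k_channel2 word sizes feeding channels 1 and 2; the
#'   default 1mer/4mer pairing reflects the loop/helix reading of peptide
#'   secondary structure and performs best empirically.
#' @param cfg optional [channel_config()]; by default one is derived from the
#'   word sizes (`len = max_len - k + 1`) and `embed_dim`.
#' @param max_len maximum peptide length the encoder supports; token targets
#'   per channel are `max_len - k + 1` (100 -> 100 tokens for 1mers, 97 for
#'   4mers).
#' @param embed_dim embedding dimension `d`.
#' @param embed_epochs,embed_window,embed_min_count,embed_method Word2Vec
#'   training settings (see [word2vec()]); the fitting default of 5 epochs
#'   with `min_count` 2 is sized for corpora of a few hundred peptides.
#' @param embeddings optional list with elements `m1`, `m2`: pre-trained
#'   `word2vec_model`s to reuse instead of training (their `k` must match the
#'   channel word sizes).
#' @param lr,batch,epochs classifier training parameters (Adam optimizer).
#' @param validation optional labeled data.frame scored after each epoch.
#' @param seed integer seed controlling embedding training, weight
#'   initialization, shuffling and dropout.
#' @param verbose print training progress.
#' @return object of class `bwr_model` with elements `net`, `embeddings`
#'   (`m1`, `m2`), `cfg`, `history`, `threshold`, `seed`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_spec(n_pos = 30, n_neg = 30, seed = 7))
#' fit <- bwr_fit(ds, embed_dim = 16, epochs = 2,
#'                cfg = channel_config(d = 16, blocks1 = 1, blocks2 = 1,
#'                                     conv_filters = c(16, 16, 32),
#'                                     dense1 = c(16, 8), fusion = c(8, 8)))
#' predict(fit, ds[1:3, ])
#' }
#' @export
bwr_fit <- function(data, k_channel1 = 1L, k_channel2 = 4L, cfg = NULL,
                    max_len = 100L, embed_dim = 150L, embed_epochs = 5L,
                    embed_window = 5L, embed_min_count = 2L,
                    embed_method = "cbow", embeddings = NULL,
                    lr = 1e-4, batch = 32L, epochs = 16L,
                    validation = NULL, seed = 1L, verbose = FALSE) {
  check_labeled(data)
  if (nrow(data) == 0L) stopf("empty training set")
  if (!all(is_valid_peptide(data$sequence)))
    stopf("invalid residues in sequences: %s",
          paste(utils::head(data$id[!is_valid_peptide(data$sequence)], 5),
                collapse = ", "))
  len1 <- max_len - k_channel1 + 1L
  len2 <- max_len - k_channel2 + 1L
  if (is.null(embeddings)) {
    m1 <- word2vec(data$sequence, k = k_channel1, d = embed_dim,
                   window = embed_window, epochs = embed_epochs,
                   min_count = if (k_channel1 == 1L) 1L else embed_min_count,
                   method = embed_method, seed = derive_seed(seed, "embed1"))
    m2 <- word2vec(data$sequence, k = k_channel2, d = embed_dim,
                   window = embed_window, epochs = embed_epochs,
                   min_count = if (k_channel2 == 1L) 1L else embed_min_count,
                   method = embed_method, seed = derive_seed(seed, "embed2"))
  } else {
    m1 <- embeddings$m1; m2 <- embeddings$m2
    stopifnot(inherits(m1, "word2vec_model"), inherits(m2, "word2vec_model"))
    if (m1$k != k_channel1 || m2$k != k_channel2)
      stopf("supplied embeddings have word sizes (%d, %d), expected (%d, %d)",
            m1$k, m2$k, k_channel1, k_channel2)
  }
  if (is.null(cfg))
    cfg <- channel_config(d = embed_dim, len1 = len1, len2 = len2)
  else { cfg$len1 <- len1; cfg$len2 <- len2 }

  net <- build_model(cfg, seed = derive_seed(seed, "net"))
  enc <- encode_for_net(data$sequence, m1, m2, len1, len2)
  val <- NULL
  if (!is.null(validation)) {
    check_labeled(validation)
    val <- list(enc = encode_for_net(validation$sequence, m1, m2, len1, len2),
                y = validation$label)
  }
  history <- nn_train(net, enc, data$label, lr = lr, batch = batch,
                      epochs = epochs, seed = derive_seed(seed, "train"),
                      validation = val, verbose = verbose)
  structure(list(net = net, embeddings = list(m1 = m1, m2 = m2), cfg = cfg,
                 k_channel1 = k_channel1, k_channel2 = k_channel2,
                 max_len = max_len, history = history, threshold = 0.5,
                 n_train = nrow(data), seed = as.integer(seed),
                 call = match.call()),
            class = "bwr_model")
}

# Classifier input prep.  The embedding tables are rescaled to unit RMS so
# the network sees comparably-scaled features regardless of Word2Vec's
# arbitrary output scale (and of corpus size/epochs); pad and OOV rows stay
# exactly zero.
scale_unit_rms <- function(V) {
  s <- sqrt(mean(V^2))
  if (s > 0) V / s else V
}

encode_for_net <- function(sequences, m1, m2, len1, len2) {
  list(idx1 = encode_index_matrix(sequences, m1, len1),
       idx2 = encode_index_matrix(sequences, m2, len2),
       V1 = scale_unit_rms(m1$V), V2 = scale_unit_rms(m2$V))
}

#' Predict activity probabilities for new peptides
#'
#' @param object a fitted `bwr_model`.
#' @param newdata data.frame with a `sequence` column, or a character vector
#'   of sequences.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls at the
#'   model's threshold.
#' @param batch prediction batch size (results are batch-size independent).
#' @param ... unused.
#' @return numeric vector aligned with `newdata`.
#' @export
predict.bwr_model <- function(object, newdata, type = c("prob", "class"),
                              batch = 32L, ...) {
  type <- match.arg(type)
  seqs <- if (is.character(newdata)) newdata else newdata$sequence
  if (!all(is_valid_peptide(seqs)))
    stopf("invalid residues in sequences at positions: %s",
          paste(utils::head(which(!is_valid_peptide(seqs)), 5), collapse = ", "))
  enc <- encode_for_net(seqs, object$embeddings$m1, object$embeddings$m2,
                        object$cfg$len1, object$cfg$len2)
  p <- nn_predict(object$net, enc, batch = batch)
  if (type == "class") as.integer(p >= object$threshold) else p
}

#' Evaluate a fitted model on a labeled dataset
#'
#' @param object a `bwr_model`.
#' @param data labeled data.frame.
#' @param ... passed to [predict.bwr_model()].
#' @return a `metrics_report`.
#' @export
evaluate <- function(object, data, ...) {
  check_labeled(data)
  compute_metrics(data$label, predict(object, data, ...), object$threshold)
}

#' @export
print.bwr_model <- function(x, ...) {
  cat(sprintf("<bwr_model> %dmer + %dmer biological words, d = %d\n",
              x$k_channel1, x$k_channel2, x$cfg$d))
  cat(sprintf("  network: %s / %s, %s parameters\n",
              if (x$cfg$channel1) x$cfg$seq1 else "-",
              if (x$cfg$channel2) x$cfg$seq2 else "-",
              format(n_params(x$net), big.mark = ",")))
  ep <- length(x$history$loss)
  if (ep > 0)
    cat(sprintf("  trained %d epochs on %d peptides; final loss %.4f, acc %.3f\n",
                ep, x$n_train, x$history$loss[ep], x$history$acc[ep]))
  else
    cat(sprintf("  untrained (0 epochs), %d peptides prepared\n", x$n_train))
  invisible(x)
}

#' @export
summary.bwr_model <- function(object, ...) {
  print(object)
  cat("\nVocabulary sizes:",
      sprintf("%dmer: %d", object$k_channel1,
              length(object$embeddings$m1$vocab$words)),
      sprintf(" %dmer: %d\n", object$k_channel2,
              length(object$embeddings$m2$vocab$words)))
  print(object$net$plan)
  invisible(object)
}

#' Save / load a fitted model
#'
#' The embeddings are written as self-describing text archives (see
#' [save_word2vec()]), the network and configuration as an RDS file.
#'
#' @param object a `bwr_model`.
#' @param dir directory to create/populate.
#' @return `dir` (save) or the restored `bwr_model` (load).
#' @export
save_bwr_model <- function(object, dir) {
  stopifnot(inherits(object, "bwr_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_word2vec(object$embeddings$m1, file.path(dir, "embeddings_ch1.w2v"))
  save_word2vec(object$embeddings$m2, file.path(dir, "embeddings_ch2.w2v"))
  slim <- object
  slim$embeddings <- NULL
  saveRDS(slim, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_bwr_model
#' @export
load_bwr_model <- function(dir) {
  object <- readRDS(file.path(dir, "model.rds"))
  object$embeddings <- list(
    m1 = load_word2vec(file.path(dir, "embeddings_ch1.w2v")),
    m2 = load_word2vec(file.path(dir, "embeddings_ch2.w2v")))
  object
}

#' Plot training history of a fitted model
#'
#' @param x a `bwr_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bwr_model <- function(x, ...) {
  h <- x$history
  cols <- cbind(loss = h$loss,
                val_loss = if (!is.null(h$val_loss)) h$val_loss)
  graphics::matplot(seq_along(h$loss), cols, type = "l", lty = 1,
                    xlab = "epoch", ylab = "binary cross-entropy",
                    main = "training history", ...)
  graphics::legend("topright", legend = colnames(cols), lty = 1,
                   col = seq_len(ncol(cols)))
  invisible(x)
}
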