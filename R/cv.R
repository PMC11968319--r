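# Cross-validation harness and the experiment grids (word-size sweep,
# network variants, ablations).  Tables are emitted as data.frames with
# "mean±std"-formatted metric strings in the customary column order.

#' Stratified k-fold cross-validation of the biological-word classifier
#'
#' By default the Word2Vec embeddings are retrained inside each fold on that
#' fold's training split only, so validation sequences never enter the
#' embedding corpora (no transductive leakage).  `shared_embeddings = TRUE`
#' trains them once on the full dataset instead — cheaper, and a regime some
#' published pipelines use.
#'
#' @param data labeled data.frame.
#' @param k number of folds.
#' @param shared_embeddings train embeddings once on all sequences.
#' @param seed integer seed (folds, embeddings, training).
#' @param digits decimals in the formatted aggregate row.
#' @param keep_fits keep the per-fold fitted models in the result (memory
#'   permitting); useful for inspecting per-fold embeddings.
#' @param ... passed to [bwr_fit()].
#' @return object of class `bwr_cv`: list with `folds` (per-fold
#'   `metrics_report`s), `aggregate` (means, sds, formatted strings),
#'   `fold_indices`, and optionally `fits`.
#' @export
cross_validate <- function(data, k = 5L, shared_embeddings = FALSE,
                           seed = 1L, digits = 3, keep_fits = FALSE, ...) {
  check_labeled(data)
  folds <- kfold_indices(data, k = k, seed = seed)
  shared <- NULL
  args <- list(...)
  if (shared_embeddings) {
    kc1 <- args$k_channel1 %||% 1L
    kc2 <- args$k_channel2 %||% 4L
    shared <- list(
      m1 = word2vec(data$sequence, k = kc1, d = args$embed_dim %||% 150L,
                    window = args$embed_window %||% 5L,
                    epochs = args$embed_epochs %||% 5L,
                    min_count = if (kc1 == 1L) 1L else (args$embed_min_count %||% 2L),
                    method = args$embed_method %||% "cbow",
                    seed = derive_seed(seed, "cv-embed1")),
      m2 = word2vec(data$sequence, k = kc2, d = args$embed_dim %||% 150L,
                    window = args$embed_window %||% 5L,
                    epochs = args$embed_epochs %||% 5L,
                    min_count = if (kc2 == 1L) 1L else (args$embed_min_count %||% 2L),
                    method = args$embed_method %||% "cbow",
                    seed = derive_seed(seed, "cv-embed2")))
  }
  reports <- vector("list", k)
  fits <- if (keep_fits) vector("list", k)
  for (f in seq_len(k)) {
    tr <- data[folds[[f]]$train, , drop = FALSE]
    va <- data[folds[[f]]$validation, , drop = FALSE]
    fit <- do.call(bwr_fit, c(list(data = tr, embeddings = shared,
                                   seed = derive_seed(seed, paste0("cv-fold", f))),
                              args))
    reports[[f]] <- evaluate(fit, va)
    if (keep_fits) fits[[f]] <- fit
  }
  structure(list(folds = reports,
                 aggregate = aggregate_metrics(reports, digits),
                 fold_indices = folds, k = k,
                 shared_embeddings = shared_embeddings, fits = fits),
            class = "bwr_cv")
}

#' @export
print.bwr_cv <- function(x, ...) {
  cat(sprintf("<bwr_cv> %d folds%s\n", x$k,
              if (x$shared_embeddings) " (shared embeddings)" else ""))
  print(as.data.frame(t(x$aggregate$formatted)), row.names = FALSE)
  invisible(x)
}

cv_row <- function(cv) as.list(cv$aggregate$formatted)

#' Cross-validated sweep over word-size combinations
#'
#' Runs the pipeline for each (channel-1 word size, channel-2 word size)
#' pair, recomputing token lengths (`max_len - k + 1`) and revalidating the
#' shape plan per pair.  A pair whose configuration cannot build is reported
#' as failed and the sweep continues.
#'
#' @param data labeled data.frame.
#' @param pairs list of length-2 integer vectors, or a 2-column matrix, of
#'   word sizes in 1..6.
#' @param k number of CV folds per pair.
#' @param seed integer seed.
#' @param ... passed to [cross_validate()] / [bwr_fit()].
#' @return data.frame with columns `Input_of_Channel1`, `Input_of_Channel2`,
#'   `ACC`, `SN`, `SP`, `MCC`, `AUC` (formatted `mean±std`), and `status`.
#' @export
kmer_sweep <- function(data, pairs = list(c(1L, 4L)), k = 5L, seed = 1L, ...) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% 1:6))
    res <- tryCatch({
      cv <- cross_validate(data, k = k, seed = seed,
                           k_channel1 = pr[1], k_channel2 = pr[2], ...)
      c(list(Input_of_Channel1 = sprintf("%dmer", pr[1]),
             Input_of_Channel2 = sprintf("%dmer", pr[2])),
        cv_row(cv)[c("ACC", "SN", "SP", "MCC", "AUROC")],
        list(status = "ok"))
    }, error = function(e)
      list(Input_of_Channel1 = sprintf("%dmer", pr[1]),
           Input_of_Channel2 = sprintf("%dmer", pr[2]),
           ACC = NA, SN = NA, SP = NA, MCC = NA, AUROC = NA,
           status = paste("failed:", conditionMessage(e))))
    res
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out)[names(out) == "AUROC"] <- "AUC"
  rownames(out) <- NULL
  out
}

# shared evaluation used by the ablation and variant grids: a single
# stratified holdout (cheap) or full CV
grid_eval <- function(data, cfg, train_frac, folds, seed, ...) {
  if (!is.null(folds)) {
    cv <- cross_validate(data, k = folds, seed = seed, cfg = cfg, ...)
    cv_row(cv)[c("ACC", "SN", "SP", "MCC", "AUROC")]
  } else {
    sp <- split_train_test(data, train_fraction = train_frac, seed = seed)
    fit <- bwr_fit(sp$train, cfg = cfg, seed = seed, ...)
    r <- evaluate(fit, sp$test)
    lapply(r[c("ACC", "SN", "SP", "MCC", "AUROC")], round, 3)
  }
}

#' Ablation grid over the three network modules
#'
#' Evaluates the six module combinations (CNN, Transformer1, Transformer2) =
#' (on,off,off), (off,on,on), (on,off,on), (on,on,off), (off,off,on),
#' (on,on,on); the last row is the full model.
#'
#' @param data labeled data.frame.
#' @param cfg base [channel_config()].
#' @param folds if given, evaluate each row by `folds`-fold CV; otherwise a
#'   single stratified holdout split (`train_frac`).
#' @param train_frac holdout training fraction.
#' @param seed integer seed (same data split for every row).
#' @param ... passed to [bwr_fit()].
#' @return data.frame with logical columns `CNN`, `Transformer1`,
#'   `Transformer2` and metric columns `ACC`, `SN`, `SP`, `MCC`, `AUC`.
#' @export
run_ablation <- function(data, cfg = channel_config(), folds = NULL,
                         train_frac = 0.8, seed = 1L, ...) {
  grid <- rbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE),
                c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                c(FALSE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  colnames(grid) <- c("CNN", "Transformer1", "Transformer2")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$use_cnn <- grid[i, 1]
    cfg_i$seq1 <- if (grid[i, 2]) "transformer" else "none"
    cfg_i$seq2 <- if (grid[i, 3]) "transformer" else "none"
    if (!grid[i, 1] && !grid[i, 2]) cfg_i$channel1 <- FALSE
    m <- grid_eval(data, cfg_i, train_frac, folds, seed, ...)
    c(as.list(grid[i, ]), m)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out)[names(out) == "AUROC"] <- "AUC"
  rownames(out) <- NULL
  out
}

#' Grid over sequence-module variants of the network
#'
#' Replaces both transformer stacks by each named recurrent/temporal module
#' and evaluates, plus the transformer reference row.
#'
#' @param data labeled data.frame.
#' @param kinds variant kinds to evaluate.
#' @inheritParams run_ablation
#' @return data.frame with a `network` column and metric columns.
#' @export
variant_grid <- function(data, kinds = c("bilstm", "tcn", "lstm", "gru",
                                         "bigru", "transformer"),
                         cfg = channel_config(), folds = NULL,
                         train_frac = 0.8, seed = 1L, ...) {
  rows <- lapply(kinds, function(kind) {
    cfg_i <- cfg
    cfg_i$seq1 <- kind
    cfg_i$seq2 <- kind
    m <- grid_eval(data, cfg_i, train_frac, folds, seed, ...)
    c(list(network = kind), m)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out)[names(out) == "AUROC"] <- "AUC"
  rownames(out) <- NULL
  out
}
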