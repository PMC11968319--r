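# Model interpretation: attention-based position attribution and a numeric
# position-wise residue enrichment table (the quantitative counterpart of a
# two-sample sequence logo).

# locate the last transformer block's attention sublayer in one channel
last_mha <- function(net, channel) {
  layers <- if (channel == 1L) net$ch1 else net$ch2
  tf <- Filter(function(ly) identical(ly$type, "transformer"), layers)
  if (length(tf) == 0L)
    stopf("channel %d has no transformer stack (ablated or replaced)", channel)
  tf[[length(tf)]]$sub$mha
}

#' Average attention mass per token position
#'
#' Runs the dataset through the model, extracts the attention matrices of the
#' selected channel's last transformer block, averages them over heads and
#' samples, and reduces to per-key-position mass (how much attention each
#' position receives, averaged over query positions).  The result is
#' normalized to sum to 1.
#'
#' @param object a fitted `bwr_model`.
#' @param data data.frame with a `sequence` column (or character vector).
#' @param channel 1 (first word size) or 2 (second word size).
#' @param batch batch size for the forward passes.
#' @return object of class `attention_map`: list with `weights` (length =
#'   channel token count, sums to 1), `channel`, `k`, `n` and `reduction`.
#' @export
attention_position_weights <- function(object, data, channel = 1L,
                                       batch = 32L) {
  stopifnot(inherits(object, "bwr_model"), channel %in% c(1L, 2L))
  seqs <- if (is.character(data)) data else data$sequence
  mha <- last_mha(object$net, channel)
  enc <- encode_for_net(seqs, object$embeddings$m1, object$embeddings$m2,
                        object$cfg$len1, object$cfg$len2)
  total <- NULL
  n <- 0L
  mha$capture <- TRUE
  on.exit(mha$capture <- FALSE)
  for (start in seq(1L, length(seqs), by = batch)) {
    ids <- start:min(start + batch - 1L, length(seqs))
    inp <- batch_inputs(object$net, enc, ids)
    net_forward(object$net, inp$x1, inp$x2, training = FALSE)
    for (Pb in mha$attn) {           # one entry per sample in the batch
      heads <- length(Pb)
      mass <- Reduce(`+`, lapply(Pb, colMeans)) / heads  # mean over queries+heads
      total <- if (is.null(total)) mass else total + mass
      n <- n + 1L
    }
  }
  w <- total / sum(total)
  structure(list(weights = w, channel = channel,
                 k = if (channel == 1L) object$k_channel1 else object$k_channel2,
                 n = n,
                 reduction = "last block, mean over heads and query positions"),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map> channel %d (%dmer), %d positions, %d samples\n",
              x$channel, x$k, length(x$weights), x$n))
  top <- order(x$weights, decreasing = TRUE)[1:min(5, length(x$weights))]
  cat("  top positions:", paste(sprintf("%d (%.4f)", top, x$weights[top]),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Position-wise residue enrichment between two peptide classes
#'
#' For fixed-length sequence sets, computes per (position, residue) the
#' within-class frequencies, their difference, and a pooled two-proportion
#' z-test.  Positions are flagged when the residue with the largest absolute
#' frequency difference is significant at `alpha` (no multiple-testing
#' correction by default, matching the convention of two-sample sequence
#' logos; `bonferroni = TRUE` divides `alpha` by the number of cells).
#'
#' @param pos_seqs,neg_seqs character vectors (or data.frames with
#'   `sequence`), all sequences of length `length`.
#' @param length the common sequence length.
#' @param alpha significance level.
#' @param bonferroni apply Bonferroni correction over the `20 * length` cells.
#' @return object of class `enrichment_table`: data.frame with columns
#'   `position`, `residue`, `freq_pos`, `freq_neg`, `diff`, `z`, `p`;
#'   attribute `flagged` lists significant positions.
#' @export
position_residue_enrichment <- function(pos_seqs, neg_seqs, length,
                                        alpha = 0.05, bonferroni = FALSE) {
  get_seqs <- function(x) if (is.character(x)) x else x$sequence
  ps <- get_seqs(pos_seqs); ns <- get_seqs(neg_seqs)
  if (base::length(ps) == 0L || base::length(ns) == 0L)
    stopf("both classes must be non-empty")
  bad <- c(which(nchar(ps) != length), which(nchar(ns) != length))
  if (base::length(bad) > 0L) {
    ids <- c(sprintf("pos[%d]", which(nchar(ps) != length)),
             sprintf("neg[%d]", which(nchar(ns) != length)))
    stopf("sequences not of length %d: %s", length,
          paste(utils::head(ids, 10), collapse = ", "))
  }
  n1 <- base::length(ps); n2 <- base::length(ns)
  count_mat <- function(seqs) {
    m <- matrix(0L, 20L, length, dimnames = list(AA_ALPHABET, NULL))
    ch <- do.call(rbind, strsplit(seqs, ""))
    for (j in seq_len(length)) {
      tab <- table(factor(ch[, j], levels = AA_ALPHABET))
      m[, j] <- as.integer(tab)
    }
    m
  }
  c1 <- count_mat(ps); c2 <- count_mat(ns)
  f1 <- c1 / n1; f2 <- c2 / n2
  pooled <- (c1 + c2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (f1 - f2) / se)
  pval <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(position = rep(seq_len(length), each = 20L),
                    residue = rep(AA_ALPHABET, length),
                    freq_pos = as.vector(f1), freq_neg = as.vector(f2),
                    diff = as.vector(f1 - f2), z = as.vector(z),
                    p = as.vector(pval), stringsAsFactors = FALSE)
  thr <- if (bonferroni) alpha / (20L * length) else alpha
  flagged <- vapply(seq_len(length), function(pos) {
    rows <- tab[tab$position == pos, ]
    top <- rows[which.max(abs(rows$diff)), ]
    top$p < thr && abs(top$diff) > 0
  }, logical(1))
  structure(tab, class = c("enrichment_table", "data.frame"),
            flagged = which(flagged), alpha = alpha, bonferroni = bonferroni)
}

#' @export
print.enrichment_table <- function(x, ...) {
  L <- max(x$position)
  cat(sprintf("<enrichment_table> %d positions x 20 residues\n", L))
  fl <- attr(x, "flagged")
  cat("  flagged positions:",
      if (base::length(fl)) paste(fl, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Export per-sample feature vectors at a named tap point
#'
#' Taps: `"input-1mer"` and `"input-4mer"` give the flattened embedding
#' matrices; `"fusion-dense"` gives the activations of the last fusion dense
#' layer before the output unit (width = last fusion width).  Intended for
#' external 2-D projection (t-SNE, UMAP, ...), which is deliberately not done
#' here.
#'
#' @param object a fitted `bwr_model`.
#' @param data labeled data.frame (labels are carried through when present).
#' @param layer tap point.
#' @param batch batch size.
#' @return list with `features` (n x width matrix) and `labels` (or NULL).
#' @export
feature_projection_export <- function(object, data,
                                      layer = c("fusion-dense", "input-1mer",
                                                "input-4mer"),
                                      batch = 32L) {
  layer <- match.arg(layer)
  seqs <- if (is.character(data)) data else data$sequence
  labels <- if (is.data.frame(data) && "label" %in% names(data)) data$label
  m1 <- object$embeddings$m1; m2 <- object$embeddings$m2
  enc <- encode_for_net(seqs, m1, m2, object$cfg$len1, object$cfg$len2)
  n <- base::length(seqs)
  if (layer == "input-1mer" || layer == "input-4mer") {
    idx <- if (layer == "input-1mer") enc$idx1 else enc$idx2
    V <- if (layer == "input-1mer") enc$V1 else enc$V2
    X <- embed_rows(idx, V)
    L <- ncol(idx)
    feats <- matrix(as.vector(t(X)), nrow = n, byrow = TRUE)  # flatten per sample
    return(list(features = feats, labels = labels))
  }
  width <- object$cfg$fusion[base::length(object$cfg$fusion)]
  feats <- matrix(0, n, width)
  for (start in seq(1L, n, by = batch)) {
    ids <- start:min(start + batch - 1L, n)
    inp <- batch_inputs(object$net, enc, ids)
    z1 <- inp$x1; z2 <- inp$x2
    if (!is.null(z1)) for (ly in object$net$ch1) z1 <- layer_forward(ly, z1, FALSE)
    if (!is.null(z2)) for (ly in object$net$ch2) z2 <- layer_forward(ly, z2, FALSE)
    z <- list(x = cbind(if (!is.null(z1)) z1$x, if (!is.null(z2)) z2$x),
              B = base::length(ids), L = NULL)
    hd <- object$net$head
    for (ly in hd[-base::length(hd)]) z <- layer_forward(ly, z, FALSE)
    feats[ids, ] <- z$x
  }
  list(features = feats, labels = labels)
}
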