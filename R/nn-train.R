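# Mini-batch Adam training of a bwr_net on pre-encoded index matrices.
# Embedding rows are materialized per batch (they are fixed inputs, not
# trained further), the loss is binary cross-entropy on the sigmoid output.

# assemble the layout tensors for a batch of sample indices
batch_inputs <- function(net, enc, ids) {
  cfg <- net$cfg
  x1 <- if (cfg$channel1)
    list(x = embed_rows(enc$idx1[ids, , drop = FALSE], enc$V1),
         B = length(ids), L = cfg$len1)
  x2 <- if (cfg$channel2)
    list(x = embed_rows(enc$idx2[ids, , drop = FALSE], enc$V2),
         B = length(ids), L = cfg$len2)
  list(x1 = x1, x2 = x2)
}

adam_state <- function(layers) {
  lapply(layers, function(ly) lapply(ly$params, function(p) {
    z <- p; z[] <- 0
    list(m = z, v = z + 0)  # +0: force distinct allocations
  }))
}

# one Adam step over all layers; moment buffers and parameters are updated
# in place by the compiled kernel, gradients are cleared
adam_step <- function(layers, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 / (1 - beta1^t)
  c2 <- 1 / (1 - beta2^t)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      adam_update(ly$params[[nm]], st$m, st$v, g, lr, beta1, beta2, eps, c1, c2)
    }
    ly$grads <- list()
  }
  state
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a built network on an encoded dataset
#'
#' Mini-batch gradient descent with the Adam optimizer on binary
#' cross-entropy.  Batch composition is reshuffled every epoch; given the
#' same seed the whole run is deterministic.
#'
#' @param net a `bwr_net` from [build_model()] (modified in place: layer
#'   environments hold the trained weights).
#' @param enc encoded inputs: list with `idx1`, `idx2` (n x len index
#'   matrices) and `V1`, `V2` (embedding tables).
#' @param y numeric 0/1 labels, length n.
#' @param lr Adam learning rate; 1e-4 suits datasets of a few thousand
#'   peptides, 1e-3 converges faster on small (hundreds) sets.
#' @param batch mini-batch size.
#' @param epochs training epochs.
#' @param seed integer seed (shuffling, dropout).
#' @param validation optional list(enc, y) evaluated after each epoch.
#' @param verbose print per-epoch loss.
#' @return list with per-epoch `loss`, `acc` and, when validation is given,
#'   `val_loss`, `val_acc`.
#' @export
nn_train <- function(net, enc, y, lr = 1e-4, batch = 32L, epochs = 16L,
                     seed = 1L, validation = NULL, verbose = FALSE) {
  n <- length(y)
  if (n == 0L) stopf("empty training set")
  stopifnot(nrow(enc$idx1 %||% enc$idx2) == n)
  layers <- collect_layers(c(net$ch1, net$ch2, net$head))
  state <- adam_state(layers)
  hist <- list(loss = numeric(epochs), acc = numeric(epochs))
  if (!is.null(validation)) hist$val_loss <- hist$val_acc <- numeric(epochs)
  with_rng(seed, "nn-train", {
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = batch)) {
        ids <- ord[start:min(start + batch - 1L, n)]
        B <- length(ids)
        inp <- batch_inputs(net, enc, ids)
        out <- net_forward(net, inp$x1, inp$x2, training = TRUE)
        yb <- y[ids]
        ep_loss <- ep_loss + bce_loss(out$p, yb) * B
        ep_correct <- ep_correct + sum((out$p >= 0.5) == (yb == 1))
        net_backward(net, (out$p - yb) / B)   # d(BCE)/dlogit through sigmoid
        t_step <- t_step + 1L
        state <- adam_step(layers, state, lr, t_step)
      }
      hist$loss[ep] <- ep_loss / n
      hist$acc[ep] <- ep_correct / n
      if (!is.null(validation)) {
        vp <- nn_predict(net, validation$enc, batch = batch)
        hist$val_loss[ep] <- bce_loss(vp, validation$y)
        hist$val_acc[ep] <- mean((vp >= 0.5) == (validation$y == 1))
      }
      if (verbose)
        message(sprintf("epoch %2d/%d  loss %.4f  acc %.3f%s", ep, epochs,
                        hist$loss[ep], hist$acc[ep],
                        if (is.null(validation)) "" else
                          sprintf("  val_loss %.4f  val_acc %.3f",
                                  hist$val_loss[ep], hist$val_acc[ep])))
    }
  })
  hist
}

#' Predict probabilities for an encoded dataset
#'
#' A pure function of the inputs: dropout is disabled and results are
#' independent of the batch size used.
#'
#' @param net a trained `bwr_net`.
#' @param enc encoded inputs as in [nn_train()].
#' @param batch prediction batch size.
#' @return numeric vector of probabilities in `[0, 1]`, aligned with rows of
#'   the index matrices.
#' @export
nn_predict <- function(net, enc, batch = 32L) {
  n <- nrow(enc$idx1 %||% enc$idx2)
  p <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    ids <- start:min(start + batch - 1L, n)
    inp <- batch_inputs(net, enc, ids)
    p[ids] <- net_forward(net, inp$x1, inp$x2, training = FALSE)$p
  }
  p
}
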