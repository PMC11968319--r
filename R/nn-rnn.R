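# Recurrent (LSTM/GRU, optionally bidirectional) and temporal-convolution
# layers used by the architecture variants that replace the transformer
# stacks.  All return full sequences (length preserved) so the downstream
# flatten/dense topology is unchanged up to feature width.

layer_rnn <- function(din, hidden, kind = c("lstm", "gru"),
                      bidirectional = FALSE) {
  kind <- match.arg(kind)
  ng <- if (kind == "lstm") 4L else 3L
  mk <- function() list(W = glorot(din, ng * hidden),
                        U = glorot(hidden, ng * hidden),
                        b = numeric(ng * hidden))
  params <- mk()
  if (bidirectional) {
    bw <- mk()
    params <- c(params, list(Wr = bw$W, Ur = bw$U, br = bw$b))
  }
  new_layer("rnn", params = params, kind = kind, hidden = hidden,
            din = din, bidirectional = bidirectional,
            dout = if (bidirectional) 2L * hidden else hidden)
}

sigm <- function(x) 1 / (1 + exp(-x))

# one direction of LSTM/GRU over sample-major X ((B*L) x din); returns
# H ((B*L) x h) plus the per-step cache needed for BPTT
rnn_run <- function(kind, X, B, L, W, U, bvec, h) {
  H <- matrix(0, B * L, h)
  hs <- matrix(0, B, h)
  cs <- matrix(0, B, h)
  cache <- vector("list", L)
  XW <- add_bias(X %*% W, bvec)   # all input projections at once
  for (t in seq_len(L)) {
    rows <- (seq_len(B) - 1L) * L + t
    z <- XW[rows, , drop = FALSE]
    if (kind == "lstm") {
      z <- z + hs %*% U
      i <- sigm(z[, 1:h, drop = FALSE])
      f <- sigm(z[, (h + 1):(2 * h), drop = FALSE])
      g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
      o <- sigm(z[, (3 * h + 1):(4 * h), drop = FALSE])
      c_prev <- cs
      cs <- f * c_prev + i * g
      tc <- tanh(cs)
      h_new <- o * tc
      cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                         tc = tc, h_prev = hs)
    } else {  # gru
      hu <- hs %*% U
      r <- sigm(z[, 1:h, drop = FALSE] + hu[, 1:h, drop = FALSE])
      u <- sigm(z[, (h + 1):(2 * h), drop = FALSE] + hu[, (h + 1):(2 * h), drop = FALSE])
      q <- hu[, (2 * h + 1):(3 * h), drop = FALSE]
      n <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE] + r * q)
      h_new <- (1 - u) * n + u * hs
      cache[[t]] <- list(r = r, u = u, n = n, q = q, h_prev = hs)
    }
    H[rows, ] <- h_new
    hs <- h_new
  }
  list(H = H, cache = cache)
}

# BPTT for one direction; returns list(dX, dW, dU, db)
rnn_bptt <- function(kind, X, dH, B, L, W, U, h, cache) {
  din <- ncol(X)
  ng <- if (kind == "lstm") 4L else 3L
  dXW <- matrix(0, B * L, ng * h)   # grads w.r.t. the input projections
  dU <- matrix(0, h, ng * h)
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(L))) {
    rows <- (seq_len(B) - 1L) * L + t
    dh <- dH[rows, , drop = FALSE] + dh_next
    cc <- cache[[t]]
    if (kind == "lstm") {
      do <- dh * cc$tc
      dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
      di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
      dc_next <- dc * cc$f
      dz <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do * cc$o * (1 - cc$o))
      dh_next <- tcrossprod(dz, U)
    } else {
      dn <- dh * (1 - cc$u)
      du <- dh * (cc$h_prev - cc$n)
      dh_prev <- dh * cc$u
      dan <- dn * (1 - cc$n^2)
      dr <- dan * cc$q
      dq <- dan * cc$r
      dz <- cbind(dr * cc$r * (1 - cc$r),
                  du * cc$u * (1 - cc$u),
                  dan)
      # hidden-path grads: r,u gates use U directly; candidate via q
      dhu <- cbind(dz[, 1:h, drop = FALSE], dz[, (h + 1):(2 * h), drop = FALSE], dq)
      dh_next <- dh_prev + tcrossprod(dhu, U)
      dU <- dU + crossprod(cc$h_prev, dhu)
    }
    if (kind == "lstm") dU <- dU + crossprod(cc$h_prev, dz)
    dXW[rows, ] <- dz
  }
  list(dX = tcrossprod(dXW, W),
       dW = crossprod(X, dXW),
       db = colSums(dXW),
       dU = dU)
}

rnn_forward <- function(ly, tx, training) {
  B <- tx$B; L <- tx$L; h <- ly$hidden
  fw <- rnn_run(ly$kind, tx$x, B, L, ly$params$W, ly$params$U, ly$params$b, h)
  if (!ly$bidirectional) {
    ly$cache <- list(x = tx$x, fw = fw$cache, B = B, L = L)
    ly$out_shape <- c(L, h)
    return(list(x = fw$H, B = B, L = L))
  }
  rev_idx <- as.vector(t(outer((seq_len(B) - 1L) * L, rev(seq_len(L)), "+")))
  xr <- tx$x[rev_idx, , drop = FALSE]
  bw <- rnn_run(ly$kind, xr, B, L, ly$params$Wr, ly$params$Ur, ly$params$br, h)
  ly$cache <- list(x = tx$x, xr = xr, fw = fw$cache, bw = bw$cache,
                   rev_idx = rev_idx, B = B, L = L)
  ly$out_shape <- c(L, 2L * h)
  list(x = cbind(fw$H, bw$H[rev_idx, , drop = FALSE]), B = B, L = L)
}

rnn_backward <- function(ly, dy) {
  cc <- ly$cache; B <- cc$B; L <- cc$L; h <- ly$hidden
  if (!ly$bidirectional) {
    g <- rnn_bptt(ly$kind, cc$x, dy, B, L, ly$params$W, ly$params$U, h, cc$fw)
    ly$grads$W <- g$dW; ly$grads$U <- g$dU; ly$grads$b <- g$db
    return(g$dX)
  }
  dfw <- dy[, 1:h, drop = FALSE]
  dbw <- dy[, (h + 1):(2 * h), drop = FALSE][cc$rev_idx, , drop = FALSE]
  g1 <- rnn_bptt(ly$kind, cc$x, dfw, B, L, ly$params$W, ly$params$U, h, cc$fw)
  g2 <- rnn_bptt(ly$kind, cc$xr, dbw, B, L, ly$params$Wr, ly$params$Ur, h, cc$bw)
  ly$grads$W <- g1$dW; ly$grads$U <- g1$dU; ly$grads$b <- g1$db
  ly$grads$Wr <- g2$dW; ly$grads$Ur <- g2$dU; ly$grads$br <- g2$db
  g1$dX + g2$dX[cc$rev_idx, , drop = FALSE]
}

# -- causal dilated convolution (TCN) -----------------------------------------

layer_cconv <- function(din, dout, w, dil, act = "relu") {
  new_layer("cconv",
            params = list(W = glorot(w * din, dout), b = numeric(dout)),
            w = w, dil = dil, din = din, dout = dout, act = act)
}

# gather indices into a zero-padded matrix (row 1 = zero row) for causal
# convolution: output t reads input t - (w-1-j)*dil for tap j = 1..w
cconv_idx <- function(B, L, w, dil) {
  lapply(seq_len(w), function(j) {
    src <- seq_len(L) - (w - j) * dil
    idx <- outer((seq_len(B) - 1L) * L, src, "+") + 1L  # +1: padded row offset
    idx[, src < 1L] <- 1L
    as.vector(t(idx))
  })
}

cconv_forward <- function(ly, tx) {
  B <- tx$B; L <- tx$L
  idx <- cconv_idx(B, L, ly$w, ly$dil)
  xpad <- rbind(0, tx$x)
  col <- do.call(cbind, lapply(idx, function(i) xpad[i, , drop = FALSE]))
  y <- add_bias(col %*% ly$params$W, ly$params$b)
  a <- act_fwd(y, ly$act)
  ly$cache <- list(col = col, idx = idx, a = a, L = L, din = ncol(tx$x))
  ly$out_shape <- c(L, ly$dout)
  list(x = a, B = B, L = L)
}

cconv_backward <- function(ly, dy) {
  dz <- act_bwd(dy, ly$cache$a, ly$act)
  ly$grads$W <- crossprod(ly$cache$col, dz)
  ly$grads$b <- colSums(dz)
  dcol <- tcrossprod(dz, ly$params$W)
  din <- ly$cache$din
  B <- nrow(dz) / ly$cache$L
  dXpad <- matrix(0, B * ly$cache$L + 1L, din)
  for (j in seq_len(ly$w)) {
    blk <- ((j - 1L) * din + 1L):(j * din)
    i <- ly$cache$idx[[j]]
    ok <- i > 1L   # drop contributions landing on the zero pad row
    dXpad[i[ok], ] <- dXpad[i[ok], ] + dcol[ok, blk, drop = FALSE]
  }
  dXpad[-1L, , drop = FALSE]
}

# TCN residual block: two causal dilated convs + identity/1x1 shortcut,
# output ReLU.  Stacked with growing dilations to widen the receptive field.
layer_tcnblock <- function(din, filters, w = 3L, dil = 1L) {
  sub <- list(c1 = layer_cconv(din, filters, w, dil, act = "relu"),
              c2 = layer_cconv(filters, filters, w, dil, act = "linear"))
  if (din != filters) sub$proj <- layer_dense(din, filters, act = "linear")
  new_layer("tcnblock", sub = sub, dout = filters)
}
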