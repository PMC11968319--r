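# Minimal neural-network kernel: layers as mutable environments with
# hand-written forward/backward passes over base-R matrix ops (BLAS).
#
# Sequence activations use a sample-major matrix layout: a batch of B
# sequences of length L with D features is a (B*L) x D matrix whose row
# (b-1)*L + t is token t of sample b.  Position-wise ops (dense, layernorm)
# are then single GEMMs; convolutions use gather/scatter index vectors; only
# attention and recurrence loop over samples/time.
#
# Every layer environment carries: type, params (named list), grads (same
# shapes, written by backward), cache (written by forward), out_shape.

new_layer <- function(type, params = list(), ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$params <- params
  ly$grads <- list()
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = ly)
  class(ly) <- "bw_layer"
  ly
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -sqrt(6 / (nin + nout)), sqrt(6 / (nin + nout))),
         nin, nout)
}

layer_dense <- function(din, dout, act = "linear") {
  new_layer("dense", params = list(W = glorot(din, dout), b = numeric(dout)),
            act = act, din = din, dout = dout)
}

layer_conv1d <- function(din, dout, w, act = "relu") {
  new_layer("conv1d",
            params = list(W = glorot(w * din, dout), b = numeric(dout)),
            w = w, din = din, dout = dout, act = act)
}

layer_maxpool <- function(w) new_layer("maxpool", w = w)

layer_dropout <- function(p) new_layer("dropout", rate = p)

layer_flatten <- function() new_layer("flatten")

layer_layernorm <- function(d, eps = 1e-5) {
  new_layer("layernorm", params = list(g = rep(1, d), b = numeric(d)), eps = eps)
}

layer_posenc <- function() new_layer("posenc")

layer_mha <- function(d, heads) {
  if (d %% heads != 0) stopf("model dim %d not divisible by %d heads", d, heads)
  new_layer("mha",
            params = list(Wq = glorot(d, d), bq = numeric(d),
                          Wk = glorot(d, d), bk = numeric(d),
                          Wv = glorot(d, d), bv = numeric(d),
                          Wo = glorot(d, d), bo = numeric(d)),
            d = d, heads = heads, dh = d %/% heads, capture = FALSE)
}

# Pre-norm transformer encoder block with dropout on both residual branches:
#   x1 = x + Drop(MHA(LN1(x)));  y = x1 + Drop(W2 relu(W1 LN2(x1)))
layer_transformer <- function(d, heads, ff_mult = 2, p_drop = 0.1) {
  new_layer("transformer",
            sub = list(ln1 = layer_layernorm(d),
                       mha = layer_mha(d, heads),
                       dropm = layer_dropout(p_drop),
                       ln2 = layer_layernorm(d),
                       ff1 = layer_dense(d, ff_mult * d, act = "relu"),
                       ff2 = layer_dense(ff_mult * d, d, act = "linear"),
                       dropf = layer_dropout(p_drop)),
            d = d)
}

# recursive traversal: all parameterized leaf layers under a layer list
collect_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (!is.null(ly$sub)) out <- c(out, collect_layers(ly$sub))
    else if (length(ly$params)) out <- c(out, list(ly))
  }
  out
}

# -- index helpers for the sample-major layout --------------------------------

# rows of output position t (t = 1..Lout) gathered from input position t + off
gather_idx <- function(B, L, Lout, off) {
  as.vector(t(outer((seq_len(B) - 1L) * L, seq_len(Lout) + off, "+")))
}

act_fwd <- function(y, act) if (act == "relu") y * (y > 0) else y
act_bwd <- function(dy, y, act) if (act == "relu") dy * (y > 0) else dy

# add a per-column bias vector to a matrix (cheaper than sweep())
add_bias <- function(y, b) y + rep(b, rep.int(nrow(y), length(b)))

softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

# -- forward ------------------------------------------------------------------

# tx: list(x = matrix, B = batch size, L = sequence length or NULL)
layer_forward <- function(ly, tx, training = FALSE) {
  switch(ly$type,
    dense = {
      y <- add_bias(tx$x %*% ly$params$W, ly$params$b)
      a <- act_fwd(y, ly$act)
      ly$cache <- list(x = tx$x, a = a)
      ly$out_shape <- c(tx$L, ncol(a))
      list(x = a, B = tx$B, L = tx$L)
    },
    conv1d = {
      w <- ly$w; L <- tx$L; Lout <- L - w + 1L
      if (Lout < 1L) stopf("conv1d kernel %d does not fit length %d", w, L)
      idx <- lapply(seq_len(w) - 1L, gather_idx, B = tx$B, L = L, Lout = Lout)
      col <- do.call(cbind, lapply(idx, function(i) tx$x[i, , drop = FALSE]))
      y <- add_bias(col %*% ly$params$W, ly$params$b)
      a <- act_fwd(y, ly$act)
      ly$cache <- list(col = col, idx = idx, a = a, L = L, din = ncol(tx$x))
      ly$out_shape <- c(Lout, ly$dout)
      list(x = a, B = tx$B, L = Lout)
    },
    maxpool = {
      w <- ly$w; L <- tx$L; Lout <- L - w + 1L
      if (Lout < 1L) stopf("maxpool width %d does not fit length %d", w, L)
      idx <- lapply(seq_len(w) - 1L, gather_idx, B = tx$B, L = L, Lout = Lout)
      y <- tx$x[idx[[1]], , drop = FALSE]
      amax <- matrix(1L, nrow(y), ncol(y))
      for (j in 2:w) {
        xj <- tx$x[idx[[j]], , drop = FALSE]
        upd <- xj > y
        y[upd] <- xj[upd]
        amax[upd] <- j
      }
      ly$cache <- list(idx = idx, amax = amax, L = L, din = ncol(tx$x))
      ly$out_shape <- c(Lout, ncol(y))
      list(x = y, B = tx$B, L = Lout)
    },
    dropout = {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(tx$x)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(tx$x)
        ly$cache <- list(mask = mask)
        out <- tx$x * mask
      } else {
        ly$cache <- list(mask = NULL)
        out <- tx$x
      }
      ly$out_shape <- c(tx$L, ncol(out))
      list(x = out, B = tx$B, L = tx$L)
    },
    flatten = {
      stopifnot(!is.null(tx$L))
      L <- tx$L; D <- ncol(tx$x); B <- tx$B
      # rows are (b, t) with t fastest within b; per sample, features are laid
      # out position-major: one aperm does it
      y <- matrix(aperm(array(tx$x, c(L, B, D)), c(2L, 3L, 1L)), B, L * D)
      ly$cache <- list(L = L, D = D)
      ly$out_shape <- ncol(y)
      list(x = y, B = B, L = NULL)
    },
    layernorm = {
      mu <- rowMeans(tx$x)
      xc <- tx$x - mu
      v <- rowMeans(xc * xc)
      istd <- 1 / sqrt(v + ly$eps)
      xhat <- xc * istd
      nr <- nrow(xhat)
      y <- add_bias(xhat * rep(ly$params$g, rep.int(nr, length(ly$params$g))),
                    ly$params$b)
      ly$cache <- list(xhat = xhat, istd = istd)
      ly$out_shape <- c(tx$L, ncol(y))
      list(x = y, B = tx$B, L = tx$L)
    },
    posenc = {
      L <- tx$L; D <- ncol(tx$x)
      key <- paste0(L, "x", D, "x", tx$B)
      if (is.null(ly$cache) || !identical(ly$cache$key, key))
        ly$cache <- list(key = key,
                         pe = sinusoidal_pe(L, D)[rep(seq_len(L), tx$B), ,
                                                  drop = FALSE])
      ly$out_shape <- c(L, D)
      list(x = tx$x + ly$cache$pe, B = tx$B, L = L)
    },
    mha = mha_forward(ly, tx, training),
    transformer = {
      s <- ly$sub
      a <- layer_forward(s$ln1, tx, training)
      m <- layer_forward(s$dropm, layer_forward(s$mha, a, training), training)
      x1 <- list(x = tx$x + m$x, B = tx$B, L = tx$L)
      b <- layer_forward(s$ln2, x1, training)
      f <- layer_forward(s$dropf,
             layer_forward(s$ff2,
               layer_forward(s$ff1, b, training), training), training)
      ly$out_shape <- c(tx$L, ncol(tx$x))
      list(x = x1$x + f$x, B = tx$B, L = tx$L)
    },
    rnn = rnn_forward(ly, tx, training),
    cconv = cconv_forward(ly, tx),
    tcnblock = {
      s <- ly$sub
      h <- layer_forward(s$c2, layer_forward(s$c1, tx, training), training)
      res <- if (!is.null(s$proj)) layer_forward(s$proj, tx, training) else tx
      y <- pmax(h$x + res$x, 0)
      ly$cache <- list(pos = y > 0)
      ly$out_shape <- c(tx$L, ncol(y))
      list(x = y, B = tx$B, L = tx$L)
    },
    stopf("unknown layer type %s", ly$type))
}

# -- backward -----------------------------------------------------------------

layer_backward <- function(ly, dy) {
  switch(ly$type,
    dense = {
      dz <- act_bwd(dy, ly$cache$a, ly$act)
      ly$grads$W <- crossprod(ly$cache$x, dz)
      ly$grads$b <- colSums(dz)
      tcrossprod(dz, ly$params$W)
    },
    conv1d = {
      dz <- act_bwd(dy, ly$cache$a, ly$act)
      ly$grads$W <- crossprod(ly$cache$col, dz)
      ly$grads$b <- colSums(dz)
      dcol <- tcrossprod(dz, ly$params$W)
      din <- ly$cache$din
      B <- nrow(dz) / (ly$cache$L - ly$w + 1L)
      dX <- matrix(0, B * ly$cache$L, din)
      for (j in seq_len(ly$w)) {
        blk <- ((j - 1L) * din + 1L):(j * din)
        i <- ly$cache$idx[[j]]
        dX[i, ] <- dX[i, ] + dcol[, blk, drop = FALSE]
      }
      dX
    },
    maxpool = {
      w <- ly$w; din <- ly$cache$din
      B <- nrow(dy) / (ly$cache$L - w + 1L)
      dX <- matrix(0, B * ly$cache$L, din)
      for (j in seq_len(w)) {
        m <- dy * (ly$cache$amax == j)
        i <- ly$cache$idx[[j]]
        dX[i, ] <- dX[i, ] + m
      }
      dX
    },
    dropout = if (is.null(ly$cache$mask)) dy else dy * ly$cache$mask,
    flatten = {
      L <- ly$cache$L; D <- ly$cache$D; B <- nrow(dy)
      matrix(aperm(array(dy, c(B, D, L)), c(3L, 1L, 2L)), B * L, D)
    },
    layernorm = {
      xhat <- ly$cache$xhat; istd <- ly$cache$istd
      ly$grads$g <- colSums(dy * xhat)
      ly$grads$b <- colSums(dy)
      dxhat <- dy * rep(ly$params$g, rep.int(nrow(dy), length(ly$params$g)))
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    },
    posenc = dy,
    mha = mha_backward(ly, dy),
    transformer = {
      s <- ly$sub
      db <- layer_backward(s$ff1,
              layer_backward(s$ff2,
                layer_backward(s$dropf, dy)))
      dx1 <- dy + layer_backward(s$ln2, db)
      dm <- layer_backward(s$mha, layer_backward(s$dropm, dx1))
      dx1 + layer_backward(s$ln1, dm)
    },
    rnn = rnn_backward(ly, dy),
    cconv = cconv_backward(ly, dy),
    tcnblock = {
      s <- ly$sub
      dh <- dy * ly$cache$pos
      dx <- layer_backward(s$c1, layer_backward(s$c2, dh))
      dres <- if (!is.null(s$proj)) layer_backward(s$proj, dh) else dh
      dx + dres
    },
    stopf("unknown layer type %s", ly$type))
}

# -- attention ----------------------------------------------------------------

sinusoidal_pe <- function(L, D) {
  pos <- seq_len(L) - 1L
  i <- seq_len(D) - 1L
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / D))
  pe <- matrix(0, L, D)
  even <- which(i %% 2 == 0L)
  odd <- which(i %% 2 == 1L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

mha_forward <- function(ly, tx, training) {
  d <- ly$d; nh <- ly$heads; dh <- ly$dh
  B <- tx$B; L <- tx$L
  Q <- add_bias(tx$x %*% ly$params$Wq, ly$params$bq)
  K <- add_bias(tx$x %*% ly$params$Wk, ly$params$bk)
  V <- add_bias(tx$x %*% ly$params$Wv, ly$params$bv)
  O <- matrix(0, B * L, d)
  P_all <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    Pb <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dh)
      P <- softmax_rows(S)
      Pb[[h]] <- P
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
    P_all[[b]] <- Pb
  }
  Y <- add_bias(O %*% ly$params$Wo, ly$params$bo)
  ly$cache <- list(x = tx$x, Q = Q, K = K, V = V, O = O, P = P_all,
                   B = B, L = L)
  if (ly$capture) ly$attn <- P_all
  ly$out_shape <- c(L, d)
  list(x = Y, B = B, L = L)
}

mha_backward <- function(ly, dy) {
  cc <- ly$cache
  d <- ly$d; nh <- ly$heads; dh <- ly$dh; B <- cc$B; L <- cc$L
  ly$grads$Wo <- crossprod(cc$O, dy)
  ly$grads$bo <- colSums(dy)
  dO <- tcrossprod(dy, ly$params$Wo)
  dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- cc$P[[b]][[h]]
      dOb <- dO[rows, cols, drop = FALSE]
      dP <- tcrossprod(dOb, cc$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(P, dOb)
      dS <- P * (dP - rowSums(dP * P))
      dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  ly$grads$Wq <- crossprod(cc$x, dQ); ly$grads$bq <- colSums(dQ)
  ly$grads$Wk <- crossprod(cc$x, dK); ly$grads$bk <- colSums(dK)
  ly$grads$Wv <- crossprod(cc$x, dV); ly$grads$bv <- colSums(dV)
  tcrossprod(dQ, ly$params$Wq) + tcrossprod(dK, ly$params$Wk) +
    tcrossprod(dV, ly$params$Wv)
}
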