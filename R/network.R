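# Dual-channel classifier architecture.
#
# Channel 1 (1mer view, length 100 x d): three valid-padding 1D convolutions
# (kernel 3, filters 128/128/256, ReLU), width-3 stride-1 max-pooling,
# dropout, three transformer encoder blocks (model dim 256), flatten, then a
# dense chain 128 -> 64 -> 32.  Channel 2 (4mer view, length 97 x d): three
# transformer encoder blocks at model dim d, flatten.  Fusion: concatenate
# (32 + 97*d), dense 64, dropout, dense 64, sigmoid output.
#
# shape_plan() reproduces every layer's output shape by pure arithmetic
# (valid conv: L - kernel + 1; stride-1 pool: L - width + 1; transformer
# blocks shape-preserving; flatten: L * D) and is the oracle the realized
# models are checked against at build time.

#' Configuration of the dual-channel classifier
#'
#' @param d embedding dimension feeding both channels.
#' @param len1,len2 token counts of the two channels; defaults 100 and 97 are
#'   the stride-1 1mer and 4mer counts of a 100-residue peptide.
#' @param conv_filters filter counts of the three channel-1 convolutions.
#' @param conv_kernel convolution kernel width (valid padding).
#' @param pool_width max-pool width (stride 1).
#' @param blocks1,blocks2 number of transformer encoder blocks per channel.
#' @param heads1,heads2 attention heads per channel (must divide the
#'   channel's model dimension).
#' @param ff_mult feed-forward width multiplier inside transformer blocks.
#' @param dense1 widths of the channel-1 dense chain after flatten.
#' @param fusion widths of the fusion head dense layers.
#' @param dropout_dense dropout rate after pooling / flatten / fusion dense
#'   (the dense-path placements customary in this architecture).
#' @param dropout_attn dropout rate on the two residual branches inside each
#'   transformer block; 0 by default (regularization lives in the dense
#'   paths), available for larger datasets.
#' @param positional add fixed sinusoidal positional encodings at each
#'   transformer stack input.
#' @param seq1,seq2 sequence module per channel: `"transformer"`, `"bilstm"`,
#'   `"tcn"`, `"lstm"`, `"gru"`, `"bigru"`, or `"none"` (module absent).
#' @param use_cnn keep the channel-1 convolution/pooling stack.
#' @param channel1,channel2 keep the whole channel (at least one required).
#' @param seq_width1,seq_width2 output feature width of non-transformer
#'   sequence modules; defaults to the channel's model dimension.
#' @return object of class `channel_config`.
#' @export
channel_config <- function(d = 150L, len1 = 100L, len2 = 97L,
                           conv_filters = c(128L, 128L, 256L),
                           conv_kernel = 3L, pool_width = 3L,
                           blocks1 = 3L, blocks2 = 3L,
                           heads1 = 4L, heads2 = 2L, ff_mult = 2L,
                           dense1 = c(128L, 64L, 32L),
                           fusion = c(64L, 64L),
                           dropout_dense = 0.3, dropout_attn = 0,
                           positional = TRUE,
                           seq1 = "transformer", seq2 = "transformer",
                           use_cnn = TRUE, channel1 = TRUE, channel2 = TRUE,
                           seq_width1 = NULL, seq_width2 = NULL) {
  kinds <- c("transformer", "bilstm", "tcn", "lstm", "gru", "bigru", "none")
  if (!seq1 %in% kinds || !seq2 %in% kinds)
    stopf("unknown sequence module; valid kinds: %s", paste(kinds, collapse = ", "))
  if (!channel1 && !channel2) stopf("at least one channel must be enabled")
  if (channel1 && !use_cnn && seq1 == "none" && channel2) channel1 <- FALSE
  structure(list(d = d, len1 = len1, len2 = len2,
                 conv_filters = conv_filters, conv_kernel = conv_kernel,
                 pool_width = pool_width, blocks1 = blocks1, blocks2 = blocks2,
                 heads1 = heads1, heads2 = heads2, ff_mult = ff_mult,
                 dense1 = dense1, fusion = fusion,
                 dropout_dense = dropout_dense, dropout_attn = dropout_attn,
                 positional = positional, seq1 = seq1, seq2 = seq2,
                 use_cnn = use_cnn, channel1 = channel1, channel2 = channel2,
                 seq_width1 = seq_width1, seq_width2 = seq_width2),
            class = "channel_config")
}

# feature width a sequence module emits given its input width
seq_module_width <- function(kind, din, want) {
  switch(kind,
    transformer = din,
    none = din,
    bilstm = ,
    bigru = 2L * ((want %||% din) %/% 2L),
    lstm = ,
    gru = ,
    tcn = (want %||% din))
}

# largest head count <= want that divides d
pick_heads <- function(d, want) {
  for (h in rev(seq_len(want))) if (d %% h == 0L) return(h)
  1L
}

#' Per-layer output shapes of a configuration (pure arithmetic)
#'
#' Computes the shape every layer of the configured model will produce,
#' without instantiating any weights.  Errors (naming the layer) if an
#' intermediate length becomes non-positive.
#'
#' @param cfg a [channel_config()].
#' @return object of class `shape_plan`: data.frame with columns `stage`,
#'   `layer`, `out_len` (NA for vector stages), `out_dim`; attributes
#'   `flatten1`, `flatten2`, `fused` give the key widths.
#' @examples
#' plan <- shape_plan(channel_config())
#' attr(plan, "fused")  # 14582 for the default architecture
#' @export
shape_plan <- function(cfg) {
  stopifnot(inherits(cfg, "channel_config"))
  rows <- list()
  add <- function(stage, layer, len, dim)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, layer = layer,
                                             out_len = len, out_dim = dim)
  need_pos <- function(len, layer)
    if (len < 1L) stopf("layer %s yields non-positive length %d", layer, len)

  flat1 <- NULL
  if (cfg$channel1) {
    L <- cfg$len1; D <- cfg$d
    add("channel1", "Input", L, D)
    if (cfg$use_cnn) {
      for (i in seq_along(cfg$conv_filters)) {
        L <- L - cfg$conv_kernel + 1L
        need_pos(L, sprintf("Conv1D_%d", i))
        D <- cfg$conv_filters[i]
        add("channel1", sprintf("Conv1D_%d", i), L, D)
      }
      L <- L - cfg$pool_width + 1L
      need_pos(L, "MaxPooling1D")
      add("channel1", "MaxPooling1D", L, D)
      add("channel1", "Dropout", L, D)
    }
    if (cfg$seq1 != "none") {
      D <- seq_module_width(cfg$seq1, D, cfg$seq_width1)
      add("channel1", sprintf("%s*%d",
                              if (cfg$seq1 == "transformer") "Transformer encoder"
                              else toupper(cfg$seq1), cfg$blocks1), L, D)
    }
    flat1 <- L * D
    add("channel1", "Flatten", NA_integer_, flat1)
    add("channel1", "Dropout", NA_integer_, flat1)
    D <- flat1
    for (i in seq_along(cfg$dense1)) {
      add("channel1", sprintf("Dense_%d", i), NA_integer_, cfg$dense1[i])
      D <- cfg$dense1[i]
    }
    ch1_out <- D
  } else ch1_out <- 0L

  flat2 <- NULL
  if (cfg$channel2) {
    L <- cfg$len2; D <- cfg$d
    add("channel2", "Input", L, D)
    if (cfg$seq2 != "none") {
      D <- seq_module_width(cfg$seq2, D, cfg$seq_width2)
      add("channel2", sprintf("%s*%d",
                              if (cfg$seq2 == "transformer") "Transformer encoder"
                              else toupper(cfg$seq2), cfg$blocks2), L, D)
    }
    flat2 <- L * D
    add("channel2", "Flatten", NA_integer_, flat2)
    ch2_out <- flat2
  } else ch2_out <- 0L

  fused <- ch1_out + ch2_out
  add("fusion", "Concatenation", NA_integer_, fused)
  D <- fused
  for (i in seq_along(cfg$fusion)) {
    add("fusion", sprintf("Dense_%d", i), NA_integer_, cfg$fusion[i])
    if (i == 1L) add("fusion", "Dropout", NA_integer_, cfg$fusion[i])
    D <- cfg$fusion[i]
  }
  add("fusion", "Output", NA_integer_, 1L)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("shape_plan", "data.frame"),
            flatten1 = flat1, flatten2 = flat2, fused = fused)
}

#' @export
print.shape_plan <- function(x, ...) {
  cat("<shape_plan>\n")
  sh <- ifelse(is.na(x$out_len),
               sprintf("(None, %d)", x$out_dim),
               sprintf("(None, %d, %d)", x$out_len, x$out_dim))
  for (st in unique(x$stage)) {
    cat(" ", st, "\n")
    sel <- x$stage == st
    cat(paste0("    ", format(x$layer[sel], width = 24), sh[sel],
               collapse = "\n"), "\n")
  }
  invisible(x)
}

# sequence-module layer stack for one channel
make_seq_module <- function(kind, din, blocks, heads, ff_mult, p_attn, width) {
  switch(kind,
    transformer = lapply(seq_len(blocks), function(i)
      layer_transformer(din, pick_heads(din, heads), ff_mult, p_attn)),
    lstm = list(layer_rnn(din, width %||% din, "lstm")),
    gru = list(layer_rnn(din, width %||% din, "gru")),
    bilstm = list(layer_rnn(din, ((width %||% din) %/% 2L), "lstm",
                            bidirectional = TRUE)),
    bigru = list(layer_rnn(din, ((width %||% din) %/% 2L), "gru",
                           bidirectional = TRUE)),
    tcn = {
      f <- width %||% din
      dil <- 2^(seq_len(blocks) - 1L)
      ins <- c(din, rep(f, blocks - 1L))
      lapply(seq_len(blocks), function(i) layer_tcnblock(ins[i], f, 3L, dil[i]))
    },
    none = list())
}

#' Build the dual-channel classifier
#'
#' Instantiates the network described by `cfg` with seeded weight
#' initialization, then self-checks: the realized output shape of every layer
#' must equal [shape_plan()] exactly, otherwise construction aborts.
#'
#' @param cfg a [channel_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `bwr_net`.
#' @export
build_model <- function(cfg = channel_config(), seed = 1L) {
  plan <- shape_plan(cfg)  # errors early on degenerate configs
  with_rng(seed, "net-init", {
    ch1 <- list()
    if (cfg$channel1) {
      D <- cfg$d
      if (cfg$use_cnn) {
        for (i in seq_along(cfg$conv_filters)) {
          ch1 <- c(ch1, list(layer_conv1d(D, cfg$conv_filters[i], cfg$conv_kernel)))
          D <- cfg$conv_filters[i]
        }
        ch1 <- c(ch1, list(layer_maxpool(cfg$pool_width),
                           layer_dropout(cfg$dropout_dense)))
      }
      if (cfg$seq1 != "none") {
        if (cfg$seq1 == "transformer" && cfg$positional)
          ch1 <- c(ch1, list(layer_posenc()))
        ch1 <- c(ch1, make_seq_module(cfg$seq1, D, cfg$blocks1, cfg$heads1,
                                      cfg$ff_mult, cfg$dropout_attn,
                                      cfg$seq_width1))
        D <- seq_module_width(cfg$seq1, D, cfg$seq_width1)
      }
      ch1 <- c(ch1, list(layer_flatten(), layer_dropout(cfg$dropout_dense)))
      D <- attr(plan, "flatten1")
      for (width in cfg$dense1) {
        ch1 <- c(ch1, list(layer_dense(D, width, act = "relu")))
        D <- width
      }
    }
    ch2 <- list()
    if (cfg$channel2) {
      D <- cfg$d
      if (cfg$seq2 != "none") {
        if (cfg$seq2 == "transformer" && cfg$positional)
          ch2 <- c(ch2, list(layer_posenc()))
        ch2 <- c(ch2, make_seq_module(cfg$seq2, D, cfg$blocks2, cfg$heads2,
                                      cfg$ff_mult, cfg$dropout_attn,
                                      cfg$seq_width2))
        D <- seq_module_width(cfg$seq2, D, cfg$seq_width2)
      }
      ch2 <- c(ch2, list(layer_flatten()))
    }
    head <- list()
    D <- attr(plan, "fused")
    for (i in seq_along(cfg$fusion)) {
      head <- c(head, list(layer_dense(D, cfg$fusion[i], act = "relu")))
      if (i == 1L) head <- c(head, list(layer_dropout(cfg$dropout_dense)))
      D <- cfg$fusion[i]
    }
    head <- c(head, list(layer_dense(D, 1L, act = "linear")))  # sigmoid in loss
    net <- structure(list(cfg = cfg, plan = plan, ch1 = ch1, ch2 = ch2,
                          head = head, seed = as.integer(seed)),
                     class = "bwr_net")
    check_realized_shapes(net)
    net
  })
}

# Expand the plan table to one expected (out_len, out_dim) row per
# instantiated layer: a "<module>*k" stack row becomes k rows (transformer
# stacks additionally get their shape-preserving positional-encoding row),
# everything else maps one-to-one.
plan_layerwise <- function(net) {
  cfg <- net$cfg
  plan <- net$plan
  out <- list()
  for (r in seq_len(nrow(plan))) {
    row <- plan[r, ]
    if (row$layer %in% c("Input", "Concatenation")) next
    stage <- row$stage
    kind <- if (stage == "channel1") cfg$seq1 else cfg$seq2
    blocks <- if (stage == "channel1") cfg$blocks1 else cfg$blocks2
    reps <- 1L
    if (grepl("\\*", row$layer)) {
      reps <- switch(kind,
                     transformer = blocks + as.integer(cfg$positional),
                     tcn = blocks,
                     1L)
    }
    if (row$layer == "Output") row$layer <- "Dense_out"
    out[[length(out) + 1L]] <-
      data.frame(out_len = rep(row$out_len, reps),
                 out_dim = rep(row$out_dim, reps))
  }
  do.call(rbind, out)
}

# forward a zero batch and verify realized per-layer shapes match the plan
check_realized_shapes <- function(net) {
  cfg <- net$cfg
  B <- 2L
  x1 <- if (cfg$channel1) list(x = matrix(0, B * cfg$len1, cfg$d), B = B, L = cfg$len1)
  x2 <- if (cfg$channel2) list(x = matrix(0, B * cfg$len2, cfg$d), B = B, L = cfg$len2)
  out <- net_forward(net, x1, x2, training = FALSE)
  realized <- realized_shapes(net)
  want <- plan_layerwise(net)
  same <- function(a, b) identical(ifelse(is.na(a), -1, as.numeric(a)),
                                   ifelse(is.na(b), -1, as.numeric(b)))
  if (nrow(want) != nrow(realized) ||
      !same(want$out_len, realized$out_len) ||
      !same(want$out_dim, realized$out_dim))
    stopf("realized layer shapes do not match the shape plan")
  if (length(out$p) != B || any(!is.finite(out$p)))
    stopf("model self-check forward pass failed")
  invisible(net)
}

realized_shapes <- function(net) {
  one <- function(ly) {
    sh <- ly$out_shape
    if (length(sh) == 2L) data.frame(out_len = sh[1], out_dim = sh[2])
    else data.frame(out_len = NA_integer_, out_dim = sh[1])
  }
  do.call(rbind, lapply(c(net$ch1, net$ch2, net$head), one))
}

# full network forward; x1/x2 are layout tensors (or NULL for absent channel)
net_forward <- function(net, x1, x2, training = FALSE) {
  feats <- list()
  if (!is.null(x1)) {
    for (ly in net$ch1) x1 <- layer_forward(ly, x1, training)
    feats$f1 <- x1$x
  }
  if (!is.null(x2)) {
    for (ly in net$ch2) x2 <- layer_forward(ly, x2, training)
    feats$f2 <- x2$x
  }
  z <- list(x = do.call(cbind, feats), B = if (!is.null(x1)) x1$B else x2$B,
            L = NULL)
  fused <- z$x
  for (ly in net$head) z <- layer_forward(ly, z, training)
  list(logit = as.vector(z$x), p = as.vector(sigm(z$x)), fused = fused)
}

# backward from dlogit (length B); returns nothing, grads live in the layers
net_backward <- function(net, dlogit) {
  dz <- matrix(dlogit, ncol = 1L)
  for (ly in rev(net$head)) dz <- layer_backward(ly, dz)
  d1 <- if (length(net$ch1)) ncol_from_layers(net$ch1) else 0L
  if (length(net$ch1)) {
    g <- dz[, seq_len(d1), drop = FALSE]
    for (ly in rev(net$ch1)) g <- layer_backward(ly, g)
  }
  if (length(net$ch2)) {
    g <- dz[, (d1 + 1L):ncol(dz), drop = FALSE]
    for (ly in rev(net$ch2)) g <- layer_backward(ly, g)
  }
  invisible(NULL)
}

ncol_from_layers <- function(layers) {
  sh <- layers[[length(layers)]]$out_shape
  if (length(sh) == 2L) sh[2] else sh[1]
}

#' Build an architecture variant with the transformer stacks replaced
#'
#' Both transformer stacks are replaced by the named sequence module
#' (returning full sequences); the rest of the topology is unchanged, with
#' downstream flatten widths recomputed through the shape plan.
#'
#' @param kind one of `"bilstm"`, `"tcn"`, `"lstm"`, `"gru"`, `"bigru"`.
#' @param cfg base [channel_config()].
#' @param seed integer seed.
#' @return a `bwr_net`.
#' @export
build_variant <- function(kind, cfg = channel_config(), seed = 1L) {
  kinds <- c("bilstm", "tcn", "lstm", "gru", "bigru")
  if (!kind %in% kinds)
    stopf("unknown variant kind '%s'; valid kinds: %s", kind,
          paste(kinds, collapse = ", "))
  cfg$seq1 <- kind
  cfg$seq2 <- kind
  build_model(cfg, seed)
}

#' Build an ablation variant of the dual-channel model
#'
#' Disabled modules are removed rather than bypassed: without the CNN the
#' channel-1 transformers consume the raw embedding; without Transformer1 the
#' CNN output flows straight to the channel-1 dense chain; without
#' Transformer2 channel 2 contributes the flattened raw embedding.  With both
#' CNN and Transformer1 disabled, channel 1 is dropped entirely (the
#' channel-2-only model).
#'
#' @param use_cnn,use_t1,use_t2 logical flags; at least one must be TRUE.
#' @param cfg base [channel_config()].
#' @param seed integer seed.
#' @return a `bwr_net`.
#' @export
build_ablation <- function(use_cnn, use_t1, use_t2, cfg = channel_config(),
                           seed = 1L) {
  if (!any(use_cnn, use_t1, use_t2)) stopf("all modules disabled")
  cfg$use_cnn <- use_cnn
  cfg$seq1 <- if (use_t1) "transformer" else "none"
  cfg$seq2 <- if (use_t2) "transformer" else "none"
  if (!use_cnn && !use_t1) cfg$channel1 <- FALSE
  build_model(cfg, seed)
}

#' @export
print.bwr_net <- function(x, ...) {
  np <- sum(vapply(collect_layers(c(x$ch1, x$ch2, x$head)),
                   function(ly) sum(lengths(ly$params)), numeric(1)))
  cat(sprintf("<bwr_net> %s/%s channels, %s params\n",
              if (x$cfg$channel1) x$cfg$seq1 else "-",
              if (x$cfg$channel2) x$cfg$seq2 else "-",
              format(np, big.mark = ",")))
  print(x$plan)
  invisible(x)
}

#' Write / read a channel configuration as a flat key-value file
#'
#' One `key = value` line per field (vectors comma-separated), so
#' configurations can be diffed, versioned and passed to the command-line
#' front end.
#'
#' @param cfg a [channel_config()].
#' @param path file path.
#' @return `path` (write) or the restored `channel_config` (read).
#' @export
write_channel_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "channel_config"))
  fields <- cfg[!vapply(cfg, is.null, logical(1))]
  lines <- vapply(names(fields), function(nm)
    sprintf("%s = %s", nm, paste(fields[[nm]], collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  args <- stats::setNames(lapply(seq_along(keys), function(i) {
    parts <- trimws(strsplit(vals[i], ",")[[1]])
    if (keys[i] %in% c("seq1", "seq2")) return(parts)
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else if (all(num == round(num))) as.integer(num) else num
  }), keys)
  do.call(channel_config, args)
}

#' Total trainable parameter count of a network
#' @param net a `bwr_net`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(collect_layers(c(net$ch1, net$ch2, net$head)),
             function(ly) sum(lengths(ly$params)), numeric(1)))
}
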