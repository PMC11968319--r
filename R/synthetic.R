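# Synthetic peptide data with a controllable k-mer-composition class signal.
#
# Negatives are i.i.d. background sequences; positives are the same
# background with one short motif implanted at a random valid position with a
# given probability.  Lengths for the two classes are drawn from the same
# distribution by construction, so length alone carries no signal -- the
# class difference is purely local k-mer composition, which is exactly what
# the biological-word pipeline is supposed to detect.  The default motifs are
# amphipathic-helix-flavoured (lysine/leucine-rich) 4-5mers; they are
# plausible signal carriers, not claims of biological fidelity.

#' Specification for a synthetic labeled peptide dataset
#'
#' @param n_pos,n_neg class sizes.
#' @param min_len,max_len sequence lengths are uniform on
#'   `[min_len, max_len]` (set equal for fixed length); must stay within
#'   the 5-100 working range.
#' @param background residue sampling probabilities, a named numeric vector
#'   over the 20 amino acids; default uniform 1/20.  See
#'   [background_freqs()] for an empirical-style preset.
#' @param motifs character vector of 3-6 residue motifs implanted in
#'   positives.
#' @param implant_prob probability that a positive receives a motif implant;
#'   1 gives the strongest class signal, 0 makes the classes
#'   indistinguishable (a null control).
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 200L, n_neg = 200L,
                       min_len = 15L, max_len = 50L,
                       background = NULL,
                       motifs = c("KLLKL", "LKKLF", "KWKLL", "FKKL"),
                       implant_prob = 1.0, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            min_len >= 5L, max_len <= 100L, min_len <= max_len,
            implant_prob >= 0, implant_prob <= 1)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(setequal(names(background), AA_ALPHABET), all(background > 0))
  background <- background[AA_ALPHABET] / sum(background)
  if (any(nchar(motifs) > min_len))
    stopf("motif longer than min_len %d: %s", min_len,
          paste(motifs[nchar(motifs) > min_len], collapse = ", "))
  if (!all(is_valid_peptide(motifs))) stopf("motifs must use the 20-letter alphabet")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 background = background, motifs = toupper(motifs),
                 implant_prob = implant_prob, seed = as.integer(seed)),
            class = "synth_spec")
}

rand_seqs <- function(n, lens, background) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = background),
          collapse = ""),
    character(1))
}

#' Generate a synthetic labeled peptide dataset
#'
#' @param spec a [synth_spec()].
#' @return data.frame with `id`, `sequence`, `label` (1 = motif class),
#'   plus a logical `implanted` column recording which positives actually
#'   carry an implant.
#' @examples
#' ds <- generate_dataset(synth_spec(n_pos = 5, n_neg = 5, seed = 42))
#' table(ds$label)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_rng(spec$seed, "synth", {
    span <- spec$max_len - spec$min_len + 1L
    lens_pos <- spec$min_len + sample.int(span, spec$n_pos, replace = TRUE) - 1L
    lens_neg <- spec$min_len + sample.int(span, spec$n_neg, replace = TRUE) - 1L
    pos <- rand_seqs(spec$n_pos, lens_pos, spec$background)
    neg <- rand_seqs(spec$n_neg, lens_neg, spec$background)
    implant <- stats::runif(spec$n_pos) < spec$implant_prob
    for (i in which(implant)) {
      m <- spec$motifs[sample.int(length(spec$motifs), 1L)]
      at <- sample.int(nchar(pos[i]) - nchar(m) + 1L, 1L)
      substr(pos[i], at, at + nchar(m) - 1L) <- m
    }
    data.frame(
      id = c(sprintf("pos_%04d", seq_len(spec$n_pos)),
             sprintf("neg_%04d", seq_len(spec$n_neg))),
      sequence = c(pos, neg),
      label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
      implanted = c(implant, rep(FALSE, spec$n_neg)),
      stringsAsFactors = FALSE)
  })
}

#' Empirical-style background residue frequencies
#'
#' A fixed preset loosely shaped like natural bioactive-peptide composition
#' (leucine/lysine/glycine-heavy, tryptophan/cysteine-poor), for generating
#' more realistic-looking backgrounds than the uniform default.
#' @return named numeric vector over the 20 residues summing to 1.
#' @export
background_freqs <- function() {
  f <- c(A = 8.3, C = 1.9, D = 4.1, E = 5.0, F = 4.4, G = 8.9, H = 2.2,
         I = 5.6, K = 9.1, L = 9.8, M = 1.8, N = 3.9, P = 4.4, Q = 3.2,
         R = 5.6, S = 6.4, T = 4.8, V = 6.3, W = 1.5, Y = 2.8)
  f / sum(f)
}

#' Worked tokenizer example: the peptide ACEKLHET
#'
#' Returns the fixture used by the tokenizer golden tests: the sequence
#' `"ACEKLHET"` together with its expected stride-1 1mer and 4mer word lists.
#' @return list with `sequence`, `kmers1`, `kmers4`.
#' @export
worked_example_fixture <- function() {
  list(sequence = "ACEKLHET",
       kmers1 = c("A", "C", "E", "K", "L", "H", "E", "T"),
       kmers4 = c("ACEK", "CEKL", "EKLH", "KLHE", "LHET"))
}

#' Randomly permute the labels of a dataset (null control)
#'
#' The multiset of labels is preserved; only the pairing of label to sequence
#' is shuffled.  Used to build label-permuted controls for which any
#' classifier should score at chance.
#'
#' @param ds labeled data.frame.
#' @param seed integer seed.
#' @return `ds` with permuted `label` column.
#' @export
permute_labels <- function(ds, seed = 1L) {
  check_labeled(ds)
  ds$label <- with_rng(seed, "permute-labels", sample(ds$label))
  ds
}
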