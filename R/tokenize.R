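# Biological-word tokenization: overlapping k-mers over peptide sequences.
#
# A "biological word" is a k-residue window slid along the sequence with a
# fixed stride.  1mers stand for individual (loop) residues; 4mers cover
# roughly one alpha-helix turn (~3.6-3.7 residues per turn), so the two word
# sizes give complementary views of local structure.

#' Tokenize a peptide sequence into overlapping k-mer words
#'
#' Words are `substr(sequence, i, i + k - 1)` for `i = 1, 1 + stride,
#' 1 + 2 * stride, ...` while the window fits; a sequence shorter than `k`
#' yields no words.  For sequence length `L >= k` the number of words is
#' `floor((L - k) / stride) + 1`.
#'
#' @param sequence single uppercase peptide string over the 20-letter alphabet.
#' @param k word length in residues (>= 1).
#' @param stride step size in residues (>= 1); the default stride of 1 gives
#'   maximally overlapping words, which works best in practice.
#' @return character vector of words, in sequence order.
#' @examples
#' tokenize_kmers("ACEKLHET", k = 4)  # "ACEK" "CEKL" "EKLH" "KLHE" "LHET"
#' tokenize_kmers("ACEKLHET", k = 1)
#' @export
tokenize_kmers <- function(sequence, k, stride = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (k < 1L) stopf("k must be >= 1 (got %s)", k)
  if (stride < 1L) stopf("stride must be >= 1 (got %s)", stride)
  L <- nchar(sequence)
  if (L < k) return(character(0))
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(sequence, starts, starts + k - 1L)
}

#' Number of k-mer words produced for a given sequence length
#'
#' @param L sequence length in residues.
#' @inheritParams tokenize_kmers
#' @return integer word count, `floor((L - k) / stride) + 1` when `L >= k`,
#'   else 0.
#' @export
kmer_count <- function(L, k, stride = 1L) {
  ifelse(L >= k, (L - k) %/% stride + 1L, 0L)
}

#' Build a word vocabulary from a tokenized corpus
#'
#' Indices are assigned by descending corpus frequency with lexicographic
#' tie-break, so the assignment is deterministic.  Index 0 is reserved for
#' out-of-vocabulary words (unseen at training time or below `min_count`).
#'
#' @param corpus list of character vectors, one word list per sequence; all
#'   words must share one length `k`.
#' @param min_count minimum corpus frequency for a word to be kept.
#' @return an object of class `bw_vocabulary`: list with `words` (index ->
#'   word, 1-based; index 0 is OOV and never maps to a word), `k`, and
#'   `counts` (frequencies, same order as `words`).
#' @examples
#' v <- build_vocabulary(list(c("AC", "CE"), c("AC")))
#' v$words
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  stopifnot(is.list(corpus))
  words <- unlist(corpus, use.names = FALSE)
  if (length(words) == 0L) stopf("empty corpus: no words to build a vocabulary from")
  k <- unique(nchar(words))
  if (length(k) != 1L)
    stopf("mixed word lengths in corpus: %s", paste(k, collapse = ", "))
  tab <- table(words)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) stopf("no word reaches min_count = %d", min_count)
  # descending frequency, ties lexicographic
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  structure(list(words = names(tab)[ord],
                 counts = as.integer(tab)[ord],
                 k = as.integer(k)),
            class = "bw_vocabulary")
}

#' @export
print.bw_vocabulary <- function(x, ...) {
  cat(sprintf("<bw_vocabulary> %d words of length %d (index 0 = OOV)\n",
              length(x$words), x$k))
  n <- min(8L, length(x$words))
  cat("  top:", paste(x$words[seq_len(n)], collapse = " "), "\n")
  invisible(x)
}

#' Map words to vocabulary indices
#'
#' @param words character vector of words.
#' @param vocab a `bw_vocabulary`.
#' @return integer vector; out-of-vocabulary words map to 0.
#' @export
encode_words <- function(words, vocab) {
  stopifnot(inherits(vocab, "bw_vocabulary"))
  idx <- match(words, vocab$words)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Pad sentinel used for fixed-length encodings
#'
#' Distinct from the OOV index 0: pad positions carry no word at all.  Both
#' embed to the zero vector downstream, but OOV hits are real words and are
#' tracked separately.
#' @export
PAD_INDEX <- -1L

#' Encode a word list to a fixed-length index vector
#'
#' Words are mapped through the vocabulary (OOV -> 0), then the vector is
#' right-padded with the pad sentinel `PAD_INDEX` (-1) to `target_len`, or
#' truncated if longer.
#'
#' @param words character vector of words.
#' @param vocab a `bw_vocabulary`.
#' @param target_len desired encoded length (>= 0).
#' @return integer vector of length `target_len`.
#' @export
encode_and_pad <- function(words, vocab, target_len) {
  stopifnot(target_len >= 0L)
  idx <- encode_words(words, vocab)
  n <- length(idx)
  if (n >= target_len) return(idx[seq_len(target_len)])
  c(idx, rep(PAD_INDEX, target_len - n))
}
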