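# Dataset assembly: length/alphabet filters, class balancing, stratified
# train/test split and k-fold indices.  Label convention: 1 = active (e.g.
# antiviral), 0 = inactive; sensitivity/specificity orientation depends on it.

#' Filter peptides by length and alphabet, removing exact duplicates
#'
#' Keeps records whose sequence length lies in `[min_len, max_len]` and whose
#' residues are all among the 20 proteinogenic amino acids; exact duplicate
#' sequences beyond the first occurrence are dropped.  The operation is total
#' (never errors on records) and idempotent.
#'
#' @param records data.frame with columns `id`, `sequence` (and optionally
#'   `label`).
#' @param min_len,max_len inclusive length bounds; the defaults 5 and 100 are
#'   the usual working range for bioactive peptides.
#' @return list with `kept` (filtered data.frame) and `report`, a named
#'   integer vector counting `rejected_length`, `rejected_alphabet`,
#'   `duplicates_removed`, and `kept`.
#' @examples
#' recs <- data.frame(id = c("a", "b", "c"),
#'                    sequence = c("ACEK", "ACEKLHET", "ACXKL"))
#' filter_peptides(recs)$report
#' @export
filter_peptides <- function(records, min_len = 5L, max_len = 100L) {
  stopifnot(min_len <= max_len)
  len <- nchar(records$sequence)
  bad_len <- len < min_len | len > max_len
  bad_alpha <- !is_valid_peptide(records$sequence)
  keep <- !bad_len & !bad_alpha
  kept <- records[keep, , drop = FALSE]
  dup <- duplicated(kept$sequence)
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(kept = out,
       report = c(rejected_length = sum(bad_len),
                  rejected_alphabet = sum(bad_alpha & !bad_len),
                  duplicates_removed = sum(dup),
                  kept = nrow(out)))
}

#' Assemble a balanced labeled dataset from positive and negative records
#'
#' When the classes are unbalanced, the larger class is uniformly subsampled
#' (without replacement) to the size of the smaller one, reproducibly for a
#' given seed.  Positives get label 1, negatives label 0; output order is
#' positives then negatives.
#'
#' @param pos,neg data.frames with columns `id`, `sequence`.
#' @param seed integer seed controlling the subsample.
#' @return data.frame with columns `id`, `sequence`, `label`.
#' @export
assemble_balanced <- function(pos, neg, seed = 1L) {
  if (nrow(pos) == 0L) stopf("positive class is empty")
  if (nrow(neg) == 0L) stopf("negative class is empty")
  n <- min(nrow(pos), nrow(neg))
  if (nrow(pos) > n)
    pos <- pos[with_rng(seed, "balance-pos", sort(sample.int(nrow(pos), n))), , drop = FALSE]
  if (nrow(neg) > n)
    neg <- neg[with_rng(seed, "balance-neg", sort(sample.int(nrow(neg), n))), , drop = FALSE]
  pos$label <- 1L
  neg$label <- 0L
  out <- rbind(pos[, c("id", "sequence", "label")],
               neg[, c("id", "sequence", "label")])
  if (anyDuplicated(out$id))
    out$id <- make.unique(out$id, sep = "_")
  rownames(out) <- NULL
  out
}

check_labeled <- function(ds) {
  stopifnot(is.data.frame(ds), all(c("id", "sequence", "label") %in% names(ds)))
  if (!all(ds$label %in% c(0L, 1L))) stopf("all labels must be 0 or 1")
  invisible(ds)
}

# stratified assignment of each class's indices to k folds, sizes differing
# by at most one, order randomized by the stream (seed, tag)
strat_folds <- function(labels, k, seed, tag) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stopf("class %s has %d members, fewer than k = %d folds",
                               cl, length(idx), k)
    idx <- with_rng(seed, paste0(tag, "-class", cl), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Reduce sequence redundancy through an external clustering tool
#'
#' Exact-duplicate removal (see [filter_peptides()]) is all this package does
#' natively; identity-threshold redundancy reduction (e.g. clustering at 50%
#' identity) is the job of dedicated external tools.  This hook writes the
#' records to FASTA, substitutes `{input}` and `{output}` into the supplied
#' command template, runs it, and reads back the representative sequences.
#'
#' @param records data.frame with `id`, `sequence` (and optionally `label`).
#' @param command command template containing `{input}` and `{output}`
#'   placeholders, e.g. `"cd-hit -i {input} -o {output} -c 0.5 -n 3"`.
#' @return the records whose ids survive in the tool's output, in original
#'   order.
#' @export
cluster_reduce_hook <- function(records, command) {
  stopifnot(grepl("{input}", command, fixed = TRUE),
            grepl("{output}", command, fixed = TRUE))
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  write_fasta(records, fin)
  cmd <- sub("{input}", fin, command, fixed = TRUE)
  cmd <- sub("{output}", fout, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stopf("clustering command failed (exit %d): %s", status, cmd)
  keep <- read_fasta(fout)$id
  records[records$id %in% keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * class size)` records go to the training
#' set (so realized counts are within one of proportional); the split is a
#' disjoint partition and is deterministic for a given seed.
#'
#' @param ds labeled data.frame (`id`, `sequence`, `label` in \{0,1\}).
#' @param train_fraction fraction of each class assigned to training,
#'   in (0, 1); 0.8 is the customary 80/20 split.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
split_train_test <- function(ds, train_fraction = 0.8, seed = 1L) {
  check_labeled(ds)
  stopifnot(train_fraction > 0, train_fraction < 1)
  take <- logical(nrow(ds))
  for (cl in c(0L, 1L)) {
    idx <- which(ds$label == cl)
    if (length(idx) < 2L) stopf("class %d has fewer than 2 members", cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both parts non-empty
    pick <- with_rng(seed, paste0("split-class", cl), sample(idx, n_tr))
    take[pick] <- TRUE
  }
  list(train = ds[take, , drop = FALSE], test = ds[!take, , drop = FALSE])
}

#' Stratified k-fold cross-validation indices
#'
#' The k validation folds are disjoint, cover every row exactly once, and
#' within each class the fold sizes differ by at most one.
#'
#' @param ds labeled data.frame.
#' @param k number of folds (>= 2); 5 is the standard choice for model
#'   selection.
#' @param seed integer seed.
#' @return list of `k` lists, each with integer vectors `train` and
#'   `validation`.
#' @export
kfold_indices <- function(ds, k = 5L, seed = 1L) {
  check_labeled(ds)
  if (k < 2L) stopf("k must be >= 2")
  fold <- strat_folds(ds$label, k, seed, "kfold")
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), validation = which(fold == f)))
}
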