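# FASTA I/O, dataset filters, balancing, splits and fold indices.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records in order, normalizes case, handles edge cases", {
  f <- write_tmp_fasta(c(">p1 some description", "ACEK", "LHET", ">p2", "acekl"))
  recs <- read_fasta(f)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$sequence, c("ACEKLHET", "ACEKL"))

  empty <- write_tmp_fasta(character(0))
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad <- write_tmp_fasta(c("ACEK", ">p1", "ACDE"))
  expect_error(read_fasta(bad), "line 1")
})

test_that("write_fasta round-trips normalized records at 60-column wrapping", {
  recs <- data.frame(id = c("a", "b"),
                     sequence = c(strrep("ACDEFGHIKL", 9), "MNPQR"),
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("labels can be attached from a two-column TSV", {
  recs <- data.frame(id = c("a", "b"), sequence = c("ACDE", "MNPQR"))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t0"), f)
  out <- read_labels_tsv(recs, f)
  expect_equal(out$label, c(1L, 0L))
})

test_that("filter_peptides applies length and alphabet rules and deduplicates", {
  recs <- data.frame(
    id = sprintf("r%d", 1:6),
    sequence = c("ACEK",                # too short at default min 5
                 strrep("A", 101),      # too long
                 "ACXKL",               # non-natural residue
                 "ACEKLHET", "ACEKLHET",# exact duplicates
                 "MNPQR"),
    stringsAsFactors = FALSE)
  out <- filter_peptides(recs)
  expect_equal(unname(out$report["rejected_length"]), 2L)
  expect_equal(unname(out$report["rejected_alphabet"]), 1L)
  expect_equal(unname(out$report["duplicates_removed"]), 1L)
  expect_equal(out$kept$sequence, c("ACEKLHET", "MNPQR"))

  # idempotent: filtering the filtered set changes nothing
  again <- filter_peptides(out$kept)
  expect_equal(again$kept, out$kept)
  expect_equal(sum(again$report[1:3]), 0L)
})

test_that("the external clustering hook round-trips through a command template", {
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = c("ACEKLHET", "MNPQRST", "ACEKLHET"),
                     stringsAsFactors = FALSE)
  # identity command: every record survives
  out <- cluster_reduce_hook(recs, "cp {input} {output}")
  expect_equal(out$id, recs$id)
  # a command that keeps only the first record (its two FASTA lines)
  out1 <- cluster_reduce_hook(recs, "head -n 2 {input} > {output}")
  expect_equal(out1$id, "a")
  expect_error(cluster_reduce_hook(recs, "false # {input} {output}"),
               "clustering command failed")
  expect_error(cluster_reduce_hook(recs, "cp x y"), "input")
})

test_that("assemble_balanced subsamples the larger class reproducibly", {
  pos <- data.frame(id = sprintf("p%d", 1:10),
                    sequence = replicate(10, random_peptide(10)))
  neg <- data.frame(id = sprintf("n%d", 1:25),
                    sequence = replicate(25, random_peptide(10)))
  ds <- assemble_balanced(pos, neg, seed = 3)
  expect_equal(sum(ds$label == 1), 10L)
  expect_equal(sum(ds$label == 0), 10L)
  expect_identical(ds, assemble_balanced(pos, neg, seed = 3))
  expect_false(identical(ds$id, assemble_balanced(pos, neg, seed = 4)$id))

  # equal classes: everything kept, positives first
  ds2 <- assemble_balanced(pos, neg[1:10, ], seed = 1)
  expect_equal(nrow(ds2), 20L)
  expect_equal(ds2$label, rep(c(1L, 0L), each = 10))

  expect_error(assemble_balanced(pos[0, ], neg), "empty")
})

test_that("split_train_test is stratified, disjoint, exhaustive and seeded", {
  set.seed(42)
  ds <- data.frame(id = sprintf("s%d", 1:200),
                   sequence = replicate(200, random_peptide(12)),
                   label = rep(c(1L, 0L), each = 100))
  sp <- split_train_test(ds, train_fraction = 0.8, seed = 9)
  expect_equal(sum(sp$train$label == 1), 80L)
  expect_equal(sum(sp$train$label == 0), 80L)
  expect_equal(nrow(sp$test), 40L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_setequal(c(sp$train$id, sp$test$id), ds$id)
  sp2 <- split_train_test(ds, train_fraction = 0.8, seed = 9)
  expect_identical(sp$train$id, sp2$train$id)
})

test_that("kfold_indices builds stratified partitions with near-equal folds", {
  set.seed(7)
  ds <- data.frame(id = sprintf("s%d", 1:100),
                   sequence = replicate(100, random_peptide(12)),
                   label = rep(c(1L, 0L), each = 50))
  folds <- kfold_indices(ds, k = 5, seed = 2)
  val <- lapply(folds, `[[`, "validation")
  expect_equal(sort(unlist(val)), 1:100)               # exact cover, disjoint
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_equal(sum(ds$label[f$validation] == 1), 10L)
    expect_equal(sum(ds$label[f$validation] == 0), 10L)
  }
})

test_that("fold sizes differ by at most one per class for awkward sizes", {
  # brute-force enumeration of realized fold sizes, 7+7 samples in 5 folds
  ds <- data.frame(id = sprintf("s%d", 1:14),
                   sequence = replicate(14, random_peptide(8)),
                   label = rep(c(1L, 0L), each = 7))
  for (seed in 1:5) {
    folds <- kfold_indices(ds, k = 5, seed = seed)
    for (cl in c(0L, 1L)) {
      sizes <- vapply(folds, function(f)
        sum(ds$label[f$validation] == cl), integer(1))
      expect_lte(max(sizes) - min(sizes), 1L)
      expect_equal(sum(sizes), 7L)
    }
  }
  expect_error(kfold_indices(ds, k = 9, seed = 1), "fewer than")
})
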