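# Peptide FASTA input/output.  Parsing and writing delegate to Biostrings;
# a pre-scan gives a line-numbered error for sequence data appearing before
# the first header, which is the malformation peptide files show in practice.

#' Read peptides from a FASTA file
#'
#' Multi-line records are concatenated, whitespace stripped, and sequences
#' uppercased.  Record order follows the file.
#'
#' @param path path to a FASTA file.
#' @param label optional binary label (0/1) assigned to every record, e.g.
#'   when positives and negatives live in separate files.
#' @return data.frame with columns `id` (first whitespace-delimited token of
#'   the header), `sequence`, and `label` (NA when unsupplied).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACEK", "LHET", ">p2", "acekl"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*$", lines) & !startsWith(trimws(lines), ">"))
  first_header <- which(startsWith(trimws(lines), ">"))[1]
  if (length(body) > 0 && (is.na(first_header) || body[1] < first_header))
    stopf("malformed FASTA %s: sequence data before first header at line %d",
          path, body[1])
  if (length(lines) == 0 || is.na(first_header))
    return(data.frame(id = character(0), sequence = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(gsub("\\s", "", as.character(ss)))
  data.frame(id = ids, sequence = unname(seqs),
             label = rep(as.integer(label), length(ids)),
             stringsAsFactors = FALSE)
}

#' Write peptides to a FASTA file
#'
#' Sequences are wrapped at 60 columns, with no trailing stop character, so
#' `read_fasta(write_fasta(x, f))` round-trips normalized records.
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Attach labels to records from a two-column TSV
#'
#' @param records data.frame with an `id` column.
#' @param path TSV with columns `id` and `label` (0/1), no header required if
#'   exactly two columns.
#' @return `records` with its `label` column filled by id match.
#' @export
read_labels_tsv <- function(records, path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1, 1])), "id")) tab <- tab[-1, ]
  if (ncol(tab) < 2) stopf("label TSV must have two columns (id, label): %s", path)
  lab <- as.integer(tab[[2]])
  names(lab) <- as.character(tab[[1]])
  if (!all(lab %in% c(0L, 1L))) stopf("labels must be 0/1 in %s", path)
  records$label <- unname(lab[records$id])
  records
}
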