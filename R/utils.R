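# shared internal helpers

# the 20 proteinogenic residues, alphabetical; everything else is "non-natural"
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Check sequences for validity over the 20-letter amino-acid alphabet
#'
#' @param sequences character vector of (uppercase) peptide sequences.
#' @return logical vector, `TRUE` where every residue is one of the 20
#'   proteinogenic amino acids and the sequence is non-empty.
#' @examples
#' is_valid_peptide(c("ACEKLHET", "ACXK", ""))
#' @export
is_valid_peptide <- function(sequences) {
  nzchar(sequences) & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                             sequences)
}

# Deterministic sub-seed for a (seed, purpose-tag) pair.  Each randomized
# operation draws from its own stream so adding a new operation never perturbs
# the draws of an existing one.  Plain 32-bit-safe integer hash.
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(tag)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, tag);
# restores the caller's RNG state afterwards.
with_rng <- function(seed, tag, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(seed, tag))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
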