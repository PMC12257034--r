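# Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom stats runif rnorm setNames uniroot
#' @importFrom utils head tail write.table read.table
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character string (ACGTN)
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# all k-mers of a string, in order; character(0) if too short
kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# random DNA with a target GC fraction
rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# translate an in-frame DNA string to one-letter amino acids ('*' = stop)
translate_dna <- function(x) {
  stopifnot(nchar(x) %% 3L == 0L)
  if (nchar(x) == 0L) return("")
  cods <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  paste(unname(Biostrings::GENETIC_CODE[cods]), collapse = "")
}

codon_to_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  unname(ifelse(is.na(aa), "X", aa))
}

split_codons <- function(x) {
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

is_transition <- function(from, to) {
  purines <- c("A", "G")
  (from %in% purines) == (to %in% purines) & from != to
}

# merge 1-based inclusive intervals; returns matrix with start,end columns
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# deterministic local RNG scope: runs expr under a seed, restores global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
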