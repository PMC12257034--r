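#' Codon usage and RSCU
#'
#' Codon counting over unique coding sequences and relative synonymous
#' codon usage, `RSCU = (n_c / N_aa) * family_size`: the observed count of a
#' codon divided by the count expected if all synonymous codons for that
#' amino acid were used equally. Values above 1 mark preferred codons. Stop
#' codons form their own three-codon family (`Ter`), as organelle codon-bias
#' reports conventionally include them.
#'
#' @name codon_usage
NULL

ALL_CODONS <- sort(names(Biostrings::GENETIC_CODE))

#' Count codons over a set of coding sequences
#'
#' @param cds_set named character vector (or list of [seq_record()]) of
#'   in-frame coding sequences; every length must be divisible by 3.
#' @param include_stop count stop codons too (default TRUE).
#' @param dedup de-duplicate identical sequences before counting ("unique
#'   CDS" rule; gene copies with identical sequence count once).
#' @return list of class `codon_counts`: `counts` (named 64-vector),
#'   `total`, `n_cds`, `include_stop`.
#' @export
count_codons <- function(cds_set, include_stop = TRUE, dedup = TRUE) {
  if (is.list(cds_set)) cds_set <- vapply(as_record_list(cds_set),
                                          function(r) r$seq, "")
  cds_set <- toupper(cds_set)
  if (any(nchar(cds_set) %% 3L != 0L))
    stop("CDS lengths must be divisible by 3")
  if (dedup) cds_set <- cds_set[!duplicated(cds_set)]
  counts <- setNames(integer(length(ALL_CODONS)), ALL_CODONS)
  internal_stop <- character(0)
  for (nm in seq_along(cds_set)) {
    cods <- split_codons(cds_set[[nm]])
    aa <- codon_to_aa(cods)
    if (any(aa[-length(aa)] == "*"))
      internal_stop <- c(internal_stop, names(cds_set)[nm] %||% nm)
    if (!include_stop) cods <- cods[aa != "*"]
    tb <- table(cods)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  if (length(internal_stop))
    warning("internal stop codon(s) before terminus in: ",
            paste(internal_stop, collapse = ", "),
            " (counted as-is; RNA editing may resolve)")
  structure(list(counts = counts, total = sum(counts),
                 n_cds = length(cds_set), include_stop = include_stop),
            class = "codon_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative synonymous codon usage
#'
#' @param counts a [count_codons()] result (or named codon-count vector).
#' @return data.frame with `codon`, `aa` (`*` = stop), `family_size`,
#'   `count`, `rscu`. Families with zero usage have `rscu = NA` (undefined,
#'   not zero).
#' @export
compute_rscu <- function(counts) {
  if (is(counts, "codon_counts")) counts <- counts$counts
  stopifnot(all(ALL_CODONS %in% names(counts)))
  aa <- unname(Biostrings::GENETIC_CODE[ALL_CODONS])
  fam_size <- as.integer(table(aa)[aa])
  fam_tot <- tapply(counts[ALL_CODONS], aa, sum)[aa]
  rscu <- ifelse(fam_tot > 0,
                 (counts[ALL_CODONS] / fam_tot) * fam_size, NA_real_)
  data.frame(codon = ALL_CODONS, aa = aa, family_size = fam_size,
             count = as.integer(counts[ALL_CODONS]),
             rscu = unname(rscu), stringsAsFactors = FALSE)
}

#' Codon-usage bias summary
#'
#' Counts codons with RSCU above 1, partitioned by third-position base
#' (A/U pooled, G, C), and ranks amino-acid usage.
#'
#' @param entries a [compute_rscu()] table.
#' @return list: `n_over_1`, `third_base` (data.frame with counts and
#'   percentages of the RSCU>1 codons, 0 d.p. on the A/U share), `aa_usage`
#'   (per-amino-acid counts and percentage of all codons, most frequent
#'   first).
#' @export
rscu_bias_summary <- function(entries) {
  over <- entries[!is.na(entries$rscu) & entries$rscu > 1, , drop = FALSE]
  third <- substr(over$codon, 3L, 3L)
  grp <- ifelse(third %in% c("A", "T"), "A/U", third)
  n <- nrow(over)
  tb <- vapply(c("A/U", "G", "C"), function(g) sum(grp == g), 0L)
  third_base <- data.frame(ending = names(tb), count = as.integer(tb),
                           pct = if (n > 0) round(100 * tb / n, 0)
                                 else NA_real_)
  aa_tot <- tapply(entries$count, entries$aa, sum)
  aa_tot <- sort(aa_tot, decreasing = TRUE)
  total <- sum(entries$count)
  aa_usage <- data.frame(aa = names(aa_tot), count = as.integer(aa_tot),
                         pct = round(100 * as.integer(aa_tot) / total, 2))
  list(n_over_1 = n, third_base = third_base, aa_usage = aa_usage,
       total_codons = total)
}

#' Start / stop codon check
#'
#' Reports the first and last codon of every CDS and flags non-ATG starts.
#' An `ACG` start is specifically marked as a candidate editing-created
#' start (C-to-U editing of ACG yields ATG on the transcript).
#'
#' @param cds_set named character vector of in-frame coding sequences.
#' @return data.frame: `gene`, `start_codon`, `stop_codon`,
#'   `canonical_start`, `editing_candidate_start`, `valid_stop`.
#' @export
check_start_stop <- function(cds_set) {
  if (is.list(cds_set)) cds_set <- vapply(as_record_list(cds_set),
                                          function(r) r$seq, "")
  stopifnot(all(nchar(cds_set) %% 3L == 0L), all(nchar(cds_set) >= 6L))
  genes <- names(cds_set) %||% paste0("cds", seq_along(cds_set))
  first <- substr(cds_set, 1L, 3L)
  last <- substring(cds_set, nchar(cds_set) - 2L)
  data.frame(gene = genes, start_codon = first, stop_codon = last,
             canonical_start = first == "ATG",
             editing_candidate_start = first == "ACG",
             valid_stop = last %in% c("TAA", "TAG", "TGA"),
             stringsAsFactors = FALSE, row.names = NULL)
}
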