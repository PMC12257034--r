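#' Mitochondrion-plastid homologous fragments (MTPT detection)
#'
#' Plastid-derived tracts in plant mitogenomes are detected as local
#' alignments between the two organelle genomes with E-value at most 1e-5
#' and identity at least 70% — the conventional thresholds for
#' mitochondrial plastid DNA surveys. Fragments are reported BLAST-style
#' (identity %, aligned length, mismatches, gap opens, query = plastid
#' span, subject = mitochondrial span) and can be annotated with the genes
#' they overlap on either genome.
#'
#' @name organelle_transfer
NULL

#' Find homologous fragments between plastid and mitochondrial genomes
#'
#' @param cp plastid [seq_record()] (query side).
#' @param mt mitochondrial [seq_record()] (subject side).
#' @param evalue E-value ceiling (default 1e-5).
#' @param min_identity identity floor in percent (default 70).
#' @param k seed word size.
#' @return data.frame of class `homolog_fragments`: `identity` (%),
#'   `length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (subject span reversed when the hit is on the minus strand),
#'   `strand`, `evalue`, sorted by length descending.
#' @export
find_homologous_fragments <- function(cp, mt, evalue = 1e-5,
                                      min_identity = 70, k = 11L) {
  stopifnot(seq_len_bp(cp) > 0L, seq_len_bp(mt) > 0L)
  idx <- build_index(mt, k = k)
  hits <- local_align(cp$seq, idx, min_score = 25, min_seeds = 2L,
                      max_extend = 300L, query_id = cp$id)
  keep <- hits$evalue <= evalue & hits$identity * 100 >= min_identity
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(
    identity = round(100 * hits$identity, 3),
    length = hits$aligned_length,
    mismatches = hits$mismatches, gap_opens = hits$gap_opens,
    q_start = hits$q_start, q_end = hits$q_end,
    s_start = ifelse(hits$strand == "-", hits$t_end, hits$t_start),
    s_end = ifelse(hits$strand == "-", hits$t_start, hits$t_end),
    strand = hits$strand, evalue = hits$evalue,
    stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homolog_fragments", "data.frame")
  out
}

#' Assign overlapping genes to homologous fragments
#'
#' Any annotation overlapping a fragment span by at least 1 bp is listed
#' (partial-gene overlaps count).
#'
#' @param fragments a [find_homologous_fragments()] table.
#' @param cp_annotations,mt_annotations [gene_annotation()] tables for the
#'   plastid (query) and mitochondrial (subject) genomes; either may be
#'   NULL.
#' @return the fragments table with `genes_cp` and `genes_mt` columns
#'   (semicolon-joined, empty when none).
#' @export
assign_genes_to_fragments <- function(fragments, cp_annotations = NULL,
                                      mt_annotations = NULL) {
  overlap_genes <- function(s, e, ann) {
    if (is.null(ann) || !nrow(ann)) return("")
    lo <- pmin(s, e); hi <- pmax(s, e)
    hit <- spans_overlap(lo, hi, ann$start, ann$end)
    paste(unique(ann$gene_id[hit]), collapse = ";")
  }
  fragments$genes_cp <- vapply(seq_len(nrow(fragments)), function(i)
    overlap_genes(fragments$q_start[i], fragments$q_end[i], cp_annotations),
    "")
  fragments$genes_mt <- vapply(seq_len(nrow(fragments)), function(i)
    overlap_genes(fragments$s_start[i], fragments$s_end[i], mt_annotations),
    "")
  fragments
}

#' Summarise homologous fragments
#'
#' @param fragments a fragments table; any data.frame with a `length`
#'   column (and optionally span columns) is accepted, so published
#'   fragment tabulations can be summarised directly.
#' @param cp_length,mt_length optional genome sizes for merged-coverage
#'   fractions.
#' @return list: `count`, `total_bp`, `longest`, `shortest`,
#'   `cp_fraction`, `mt_fraction` (NA without genome sizes/spans), `empty`.
#' @export
fragment_summary <- function(fragments, cp_length = NULL, mt_length = NULL) {
  if (is.null(fragments) || !nrow(fragments))
    return(list(count = 0L, total_bp = 0L, longest = 0L, shortest = 0L,
                cp_fraction = NA_real_, mt_fraction = NA_real_,
                empty = TRUE))
  cov <- function(s, e, L) {
    if (is.null(L) || is.null(s)) return(NA_real_)
    m <- merge_intervals(as.integer(pmin(s, e)), as.integer(pmax(s, e)))
    sum(m[, "end"] - m[, "start"] + 1L) / L
  }
  list(count = nrow(fragments),
       total_bp = sum(fragments$length),
       longest = max(fragments$length),
       shortest = min(fragments$length),
       cp_fraction = cov(fragments$q_start, fragments$q_end, cp_length),
       mt_fraction = cov(fragments$s_start, fragments$s_end, mt_length),
       empty = FALSE)
}

#' All local matches between two genomes (dot-plot export)
#'
#' @param genome_a,genome_b [seq_record()] objects; passing the same
#'   sequence yields the self-comparison (the full-length main diagonal is
#'   reported).
#' @param min_len minimum match length.
#' @param k seed word size.
#' @return data.frame: `a_start`, `a_end`, `b_start`, `b_end`, `strand`,
#'   `identity` — rows suitable for dot-plot rendering.
#' @export
cross_genome_matches <- function(genome_a, genome_b, min_len = 100L,
                                 k = 11L) {
  stopifnot(seq_len_bp(genome_a) > 0L, seq_len_bp(genome_b) > 0L)
  idx <- build_index(genome_b, k = k)
  hits <- local_align(genome_a$seq, idx, min_score = 25, min_seeds = 2L,
                      max_extend = 300L, query_id = genome_a$id)
  hits <- hits[hits$aligned_length >= min_len, , drop = FALSE]
  out <- data.frame(a_start = hits$q_start, a_end = hits$q_end,
                    b_start = hits$t_start, b_end = hits$t_end,
                    strand = hits$strand, identity = hits$identity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
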