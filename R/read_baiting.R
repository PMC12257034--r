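#' Iterative mitochondrial read baiting
#'
#' Mimics the organelle read-extraction strategy used upstream of plant
#' mitogenome assembly: long reads are first screened against a set of
#' conserved core genes (alignment length strictly greater than 50 bp makes
#' a candidate), the best candidates become seeds, and the pool is then
#' recruited iteratively — any unrecruited read overlapping the recruited
#' set by more than `min_overlap` (default 1 kb) at identity at least 0.85
#' is added, until a fixed point.
#'
#' @name read_baiting
NULL

#' Select seed reads by core-gene content
#'
#' Candidates are reads with at least one core-gene alignment longer than
#' `min_hit` bp (strict). Candidates are ranked by number of distinct core
#' genes hit, then by summed per-gene coverage; reads hitting at least two
#' distinct genes are all seeds, otherwise the top `top_fraction` by
#' coverage are taken.
#'
#' @param reads named character vector of read sequences.
#' @param core_genes named character vector (or list of [seq_record()]) of
#'   core gene sequences.
#' @param min_hit minimum alignment length, exclusive (default 50).
#' @param top_fraction fallback fraction of candidates kept as seeds.
#' @return list of class `seed_set`: `seeds` (read ids), `candidates`
#'   (read_id, n_genes, coverage), `gene_coverage` (per-gene fraction of
#'   positions covered by seed reads), `iteration = 0`.
#' @export
select_seed_reads <- function(reads, core_genes, min_hit = 50L,
                              top_fraction = 0.2) {
  genes <- as_record_list(core_genes)
  stopifnot(length(genes) > 0L, !is.null(names(reads)))
  idx <- build_index(genes, k = 11L)
  gene_len <- vapply(genes, seq_len_bp, 0L)
  cand <- list()
  cov_spans <- list()
  for (i in seq_along(reads)) {
    h <- local_align(reads[[i]], idx, min_score = 30,
                     query_id = names(reads)[i], max_clusters = 10L)
    if (!nrow(h)) next
    h <- h[h$aligned_length > min_hit, , drop = FALSE]
    if (!nrow(h)) next
    per_gene <- tapply(h$aligned_length, h$target_id, max)
    coverage <- sum(pmin(per_gene / gene_len[names(per_gene)], 1))
    cand[[length(cand) + 1L]] <- data.frame(
      read_id = names(reads)[i], n_genes = length(per_gene),
      coverage = coverage, stringsAsFactors = FALSE)
    cov_spans[[names(reads)[i]]] <- h[, c("target_id", "t_start", "t_end")]
  }
  if (!length(cand)) {
    warning("no candidate reads hit any core gene")
    return(structure(list(seeds = character(0),
                          candidates = data.frame(read_id = character(0),
                                                  n_genes = integer(0),
                                                  coverage = numeric(0)),
                          gene_coverage = setNames(numeric(length(genes)),
                                                   names(genes)),
                          iteration = 0L),
                     class = "seed_set"))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$n_genes, -cand$coverage), , drop = FALSE]
  multi <- cand$read_id[cand$n_genes >= 2L]
  seeds <- if (length(multi)) multi
           else head(cand$read_id, max(1L, ceiling(top_fraction * nrow(cand))))
  spans <- do.call(rbind, cov_spans[seeds])
  gene_cov <- vapply(names(genes), function(g) {
    sp <- spans[spans$target_id == g, , drop = FALSE]
    if (!nrow(sp)) return(0)
    m <- merge_intervals(sp$t_start, sp$t_end)
    sum(m[, "end"] - m[, "start"] + 1L) / gene_len[g]
  }, 0)
  structure(list(seeds = seeds, candidates = cand,
                 gene_coverage = gene_cov, iteration = 0L),
            class = "seed_set")
}

#' Recruit reads iteratively by overlap with the recruited set
#'
#' @param reads named character vector of all reads.
#' @param seeds a `seed_set` (or character vector of seed read ids).
#' @param min_overlap overlap length threshold, exclusive (default 1000 bp).
#' @param min_identity identity floor on the overlap alignment (0.85;
#'   prevents low-complexity chaining).
#' @param max_iter iteration cap (default 20).
#' @return list of class `baiting_result`: `recruited` (ids, seeds
#'   included), `iterations`, `per_iteration` (new recruits per round),
#'   `converged`.
#' @export
recruit_reads_iterative <- function(reads, seeds, min_overlap = 1000L,
                                    min_identity = 0.85, max_iter = 20L) {
  seed_ids <- if (is(seeds, "seed_set")) seeds$seeds else seeds
  stopifnot(length(seed_ids) > 0L, all(seed_ids %in% names(reads)))
  recruited <- seed_ids
  per_iter <- integer(0)
  converged <- FALSE
  min_score_floor <- floor(min_overlap * (min_identity - 2 * (1 - min_identity)))
  for (it in seq_len(max_iter)) {
    pool <- setdiff(names(reads), recruited)
    if (!length(pool)) { converged <- TRUE; break }
    idx <- build_index(reads[recruited], k = 11L)
    new_ids <- character(0)
    for (rid in pool) {
      # a qualifying overlap (>1 kb at >=0.85 identity) always produces a
      # dense seed chain; requiring many seeds per cluster skips spurious
      # extensions of contaminant reads entirely
      h <- local_align(reads[[rid]], idx, min_score = min_score_floor,
                       query_id = rid, max_clusters = 4L, max_targets = 4L,
                       min_seeds = 20L, max_extend = 200L)
      if (!nrow(h)) next
      ok <- h$aligned_length > min_overlap & h$identity >= min_identity
      if (any(ok)) new_ids <- c(new_ids, rid)
    }
    per_iter <- c(per_iter, length(new_ids))
    if (!length(new_ids)) { converged <- TRUE; break }
    recruited <- c(recruited, new_ids)
  }
  if (!converged && length(per_iter) == max_iter)
    warning("max_iter reached without convergence; partial result returned")
  structure(list(recruited = recruited, iterations = length(per_iter),
                 per_iteration = per_iter, converged = converged),
            class = "baiting_result")
}
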