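#' Shared seed-and-extend local aligner
#'
#' All alignment-driven stages (read baiting, annotation transfer, the
#' RNA-editing pileup, dispersed repeats and plastid-transfer detection) run
#' on one engine: an exact k-mer index over the target set, diagonal seed
#' chaining, and gapped extension of each seed cluster with a C-backed
#' Smith-Waterman (`Biostrings::pairwiseAlignment`) restricted to the
#' seed-bounded window. Default scoring: match +1, mismatch -2, gap open -5
#' (first gapped base included), gap extend -2.
#'
#' E-values use Karlin-Altschul statistics `E = K * m * n * exp(-lambda * S)`
#' with `lambda = 1.28`, `K = 0.46` for the +1/-2 scheme.
#'
#' @name alignment_core
NULL

KA_LAMBDA <- 1.28
KA_K <- 0.46

#' Build an exact k-mer index over one or more target sequences
#'
#' @param targets a [seq_record()], list of them, or named character vector.
#' @param k word size, 7..21.
#' @param occ_cap k-mers occurring more than this many times across the
#'   target set are masked (repeat shielding).
#' @return an opaque index object consumed by [local_align()].
#' @export
build_index <- function(targets, k = 11L, occ_cap = 200L) {
  recs <- as_record_list(targets)
  k <- as.integer(k)
  if (k < 7L || k > 21L) stop("k must be in 7..21")
  lens <- vapply(recs, seq_len_bp, 0L)
  if (all(lens < k)) stop("k larger than every target sequence")
  km <- character(0); tid <- character(0); pos <- integer(0)
  for (r in recs) {
    kk <- kmers(r$seq, k)
    if (!length(kk)) next
    km <- c(km, kk)
    tid <- c(tid, rep(r$id, length(kk)))
    pos <- c(pos, seq_along(kk))
  }
  drop <- grepl("N", km, fixed = TRUE)
  if (any(drop)) { km <- km[!drop]; tid <- tid[!drop]; pos <- pos[!drop] }
  dt <- data.table::data.table(kmer = km, tid = tid, pos = pos)
  cnt <- dt[, list(n = .N), by = "kmer"]
  masked_kmers <- cnt$kmer[cnt$n > occ_cap]
  if (length(masked_kmers))
    dt <- dt[!dt$kmer %in% masked_kmers, ]
  data.table::setkey(dt, kmer)
  structure(list(k = k, occ_cap = occ_cap, dt = dt,
                 masked_kmers = masked_kmers,
                 seqs = vapply(recs, function(r) r$seq, ""),
                 total_bp = sum(lens)),
            class = "kmer_index")
}

#' Look up the target positions of one k-mer
#'
#' @param index a [build_index()] object.
#' @param kmer character scalar of length `k`.
#' @return data.frame with `target_id`, `pos` (empty when absent or masked).
#' @export
index_lookup <- function(index, kmer) {
  .query_kmer <- kmer
  m <- index$dt[list(.query_kmer), nomatch = NULL, allow.cartesian = TRUE]
  data.frame(target_id = m$tid, pos = m$pos, stringsAsFactors = FALSE)
}

empty_hits <- function(traceback = FALSE) {
  df <- data.frame(query_id = character(0), target_id = character(0),
                   q_start = integer(0), q_end = integer(0),
                   t_start = integer(0), t_end = integer(0),
                   strand = character(0), aligned_length = integer(0),
                   matches = integer(0), mismatches = integer(0),
                   gap_opens = integer(0), identity = numeric(0),
                   score = numeric(0), evalue = numeric(0),
                   stringsAsFactors = FALSE)
  if (traceback) { df$q_aln <- character(0); df$t_aln <- character(0) }
  df
}

# gapless X-drop extension along one diagonal, anchored on a seed run;
# used when the DP window would be too large (e.g. whole-genome diagonals)
xdrop_extend <- function(qs, tseq, qlo, tlo, core_len, match, mismatch,
                         xdrop = 20) {
  qch <- strsplit(qs, "", fixed = TRUE)[[1]]
  tch <- strsplit(tseq, "", fixed = TRUE)[[1]]
  qn <- length(qch); tn <- length(tch)
  # extend right from the end of the core
  qi <- qlo + core_len - 1L; ti <- tlo + core_len - 1L
  best_r <- c(qi, ti); cur <- 0; best <- 0
  while (qi < qn && ti < tn) {
    qi <- qi + 1L; ti <- ti + 1L
    cur <- cur + if (qch[qi] == tch[ti]) match else mismatch
    if (cur > best) { best <- cur; best_r <- c(qi, ti) }
    if (cur < best - xdrop) break
  }
  gain_r <- best
  # extend left from the start of the core
  qi <- qlo; ti <- tlo
  best_l <- c(qi, ti); cur <- 0; best <- 0
  while (qi > 1L && ti > 1L) {
    qi <- qi - 1L; ti <- ti - 1L
    cur <- cur + if (qch[qi] == tch[ti]) match else mismatch
    if (cur > best) { best <- cur; best_l <- c(qi, ti) }
    if (cur < best - xdrop) break
  }
  gain_l <- best
  qs1 <- best_l[1]; ts1 <- best_l[2]
  qe1 <- best_r[1]; te1 <- best_r[2]
  p_aln <- substr(qs, qs1, qe1)
  s_aln <- paste(tch[ts1:te1], collapse = "")
  pc <- strsplit(p_aln, "")[[1]]; sc2 <- tch[ts1:te1]
  matches <- sum(pc == sc2)
  mism <- sum(pc != sc2)
  list(score = matches * match + mism * mismatch,
       matches = matches, mism = mism, gap_opens = 0L,
       alen = qe1 - qs1 + 1L, qs1 = qs1, qe1 = qe1, ts1 = ts1, te1 = te1,
       p_aln = p_aln, s_aln = s_aln)
}

sub_matrix <- function(match = 1, mismatch = -2) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  m
}

#' Local alignment of a query against an indexed target set
#'
#' Seeds are exact k-mer matches; seeds on nearby diagonals are chained into
#' clusters, and each cluster is extended by gapped local alignment of the
#' query against the seed-bounded target window (padded by `band`).
#' Both strands of the query are searched. Equal-score ties are broken by
#' leftmost target start, then leftmost query start.
#'
#' @param query character scalar (or [seq_record()]).
#' @param index index from [build_index()].
#' @param min_score minimum alignment score to report.
#' @param band diagonal tolerance when chaining seeds, and window padding.
#' @param min_seeds minimum seeds per cluster before extension is attempted
#'   (raise to 2+ to suppress spurious single-word extensions in
#'   genome-scale self-comparison).
#' @param min_diag_seeds minimum seeds on the cluster's dominant diagonal
#'   before extension; any real local similarity places consecutive exact
#'   words on one diagonal, so raising this prunes chance seed clusters at
#'   small word sizes without losing true hits.
#' @param chain_gap maximum query-position gap between chained seeds.
#' @param traceback keep per-base aligned strings (`q_aln`, `t_aln`) on each
#'   hit; required by [pileup()].
#' @param query_id id recorded on the hits.
#' @param exclude_self drop seeds that map a position onto itself
#'   (self-comparison mode; query must be one of the indexed targets).
#' @param max_extend cap, in bp, on how far the alignment window may extend
#'   beyond the seed-covered region on either side (default unlimited, i.e.
#'   the full query is alignable). Set small for genome self-comparison so
#'   distinct repeat copies cannot collapse onto the trivial diagonal.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param max_clusters extend at most this many clusters (largest first).
#' @param max_targets consider only this many targets (those with most
#'   seeds) before clustering; useful when any qualifying hit suffices,
#'   e.g. overlap-based read recruitment.
#' @return data.frame of hits (class `alignment_hits`), sorted by score.
#' @export
local_align <- function(query, index, min_score = 30, band = 50L,
                        min_seeds = 1L, min_diag_seeds = 1L,
                        chain_gap = 500L,
                        traceback = FALSE, query_id = "query",
                        exclude_self = FALSE, max_extend = Inf,
                        match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2,
                        max_clusters = Inf, max_targets = Inf) {
  if (is(query, "seq_record")) { query_id <- query$id; query <- query$seq }
  stopifnot(is(index, "kmer_index"))
  k <- index$k
  qlen <- nchar(query)
  submat <- sub_matrix(match, mismatch)
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qk <- kmers(qs, k)
    if (!length(qk)) next
    qdt <- data.table::data.table(kmer = qk, qpos = seq_along(qk))
    m <- index$dt[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(m)) next
    qpos <- m$qpos
    tids <- m$tid
    tpos <- m$pos
    if (exclude_self && strand == "+") {
      selfh <- tids == query_id & tpos == qpos
      qpos <- qpos[!selfh]; tids <- tids[!selfh]; tpos <- tpos[!selfh]
    }
    if (!length(qpos)) next
    tg_set <- unique(tids)
    if (is.finite(max_targets) && length(tg_set) > max_targets) {
      tt <- sort(table(tids), decreasing = TRUE)
      tg_set <- names(tt)[seq_len(max_targets)]
      keep <- tids %in% tg_set
      qpos <- qpos[keep]; tpos <- tpos[keep]; tids <- tids[keep]
    }
    clusters <- list()
    for (tg in tg_set) {
      w <- tids == tg
      qp <- qpos[w]; tp <- tpos[w]
      dg <- tp - qp
      o <- order(dg, qp)
      qp <- qp[o]; tp <- tp[o]; dg <- dg[o]
      brk <- c(TRUE, diff(dg) > band | abs(diff(qp)) > chain_gap)
      grp <- cumsum(brk)
      for (g in unique(grp)) {
        gi <- which(grp == g)
        if (length(gi) < min_seeds) next
        clusters[[length(clusters) + 1L]] <-
          list(tg = tg, qp = qp[gi], tp = tp[gi], dg = dg[gi])
      }
    }
    if (!length(clusters)) next
    clusters <- clusters[order(-vapply(clusters, function(cl)
      length(cl$qp), 0L))]
    n_done <- 0L
    for (cl in clusters) {
      if (n_done >= max_clusters) break
      n_done <- n_done + 1L
      tg <- cl$tg
      tseq <- index$seqs[[tg]]
      tlen <- nchar(tseq)
      qlo <- min(cl$qp); qhi <- max(cl$qp) + k - 1L
      tlo <- min(cl$tp); thi <- max(cl$tp) + k - 1L
      one_diag <- all(cl$dg == cl$dg[1])
      dg_tab <- table(cl$dg)
      if (max(dg_tab) < min_diag_seeds) next
      # fast path: a contiguous seed run on the dominant diagonal is an
      # exact match; taken when it explains (nearly) the whole cluster
      dd <- as.integer(names(which.max(dg_tab)))
      qps <- sort(cl$qp[cl$dg == dd])
      run_brk <- c(0L, cumsum(diff(qps) != 1L))
      run_len <- max(tabulate(run_brk + 1L))
      ri <- which(run_brk == (which.max(tabulate(run_brk + 1L)) - 1L))
      seg_q1 <- qps[ri[1]]; seg_q2 <- qps[ri[length(ri)]] + k - 1L
      seg_len <- seg_q2 - seg_q1 + 1L
      exact_run <- seg_len * match >= min_score &&
        seg_len >= 0.9 * (qhi - qlo + 1L)
      ares <- NULL
      if (exact_run) {
        ares <- list(score = seg_len * match, matches = seg_len, mism = 0L,
                     gap_opens = 0L, alen = seg_len,
                     qs1 = seg_q1, qe1 = seg_q2,
                     ts1 = seg_q1 + dd, te1 = seg_q2 + dd,
                     p_aln = substr(qs, seg_q1, seg_q2),
                     s_aln = substr(tseq, seg_q1 + dd, seg_q2 + dd))
      } else {
        ext_l <- min(qlo - 1L, max_extend)
        ext_r <- min(qlen - qhi, max_extend)
        qwlo <- qlo - ext_l; qwhi <- qhi + ext_r
        wlo <- max(1L, tlo - ext_l - band)
        whi <- min(tlen, thi + ext_r + band)
        area <- as.numeric(qwhi - qwlo + 1L) * (whi - wlo + 1L)
        if (area <= 2.5e7) {
          qwin <- substr(qs, qwlo, qwhi)
          win <- substr(tseq, wlo, whi)
          pa <- Biostrings::pairwiseAlignment(
            pattern = qwin, subject = win, type = "local",
            substitutionMatrix = submat,
            gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
          sc <- Biostrings::score(pa)
          if (sc >= min_score) {
            p_aln <- as.character(Biostrings::alignedPattern(pa))
            s_aln <- as.character(Biostrings::alignedSubject(pa))
            pc <- strsplit(p_aln, "")[[1]]
            scc <- strsplit(s_aln, "")[[1]]
            nongap <- pc != "-" & scc != "-"
            ares <- list(
              score = sc, matches = sum(nongap & pc == scc),
              mism = sum(nongap & pc != scc),
              gap_opens = sum(diff(c(FALSE, pc == "-")) == 1L) +
                sum(diff(c(FALSE, scc == "-")) == 1L),
              alen = length(pc),
              qs1 = qwlo + Biostrings::start(Biostrings::pattern(pa)) - 1L,
              qe1 = qwlo + Biostrings::end(Biostrings::pattern(pa)) - 1L,
              ts1 = wlo + Biostrings::start(Biostrings::subject(pa)) - 1L,
              te1 = wlo + Biostrings::end(Biostrings::subject(pa)) - 1L,
              p_aln = p_aln, s_aln = s_aln)
          }
        } else if (one_diag) {
          # window too large for DP: gapless X-drop extension on the diagonal
          ares <- xdrop_extend(qs, tseq, qlo, tlo,
                               qhi - qlo + 1L, match, mismatch)
        }
      }
      if (is.null(ares) || ares$score < min_score) next
      if (strand == "-") {
        q_start <- qlen - ares$qe1 + 1L; q_end <- qlen - ares$qs1 + 1L
      } else {
        q_start <- ares$qs1; q_end <- ares$qe1
      }
      row <- data.frame(query_id = query_id, target_id = tg,
                        q_start = q_start, q_end = q_end,
                        t_start = ares$ts1, t_end = ares$te1,
                        strand = strand,
                        aligned_length = ares$alen, matches = ares$matches,
                        mismatches = ares$mism, gap_opens = ares$gap_opens,
                        identity = ares$matches / ares$alen,
                        score = ares$score,
                        evalue = KA_K * qlen * index$total_bp *
                          exp(-KA_LAMBDA * ares$score),
                        stringsAsFactors = FALSE)
      if (traceback) { row$q_aln <- ares$p_aln; row$t_aln <- ares$s_aln }
      hits[[length(hits) + 1L]] <- row
    }
  }
  if (!length(hits)) return(empty_hits(traceback))
  res <- do.call(rbind, hits)
  res <- res[!duplicated(res[, c("target_id", "t_start", "t_end",
                                 "q_start", "q_end", "strand")]), ,
             drop = FALSE]
  res <- res[order(-res$score, res$t_start, res$q_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("alignment_hits", "data.frame")
  res
}

#' Pile up base-level alignments onto their targets
#'
#' Requires hits carrying tracebacks (`local_align(..., traceback = TRUE)`).
#' One column is produced per covered target position, with counts of
#' A/C/G/T and deletions observed across all covering alignments.
#'
#' @param hits an `alignment_hits` data.frame with `q_aln`/`t_aln`.
#' @param targets the aligned target set (list of [seq_record()] or named
#'   character vector) supplying reference bases.
#' @return data.frame: `target_id`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `del`, `depth`.
#' @export
pileup <- function(hits, targets) {
  recs <- as_record_list(targets)
  if (is.null(hits$q_aln)) stop("hits carry no traceback; rerun local_align(traceback = TRUE)")
  if (!nrow(hits))
    return(data.frame(target_id = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), del = integer(0),
                      depth = integer(0)))
  tid_all <- character(0); pos_all <- integer(0); base_all <- character(0)
  for (i in seq_len(nrow(hits))) {
    qc <- strsplit(hits$q_aln[i], "")[[1]]
    tc <- strsplit(hits$t_aln[i], "")[[1]]
    tgap <- tc == "-"
    tposs <- hits$t_start[i] + cumsum(!tgap) - 1L
    keep <- !tgap
    obs <- ifelse(qc[keep] == "-", "del", qc[keep])
    tid_all <- c(tid_all, rep(hits$target_id[i], sum(keep)))
    pos_all <- c(pos_all, tposs[keep])
    base_all <- c(base_all, obs)
  }
  key <- paste(tid_all, pos_all, sep = "\r")
  tab <- table(key, factor(base_all, levels = c("A", "C", "G", "T", "del")))
  ks <- rownames(tab)
  parts <- strsplit(ks, "\r", fixed = TRUE)
  tid <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  ref <- vapply(seq_along(tid), function(i)
    substr(recs[[tid[i]]]$seq, pos[i], pos[i]), "")
  out <- data.frame(target_id = tid, pos = pos, ref = ref,
                    A = as.integer(tab[, "A"]), C = as.integer(tab[, "C"]),
                    G = as.integer(tab[, "G"]), T = as.integer(tab[, "T"]),
                    del = as.integer(tab[, "del"]),
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out <- out[order(out$target_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export hits as a BLAST outfmt-6 style table
#'
#' @param hits an `alignment_hits` data.frame.
#' @param path optional TSV destination.
#' @return the reformatted data.frame (invisibly when written to file).
#' @export
hits_to_outfmt6 <- function(hits, path = NULL) {
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$target_id,
                   pident = round(100 * hits$identity, 3),
                   length = hits$aligned_length,
                   mismatch = hits$mismatches, gapopen = hits$gap_opens,
                   qstart = hits$q_start, qend = hits$q_end,
                   sstart = ifelse(hits$strand == "-", hits$t_end, hits$t_start),
                   send = ifelse(hits$strand == "-", hits$t_start, hits$t_end),
                   evalue = signif(hits$evalue, 3), bitscore = hits$score)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
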