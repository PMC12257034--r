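#' Sequence records and standard-format IO
#'
#' A `seq_record` is a lightweight container for one named nucleotide
#' sequence: an id, an uppercase DNA string over `A,C,G,T,N`, and a
#' circularity flag. Plant mitogenomes are typically circular molecules, and
#' several operations (CDS extraction, read simulation) honour wrap-around
#' coordinates when `circular = TRUE`.
#'
#' @param id character scalar, sequence name.
#' @param seq character scalar, DNA sequence. Lowercase is uppercased on
#'   construction; characters outside `A,C,G,T,N` are rejected unless
#'   `mask_invalid = TRUE`, in which case they become `N`.
#' @param circular logical, is the molecule circular?
#' @param mask_invalid replace non-ACGTN characters with `N` instead of
#'   raising an error.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, seq, circular = FALSE, mask_invalid = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    if (mask_invalid) {
      seq <- gsub("[^ACGTN]", "N", seq)
    } else {
      stop("invalid characters in sequence '", id, "': ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    }
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

seq_len_bp <- function(rec) nchar(rec$seq)

#' Read a FASTA file into a list of sequence records
#'
#' @param path FASTA file.
#' @param circular logical flag applied to all records (FASTA itself does not
#'   carry topology).
#' @return list of [seq_record()] objects, named by id.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i)
    seq_record(ids[i], as.character(ss[[i]]), circular = circular))
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param recs a `seq_record`, a list of them, or a named character vector.
#' @param path output file.
#' @export
write_fasta <- function(recs, path) {
  recs <- as_record_list(recs)
  ss <- Biostrings::DNAStringSet(vapply(recs, function(r) r$seq, ""))
  names(ss) <- vapply(recs, function(r) r$id, "")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

as_record_list <- function(x, circular = FALSE) {
  if (is(x, "seq_record")) return(setNames(list(x), x$id))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(setNames(
      lapply(seq_along(x), function(i) seq_record(ids[i], x[[i]], circular)),
      ids))
  }
  stopifnot(is.list(x), all(vapply(x, is, TRUE, "seq_record")))
  setNames(x, vapply(x, function(r) r$id, ""))
}

#' Read / write FASTQ
#'
#' Minimal FASTQ support for the simulated read sets: qualities are carried
#' as-is on read and written as constant `I` (Q40) on write when absent.
#'
#' @param path FASTQ file.
#' @return `read_fastq`: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @param reads named character vector of read sequences.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  ss <- Biostrings::DNAStringSet(unname(reads))
  names(ss) <- names(reads)
  qual <- Biostrings::BStringSet(vapply(width(ss), function(w)
    paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @importFrom BiocGenerics width
NULL

#' Base composition of a sequence record
#'
#' Exact integer counts of A/C/G/T (and N), base fractions over non-N bases,
#' and the GC fraction `(G+C)/(A+C+G+T)`.
#'
#' @param rec a [seq_record()].
#' @return list with `counts`, `fractions`, `gc`, `length`.
#' @export
base_composition <- function(rec) {
  stopifnot(is(rec, "seq_record"), nchar(rec$seq) > 0L)
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  counts <- vapply(c(DNA_BASES, "N"), function(b) sum(ch == b), 0L)
  acgt <- sum(counts[DNA_BASES])
  if (acgt == 0L) stop("undefined composition: sequence is all N")
  fr <- counts[DNA_BASES] / acgt
  list(counts = counts,
       fractions = fr,
       gc = unname((counts["G"] + counts["C"]) / acgt),
       length = nchar(rec$seq))
}

# ---- gene annotations -------------------------------------------------------

#' Build a gene annotation table
#'
#' Annotations are a plain data.frame with one row per exon, 1-based
#' inclusive coordinates. Wrap-around exons on circular molecules are encoded
#' as `start > end` (the exon runs through the origin).
#'
#' @param gene_id,feature_type,strand,start,end,exon_rank,copy_index vectors,
#'   recycled to a common length. `feature_type` must be one of
#'   `mRNA`, `tRNA`, `rRNA`, `pseudogene`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, feature_type = "mRNA", strand = "+",
                            start, end, exon_rank = 1L, copy_index = 1L) {
  if (length(gene_id) == 0L) {
    df <- data.frame(gene_id = character(0), feature_type = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0), exon_rank = integer(0),
                     copy_index = integer(0), stringsAsFactors = FALSE)
    class(df) <- c("gene_annotation", "data.frame")
    return(df)
  }
  df <- data.frame(gene_id = as.character(gene_id),
                   feature_type = as.character(feature_type),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   exon_rank = as.integer(exon_rank),
                   copy_index = as.integer(copy_index),
                   stringsAsFactors = FALSE)
  ok <- df$feature_type %in% c("mRNA", "tRNA", "rRNA", "pseudogene")
  if (!all(ok)) stop("unknown feature_type: ",
                     paste(unique(df$feature_type[!ok]), collapse = ","))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

validate_annotation <- function(ann, rec = NULL) {
  stopifnot(is.data.frame(ann))
  for (g in unique(ann$gene_id)) {
    ex <- ann[ann$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    lin <- ex[ex$start <= ex$end, , drop = FALSE]
    if (nrow(lin) > 1L) {
      o <- order(lin$start)
      if (any(lin$start[o][-1] <= lin$end[o][-nrow(lin)]))
        stop("overlapping exons in gene ", g)
    }
    if (!is.null(rec)) {
      L <- seq_len_bp(rec)
      if (any(ex$start < 1L | ex$end < 1L | pmax(ex$start, ex$end) > L))
        stop("exon out of bounds in gene ", g)
      if (any(ex$start > ex$end) && !rec$circular)
        stop("wrap-around exon on a linear sequence in gene ", g)
    }
  }
  invisible(TRUE)
}

#' Extract the coding sequence for one gene
#'
#' Exons are concatenated in transcription order and reverse-complemented for
#' minus-strand genes. Wrap-around exons (`start > end`) are resolved through
#' the circular origin.
#'
#' @param genome a [seq_record()].
#' @param ann a [gene_annotation()] table restricted to one gene (or a table
#'   plus `gene_id` to select).
#' @param gene_id optional gene to select from `ann`.
#' @return character scalar; attribute `in_frame` flags length %% 3 == 0.
#' @export
extract_cds <- function(genome, ann, gene_id = NULL) {
  if (!is.null(gene_id)) ann <- ann[ann$gene_id == gene_id, , drop = FALSE]
  stopifnot(nrow(ann) > 0L, length(unique(ann$gene_id)) == 1L)
  validate_annotation(ann, genome)
  ann <- ann[order(ann$exon_rank), , drop = FALSE]
  L <- seq_len_bp(genome)
  pieces <- mapply(function(s, e) {
    if (s <= e) substr(genome$seq, s, e)
    else paste0(substr(genome$seq, s, L), substr(genome$seq, 1L, e))
  }, ann$start, ann$end)
  cds <- paste(pieces, collapse = "")
  if (ann$strand[1] == "-") cds <- revcomp(cds)
  attr(cds, "in_frame") <- nchar(cds) %% 3L == 0L
  cds
}

#' Find open reading frames
#'
#' Scans all six frames for ORFs running from an `ATG` start codon to the
#' nearest in-frame stop; every qualifying start is reported (nested ORFs
#' sharing a stop appear once per start). Lengths include the stop codon.
#'
#' @param rec a [seq_record()].
#' @param min_len minimum ORF length in bp (stop included); must be a
#'   multiple of 3. Default 102.
#' @return data.frame with `start`, `end` (1-based inclusive on the forward
#'   strand), `strand`, `frame` (1..3 on the reading strand), `length`.
#' @export
find_orfs <- function(rec, min_len = 102L) {
  stopifnot(is(rec, "seq_record"), min_len %% 3L == 0L)
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    if (n < min_len) return(NULL)
    cods_at <- function(off) {
      starts <- seq(off, n - 2L, by = 3L)
      substring(s, starts, starts + 2L)
    }
    out <- list()
    for (off in 1:3) {
      if (n - off + 1L < 3L) next
      cods <- cods_at(off)
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      is_atg <- cods == "ATG"
      # for each codon index, index of next stop at or after it
      nxt <- integer(length(cods)); last <- NA_integer_
      for (i in rev(seq_along(cods))) {
        if (is_stop[i]) last <- i
        nxt[i] <- last
      }
      starts_i <- which(is_atg & !is.na(nxt))
      if (!length(starts_i)) next
      stops_i <- nxt[starts_i]
      len <- (stops_i - starts_i + 1L) * 3L
      keep <- len >= min_len
      if (!any(keep)) next
      st <- off + (starts_i[keep] - 1L) * 3L
      en <- off + stops_i[keep] * 3L - 1L
      out[[length(out) + 1L]] <-
        data.frame(start = st, end = en, strand = strand, frame = off,
                   length = len[keep])
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- scan_strand(rec$seq, "+")
  rcseq <- revcomp(rec$seq)
  rev_ <- scan_strand(rcseq, "-")
  n <- nchar(rec$seq)
  if (!is.null(rev_)) {
    # map coordinates back to the forward strand
    s2 <- n - rev_$end + 1L; e2 <- n - rev_$start + 1L
    rev_$start <- s2; rev_$end <- e2
  }
  res <- rbind(fwd, rev_)
  if (is.null(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length = integer(0)))
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# ---- GFF3 -------------------------------------------------------------------

#' Write / read gene annotations as GFF3
#'
#' Uses `rtracklayer` for serialization. Wrap-around exons cannot be
#' expressed in GFF3 and are rejected.
#'
#' @param ann a [gene_annotation()] table.
#' @param seq_id the sequence id the features live on.
#' @param path file path.
#' @export
write_gff3 <- function(ann, seq_id, path) {
  if (any(ann$start > ann$end)) stop("wrap-around exons cannot be written to GFF3")
  key <- paste(ann$gene_id, ann$copy_index, sep = "#")
  gene_rows <- do.call(rbind, lapply(unique(key), function(k) {
    ex <- ann[key == k, , drop = FALSE]
    data.frame(gene_id = ex$gene_id[1], feature_type = ex$feature_type[1],
               strand = ex$strand[1], start = min(ex$start),
               end = max(ex$end), copy_index = ex$copy_index[1])
  }))
  gkey <- paste(gene_rows$gene_id, gene_rows$copy_index, sep = "#")
  gr_gene <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(gene_rows$start, gene_rows$end),
    strand = gene_rows$strand,
    type = gene_rows$feature_type,
    ID = gkey, Name = gene_rows$gene_id,
    copy_index = gene_rows$copy_index)
  gr_ex <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand,
    type = "exon",
    ID = paste0(key, ".exon", ann$exon_rank),
    Parent = key,
    exon_rank = ann$exon_rank)
  rtracklayer::export(c(gr_gene, gr_ex), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parents <- vapply(ex$Parent, function(p) p[[1]], "")
  genes <- gr[gr$type != "exon"]
  gidx <- match(parents, genes$ID)
  rank <- if (!is.null(ex$exon_rank)) as.integer(ex$exon_rank)
          else as.integer(sub(".*exon", "", vapply(ex$ID, identity, "")))
  gene_annotation(
    gene_id = genes$Name[gidx],
    feature_type = as.character(genes$type[gidx]),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex), end = BiocGenerics::end(ex),
    exon_rank = rank,
    copy_index = as.integer(genes$copy_index[gidx]))
}

# ---- annotation transfer ----------------------------------------------------

#' Transfer gene annotations onto a target genome by local alignment
#'
#' Each reference gene sequence is aligned to the target with the shared
#' seed-and-extend aligner; hits covering at least `min_cov` of the reference
#' at identity at least `min_identity` become single-exon annotations.
#' Overlapping calls are resolved in favour of the higher-scoring hit.
#'
#' @param target [seq_record()] to annotate.
#' @param reference_genes list of [seq_record()] (or named character vector)
#'   of reference gene sequences.
#' @param min_identity,min_cov acceptance thresholds (defaults 0.7 / 0.7).
#' @param feature_type type recorded for accepted calls.
#' @return a [gene_annotation()] table with extra columns `identity`, `score`.
#' @export
transfer_annotation <- function(target, reference_genes,
                                min_identity = 0.7, min_cov = 0.7,
                                feature_type = "mRNA") {
  refs <- as_record_list(reference_genes)
  stopifnot(length(refs) > 0L)
  idx <- build_index(target, k = 9L)
  calls <- list()
  for (r in refs) {
    hits <- local_align(r$seq, idx, min_score = 20, query_id = r$id)
    if (!nrow(hits)) next
    cov <- (hits$q_end - hits$q_start + 1L) / nchar(r$seq)
    hits <- hits[hits$identity >= min_identity & cov >= min_cov, , drop = FALSE]
    if (nrow(hits)) calls[[length(calls) + 1L]] <- hits
  }
  if (!length(calls))
    return(gene_annotation(character(0), character(0), character(0),
                           integer(0), integer(0)))
  hits <- do.call(rbind, calls)
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(hits)) > i)
    ov <- spans_overlap(hits$t_start[i], hits$t_end[i],
                        hits$t_start[later], hits$t_end[later])
    keep[later[ov]] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  ann <- gene_annotation(gene_id = hits$query_id,
                         feature_type = feature_type,
                         strand = hits$strand,
                         start = hits$t_start, end = hits$t_end)
  ann$identity <- hits$identity
  ann$score <- hits$score
  ann[order(ann$start), , drop = FALSE]
}
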