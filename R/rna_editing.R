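#' C-to-U RNA editing: calling and hydropathy-effect classification
#'
#' Plant mitochondrial transcripts are post-transcriptionally edited,
#' overwhelmingly by C-to-U conversion. Candidate sites are called from RNA
#' reads piled up on the coding sequences: positions where the CDS carries C
#' but a sufficient fraction of covering reads carry T. Each site is
#' annotated with its codon context and the amino-acid consequence, and the
#' consequence is classified by the hydropathy classes of the residues
#' before and after editing.
#'
#' The hydropathy partition (hydrophilic: R K D E N Q H S T Y C G;
#' hydrophobic: A V L I P F M W; stop its own class) follows the
#' Kyte-Doolittle sign convention, with glycine grouped hydrophilic.
#'
#' @name rna_editing
NULL

HYDROPHILIC_AA <- c("R", "K", "D", "E", "N", "Q", "H", "S", "T", "Y", "C", "G")
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "P", "F", "M", "W")

hydropathy_class <- function(aa) {
  ifelse(aa == "*", "stop",
         ifelse(aa %in% HYDROPHILIC_AA, "hydrophilic",
                ifelse(aa %in% HYDROPHOBIC_AA, "hydrophobic", NA_character_)))
}

#' Classify an amino-acid change by hydropathy transition
#'
#' @param aa_before,aa_after one-letter amino acids (`*` or `X` for stop).
#' @return one of `hydrophilic-hydrophilic`, `hydrophilic-hydrophobic`,
#'   `hydrophilic-stop`, `hydrophobic-hydrophilic`,
#'   `hydrophobic-hydrophobic`, `hydrophobic-stop`. Vectorised.
#' @export
classify_hydropathy_transition <- function(aa_before, aa_after) {
  aa_before <- toupper(aa_before); aa_after <- toupper(aa_after)
  aa_before[aa_before == "X"] <- "*"; aa_after[aa_after == "X"] <- "*"
  c1 <- hydropathy_class(aa_before)
  c2 <- hydropathy_class(aa_after)
  if (anyNA(c1) || anyNA(c2))
    stop("unknown amino-acid symbol: ",
         paste(unique(c(aa_before[is.na(c1)], aa_after[is.na(c2)])),
               collapse = ","))
  if (any(c1 == "stop")) stop("stop codon cannot be the edited-from state")
  paste(c1, c2, sep = "-")
}

#' Annotate the coding consequence of one editing site
#'
#' @param gene gene id.
#' @param cds in-frame coding sequence of the gene.
#' @param cds_pos 1-based position of the site on the CDS.
#' @param edited_base the base observed on the transcript (default `T`).
#' @param depth,edit_fraction optional pileup support carried through.
#' @return one-row data.frame (class `editing_site`): gene, cds_pos,
#'   codon_index, codon_pos, ref_codon, edited_codon, aa_before, aa_after,
#'   category, start_gain, stop_gain, depth, edit_fraction.
#' @export
annotate_editing_effect <- function(gene, cds, cds_pos, edited_base = "T",
                                    depth = NA_integer_,
                                    edit_fraction = NA_real_) {
  stopifnot(cds_pos >= 1L, cds_pos <= nchar(cds))
  if (nchar(cds) %% 3L != 0L && cds_pos > (nchar(cds) %/% 3L) * 3L)
    stop("site falls in an incomplete terminal codon")
  ci <- (cds_pos - 1L) %/% 3L + 1L
  cp <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
  edited_codon <- ref_codon
  substr(edited_codon, cp, cp) <- edited_base
  aa1 <- codon_to_aa(ref_codon)
  aa2 <- codon_to_aa(edited_codon)
  out <- data.frame(
    gene = gene, cds_pos = as.integer(cds_pos), codon_index = ci,
    codon_pos = cp, ref_codon = ref_codon, edited_codon = edited_codon,
    aa_before = aa1, aa_after = aa2,
    category = classify_hydropathy_transition(aa1, aa2),
    start_gain = ci == 1L && ref_codon == "ACG" && edited_codon == "ATG",
    stop_gain = aa1 != "*" && aa2 == "*",
    depth = as.integer(depth), edit_fraction = edit_fraction,
    stringsAsFactors = FALSE)
  class(out) <- c("editing_site", "data.frame")
  out
}

#' Call candidate C-to-U editing sites from RNA reads
#'
#' Reads are aligned to each CDS with the shared aligner and piled up;
#' positions where the reference base is C and the T fraction reaches
#' `min_fraction` at depth at least `min_depth` are reported (mode `"any"`
#' lifts the C-to-T restriction and reports the modal alternate base).
#' Raising either threshold never adds sites.
#'
#' @param rna_reads named character vector of RNA read sequences
#'   (sense-strand).
#' @param cds_set named character vector of in-frame coding sequences.
#' @param min_depth minimum coverage (default 5).
#' @param min_fraction minimum edited-read fraction (default 0.1).
#' @param mode `"C2U"` (default) or `"any"`.
#' @param k seed word size for the read alignment.
#' @return data.frame of annotated editing sites (one row per site).
#' @export
call_editing_sites <- function(rna_reads, cds_set, min_depth = 5L,
                               min_fraction = 0.1, mode = c("C2U", "any"),
                               k = 11L) {
  mode <- match.arg(mode)
  if (is.list(cds_set)) cds_set <- vapply(as_record_list(cds_set),
                                          function(r) r$seq, "")
  stopifnot(!is.null(names(cds_set)))
  idx <- build_index(cds_set, k = k)
  hits <- list()
  for (i in seq_along(rna_reads)) {
    h <- local_align(rna_reads[[i]], idx,
                     min_score = max(20, floor(nchar(rna_reads[[i]]) * 0.6)),
                     traceback = TRUE,
                     query_id = names(rna_reads)[i] %||% paste0("read", i))
    if (nrow(h)) hits[[length(hits) + 1L]] <- h[1L, , drop = FALSE]
  }
  empty <- annotate_editing_effect("g", "ATGTAA", 1L)[0, ]
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  pile <- pileup(hits, cds_set)
  if (!nrow(pile)) return(empty)
  alt_count <- if (mode == "C2U") pile$T else {
    pmax(pile$A * (pile$ref != "A"), pile$C * (pile$ref != "C"),
         pile$G * (pile$ref != "G"), pile$T * (pile$ref != "T"))
  }
  frac <- ifelse(pile$depth > 0, alt_count / pile$depth, 0)
  sel <- pile$depth >= min_depth & frac >= min_fraction & alt_count > 0
  if (mode == "C2U") sel <- sel & pile$ref == "C"
  sel <- which(sel)
  if (!length(sel)) return(empty)
  rows <- lapply(sel, function(j) {
    ed <- if (mode == "C2U") "T" else {
      bs <- c(A = pile$A[j], C = pile$C[j], G = pile$G[j], T = pile$T[j])
      bs[pile$ref[j]] <- -1L
      names(which.max(bs))
    }
    annotate_editing_effect(pile$target_id[j], cds_set[[pile$target_id[j]]],
                            pile$pos[j], edited_base = ed,
                            depth = pile$depth[j],
                            edit_fraction = frac[j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise editing sites by hydropathy category
#'
#' Accepts either a table of called sites (from [call_editing_sites()]) or a
#' codon-transition tabulation with columns `ref_codon`, `edited_codon` and
#' `count` (e.g. a published transition table used as input). Produces
#' per-category counts and percentages of the total (2 d.p.), the
#' per-codon-transition breakdown, and per-gene site counts when gene ids
#' are present.
#'
#' @param sites data.frame as described above.
#' @return list: `total`, `by_category` (category, count, pct),
#'   `by_transition`, `by_gene` (NULL without gene ids).
#' @export
editing_summary <- function(sites) {
  stopifnot(nrow(sites) > 0L)
  if (is.null(sites$count)) sites$count <- 1L
  if (is.null(sites$category)) {
    aa1 <- codon_to_aa(sites$ref_codon)
    aa2 <- codon_to_aa(sites$edited_codon)
    sites$category <- classify_hydropathy_transition(aa1, aa2)
  }
  total <- sum(sites$count)
  cat_levels <- c("hydrophilic-hydrophilic", "hydrophilic-hydrophobic",
                  "hydrophilic-stop", "hydrophobic-hydrophilic",
                  "hydrophobic-hydrophobic", "hydrophobic-stop")
  cat_cnt <- tapply(sites$count, factor(sites$category, cat_levels), sum)
  cat_cnt[is.na(cat_cnt)] <- 0
  by_category <- data.frame(category = cat_levels,
                            count = as.integer(cat_cnt),
                            pct = round(100 * as.integer(cat_cnt) / total, 2),
                            row.names = NULL)
  key <- paste(sites$ref_codon, sites$edited_codon, sep = ">")
  tr_cnt <- tapply(sites$count, key, sum)
  by_transition <- data.frame(transition = names(tr_cnt),
                              count = as.integer(tr_cnt), row.names = NULL)
  by_gene <- NULL
  if (!is.null(sites$gene)) {
    g <- tapply(sites$count, sites$gene, sum)
    by_gene <- data.frame(gene = names(g), n_sites = as.integer(g),
                          row.names = NULL)
  }
  list(total = total, by_category = by_category,
       by_transition = by_transition, by_gene = by_gene)
}

#' Bundled reference tabulations
#'
#' Plain-text reference tables distributed with the package for the
#' decaploid *Camellia hainanica* mitochondrial genome (GenBank PV110147):
#' RNA-editing codon-transition counts, SSR class counts, and the
#' mitochondrion-plastid homologous-fragment coordinates. They serve as
#' worked-example inputs for [editing_summary()], [ssr_class_summary()] and
#' [fragment_summary()].
#'
#' @param name one of `"editing_transitions"`, `"ssr_classes"`,
#'   `"mtpt_fragments"`.
#' @return data.frame.
#' @export
reference_table <- function(name = c("editing_transitions", "ssr_classes",
                                     "mtpt_fragments")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".tsv"), package = "mitokit",
                   mustWork = TRUE)
  df <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "#", fill = TRUE)
  for (col in names(df))
    if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
  df
}
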