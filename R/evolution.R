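#' Codon-level selection and diversity statistics
#'
#' Implements the Li-Wu-Luo (LWL) Ka/Ks estimator and its modified variant
#' (MLWL) on codon-wise alignments, per-gene nucleotide diversity with
#' pairwise gap deletion, and shared-CDS selection for phylogenetic
#' matrices.
#'
#' LWL partitions the three positions of every codon into nondegenerate
#' (0-fold), two-fold and four-fold classes, counts transitions and
#' transversions per class (averaging over all minimal substitution
#' pathways for codons differing at more than one position, excluding
#' pathways through stop codons), applies a Kimura two-parameter correction
#' per class, and composes
#' \deqn{Ks = (L2 A2 + L4 (A4 + B4)) / (L2/3 + L4)}
#' \deqn{Ka = (L0 (A0 + B0) + L2 B2) / (L0 + 2 L2 / 3)}
#' MLWL refines the two-fold class: sites whose synonymous change is a
#' transversion (e.g. Arg AGA position 1, Ile ATA position 3) contribute
#' their transversion distance to Ks instead, and the fixed 1/3 : 2/3 split
#' of two-fold sites is replaced by the observed transition proportion
#' r = R/(R+1). With no such sites and R = 0.5 MLWL equals LWL.
#'
#' @name evolution
NULL

# --- site degeneracy tables (computed once at load from the genetic code) ---

.degeneracy_env <- new.env(parent = emptyenv())

degeneracy_table <- function() {
  if (!is.null(.degeneracy_env$tab)) return(.degeneracy_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  tab <- list()
  for (cod in codons) {
    aa <- gc[[cod]]
    row <- list()
    for (p in 1:3) {
      alts <- setdiff(DNA_BASES, substr(cod, p, p))
      mut <- vapply(alts, function(b) { x <- cod; substr(x, p, p) <- b; x }, "")
      syn <- gc[mut] == aa            # change to stop is nonsynonymous
      nsyn <- sum(syn)
      fold <- if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
      syn_ts <- any(syn & is_transition(substr(cod, p, p), alts))
      # two-fold subtype: transversional iff no synonymous transition exists
      subtype <- if (fold != 2L) NA_character_
                 else if (syn_ts) "2s" else "2v"
      row[[p]] <- list(fold = fold, subtype = subtype)
    }
    tab[[cod]] <- row
  }
  .degeneracy_env$tab <- tab
  tab
}

#' Classify the degeneracy of one codon position
#'
#' @param codon a sense codon (stop codons are flagged with an error).
#' @param position 1, 2 or 3.
#' @return `"0-fold"`, `"2-fold"` or `"4-fold"`; attribute `subtype` is
#'   `"2s"` (synonymous change is a transition) or `"2v"` (transversion)
#'   for two-fold sites.
#' @export
classify_site_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  stopifnot(position %in% 1:3)
  if (codon_to_aa(codon) == "*")
    stop("stop codon: excluded from site counts")
  e <- degeneracy_table()[[codon]][[position]]
  structure(paste0(e$fold, "-fold"), subtype = e$subtype)
}

# per-codon site-class weight vector c(L0, L2s, L2v, L4); NULL for stops
codon_site_weights <- function(codon) {
  if (codon_to_aa(codon) == "*") return(NULL)
  row <- degeneracy_table()[[codon]]
  w <- c(`0` = 0, `2s` = 0, `2v` = 0, `4` = 0)
  for (p in 1:3) {
    e <- row[[p]]
    key <- if (e$fold == 2L) e$subtype else as.character(e$fold)
    w[key] <- w[key] + 1
  }
  w
}

# --- codon-aware pairwise alignment -----------------------------------------

#' Codon-aware alignment of two coding sequences
#'
#' Proteins are aligned globally (identity scoring, affine gaps) and the
#' alignment is back-threaded to nucleotides; codon columns containing a
#' gap, an ambiguous base, or a stop in either sequence are excluded.
#'
#' @param a,b in-frame coding sequences (character scalars).
#' @return list of class `codon_alignment`: `codons_a`, `codons_b`
#'   (equal-length codon vectors, gap- and stop-free), `n_codons`.
#' @export
codon_align <- function(a, b) {
  stopifnot(nchar(a) %% 3L == 0L, nchar(b) %% 3L == 0L)
  pa_ <- translate_dna(a); pb_ <- translate_dna(b)
  # strip terminal stops before aligning
  if (endsWith(pa_, "*")) { pa_ <- substr(pa_, 1, nchar(pa_) - 1) }
  if (endsWith(pb_, "*")) { pb_ <- substr(pb_, 1, nchar(pb_) - 1) }
  aas <- unique(c(strsplit(paste0(pa_, pb_), "")[[1]], "X"))
  subm <- matrix(-1, length(aas), length(aas), dimnames = list(aas, aas))
  diag(subm) <- 1
  pal <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(pa_), subject = Biostrings::AAString(pb_),
    type = "global", substitutionMatrix = subm,
    gapOpening = 7, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pal)), "")[[1]]
  qb <- strsplit(as.character(Biostrings::alignedSubject(pal)), "")[[1]]
  ca <- split_codons(a); cb <- split_codons(b)
  ia <- 0L; ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  for (j in seq_along(qa)) {
    if (qa[j] != "-") ia <- ia + 1L
    if (qb[j] != "-") ib <- ib + 1L
    if (qa[j] != "-" && qb[j] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  codons_a <- ca[keep_a]; codons_b <- cb[keep_b]
  ok <- !grepl("N", codons_a) & !grepl("N", codons_b) &
    codon_to_aa(codons_a) != "*" & codon_to_aa(codons_b) != "*"
  structure(list(codons_a = codons_a[ok], codons_b = codons_b[ok],
                 n_codons = sum(ok)),
            class = "codon_alignment")
}

# enumerate minimal substitution pathways between two codons and return the
# averaged per-step difference records (position, from, to)
codon_pathway_steps <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diffpos)
  if (nd == 0L) return(NULL)
  perms <- if (nd == 1L) list(diffpos)
           else if (nd == 2L) list(diffpos, rev(diffpos))
           else {
    p <- diffpos
    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)],
         p[c(3,1,2)], p[c(3,2,1)])
  }
  path_steps <- list(); path_ok <- logical(0)
  for (perm in perms) {
    cur <- c1
    steps <- list()
    blocked <- FALSE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (codon_to_aa(nxt) == "*" || codon_to_aa(cur) == "*") blocked <- TRUE
      steps[[length(steps) + 1L]] <-
        list(pos = p, from = substr(cur, p, p), to = substr(c2, p, p))
      cur <- nxt
    }
    path_steps[[length(path_steps) + 1L]] <- steps
    path_ok <- c(path_ok, !blocked)
  }
  use <- if (any(path_ok)) which(path_ok) else seq_along(path_steps)
  w <- 1 / length(use)
  out <- list()
  for (i in use) for (st in path_steps[[i]])
    out[[length(out) + 1L]] <- c(st, weight = w)
  out
}

#' LWL / MLWL Ka and Ks for a codon alignment
#'
#' @param aln a [codon_align()] result, or a length-2 character vector of
#'   in-frame CDS to align first.
#' @param method `"MLWL"` (default) or `"LWL"`.
#' @param gene_id id carried into the result.
#' @return one-row data.frame (class `kaks_result`): gene, method, L0, L2,
#'   L4, A0..B4 distances, ts/tv counts, Ka, Ks, ratio (`NA` when Ks is 0),
#'   `saturated` flag.
#' @export
compute_kaks <- function(aln, method = c("MLWL", "LWL"), gene_id = "gene") {
  method <- match.arg(method)
  if (is.character(aln) && length(aln) == 2L) aln <- codon_align(aln[1], aln[2])
  stopifnot(is(aln, "codon_alignment"))
  if (aln$n_codons < 10L) stop("need at least 10 gap-free codons")
  ca <- aln$codons_a; cb <- aln$codons_b
  # site counts averaged over the two sequences
  L <- c(`0` = 0, `2s` = 0, `2v` = 0, `4` = 0)
  for (i in seq_along(ca)) {
    L <- L + (codon_site_weights(ca[i]) + codon_site_weights(cb[i])) / 2
  }
  # substitution counts per class: S = transitions, V = transversions
  S <- c(`0` = 0, `2s` = 0, `2v` = 0, `4` = 0)
  V <- S
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    steps <- codon_pathway_steps(ca[i], cb[i])
    for (st in steps) {
      p <- st$pos
      ea <- degeneracy_table()[[ca[i]]][[p]]
      eb <- degeneracy_table()[[cb[i]]][[p]]
      keys <- vapply(list(ea, eb), function(e)
        if (e$fold == 2L) e$subtype else as.character(e$fold), "")
      ts <- is_transition(st$from, st$to)
      for (key in keys) {
        if (ts) S[key] <- S[key] + 0.5 * st$weight
        else V[key] <- V[key] + 0.5 * st$weight
      }
    }
  }
  k2p <- function(P, Q) {
    P <- unname(P); Q <- unname(Q)
    a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) return(c(A = NA_real_, B = NA_real_))
    c(A = 0.5 * log(1 / a1) - 0.25 * log(1 / a2),
      B = 0.5 * log(1 / a2))
  }
  AB <- sapply(names(L), function(key) {
    if (L[key] == 0) return(c(A = 0, B = 0))
    k2p(S[key] / L[key], V[key] / L[key])
  })
  saturated <- anyNA(AB)
  L0 <- L[["0"]]; L2s <- L[["2s"]]; L2v <- L[["2v"]]; L4 <- L[["4"]]
  L2 <- L2s + L2v
  # pooled 2-fold distances for the classic LWL composition
  P2 <- if (L2 > 0) (S[["2s"]] + S[["2v"]]) / L2 else 0
  Q2 <- if (L2 > 0) (V[["2s"]] + V[["2v"]]) / L2 else 0
  AB2 <- if (L2 > 0) k2p(P2, Q2) else c(A = 0, B = 0)
  saturated <- saturated || anyNA(AB2)
  if (saturated) {
    Ka <- NA_real_; Ks <- NA_real_
  } else if (method == "LWL") {
    Ks <- (L2 * AB2[["A"]] + L4 * (AB["A", "4"] + AB["B", "4"])) /
      (L2 / 3 + L4)
    Ka <- (L0 * (AB["A", "0"] + AB["B", "0"]) + L2 * AB2[["B"]]) /
      (L0 + 2 * L2 / 3)
  } else {
    Stot <- sum(S); Vtot <- sum(V)
    r <- if (Stot + Vtot == 0) 1 / 3
         else if (Vtot == 0) 1
         else { R <- Stot / Vtot; R / (R + 1) }
    syn_sites <- L2s * r + L2v * (1 - r) + L4
    non_sites <- L0 + L2s * (1 - r) + L2v * r
    Ks <- if (syn_sites > 0)
      (L2s * AB["A", "2s"] + L2v * AB["B", "2v"] +
         L4 * (AB["A", "4"] + AB["B", "4"])) / syn_sites else 0
    Ka <- if (non_sites > 0)
      (L0 * (AB["A", "0"] + AB["B", "0"]) + L2s * AB["B", "2s"] +
         L2v * AB["A", "2v"]) / non_sites else 0
  }
  out <- data.frame(
    gene = gene_id, method = method,
    L0 = L0, L2 = L2, L2s = L2s, L2v = L2v, L4 = L4,
    A0 = AB["A", "0"], B0 = AB["B", "0"],
    A2 = AB2[["A"]], B2 = AB2[["B"]],
    A4 = AB["A", "4"], B4 = AB["B", "4"],
    ts_total = sum(S), tv_total = sum(V),
    Ka = unname(Ka), Ks = unname(Ks),
    ratio = if (!is.na(Ks) && Ks > 0) unname(Ka / Ks) else NA_real_,
    saturated = saturated,
    n_codons = aln$n_codons, stringsAsFactors = FALSE)
  class(out) <- c("kaks_result", "data.frame")
  out
}

#' Nucleotide diversity (pi)
#'
#' Average pairwise nucleotide difference per site over a set of aligned
#' sequences, with pairwise deletion of gap/N columns:
#' \deqn{\pi = \sum_{i<j} d_{ij} / \binom{n}{2}}
#'
#' @param seqs character vector (length >= 2) of equal-length aligned
#'   sequences; `-` and `N` are treated as missing.
#' @param gene_id id carried into the result.
#' @return one-row data.frame: gene, n_seqs, sites (minimum pairwise
#'   comparable sites), pi.
#' @export
nucleotide_diversity <- function(seqs, gene_id = "gene") {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  valid <- mat %in% DNA_BASES
  dim(valid) <- dim(mat)
  n <- nrow(mat)
  dsum <- 0; min_sites <- ncol(mat)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    sites <- sum(ok)
    if (sites == 0L) stop("no comparable sites between sequences ", i, ",", j)
    dsum <- dsum + sum(mat[i, ok] != mat[j, ok]) / sites
    min_sites <- min(min_sites, sites)
  }
  data.frame(gene = gene_id, n_seqs = n, sites = min_sites,
             pi = dsum / choose(n, 2), stringsAsFactors = FALSE)
}

#' Select CDS shared by a fraction of species
#'
#' @param presence logical/0-1 matrix, genes in rows (named), species in
#'   columns.
#' @param threshold minimum fraction of species (default 0.7); a gene is
#'   kept when present in at least `ceiling(threshold * n_species)` species.
#' @return character vector of retained gene names, sorted.
#' @export
shared_cds_selection <- function(presence, threshold = 0.7) {
  stopifnot(is.matrix(presence), nrow(presence) > 0L, ncol(presence) > 0L)
  stopifnot(all(presence %in% c(0, 1, TRUE, FALSE)))
  need <- ceiling(threshold * ncol(presence))
  keep <- rowSums(presence == 1 | presence == TRUE) >= need
  sort(rownames(presence)[keep])
}
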