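#' Synthetic mitogenome bundles with machine-readable ground truth
#'
#' The generator emits every input the analysis consumes — a circular
#' mitogenome with planted microsatellites, tandem and dispersed repeats and
#' annotated CDS; long DNA reads with labelled nuclear/plastid contaminants;
#' RNA reads carrying planted C-to-U edits; homolog sets with controlled
#' synonymous/nonsynonymous divergence; and a plastid genome carrying
#' degraded copies of mitochondrial segments — together with a truth object
#' recording every planted feature by exact coordinates.
#'
#' Background sequence is drawn i.i.d. per base at the target GC and then
#' scrubbed: windows that accidentally contain repeats at the detection
#' thresholds of the repeats module are resampled, and the bases flanking
#' every planted repeat are set to break periodicity, so that on clean
#' background the detectors see planted features and nothing else.
#' Reads are error-free unless an error rate is requested.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' @param seed integer RNG seed (all outputs are byte-identical for
#'   identical configurations).
#' @param genome_length genome size in bp.
#' @param gc_target background GC fraction, in (0,1).
#' @param n_genes number of planted protein-coding genes.
#' @param gene_length_range range (bp, multiples of 3 enforced) for gene
#'   lengths, start and stop codons included.
#' @param ssr_plan data.frame(`motif`, `copies`[, `start`]); `start = NA`
#'   places automatically.
#' @param tandem_plan data.frame(`unit`, `copies`[, `start`]); perfect
#'   tandems; `(copies-1) * nchar(unit)` must be at least 25 so the locus
#'   clears the reporting score floor.
#' @param dispersed_plan data.frame(`length`, `orientation`); pairs of
#'   copies of clean background segments.
#' @param edit_plan data.frame(`gene`, `codon_index`, `codon_pos`
#'   [, `fraction`]); the reference base at each site is forced to C.
#'   `codon_index = 1, codon_pos = 2` turns the start codon into ACG.
#' @param transfer_plan data.frame(`length`, `identity`) of
#'   plastid-transfer fragments.
#' @param divergence_plan data.frame(`species`, `ks`, `ka`) for homolog
#'   sets.
#' @param read_profile list: `depth`, `mean_len`, `sd_len`, `min_len`,
#'   `contaminant_fraction`, `error_rate`, `rna_read_len`, `rna_depth`,
#'   `edit_fraction`.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             genome_length = 50000L,
                             gc_target = 0.45,
                             n_genes = 8L,
                             gene_length_range = c(600L, 1500L),
                             ssr_plan = default_ssr_plan(),
                             tandem_plan = default_tandem_plan(),
                             dispersed_plan = default_dispersed_plan(),
                             edit_plan = NULL,
                             transfer_plan = default_transfer_plan(),
                             divergence_plan = default_divergence_plan(),
                             read_profile = default_read_profile()) {
  stopifnot(gc_target > 0, gc_target < 1, genome_length > 1000)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_target = gc_target, n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              ssr_plan = ssr_plan, tandem_plan = tandem_plan,
              dispersed_plan = dispersed_plan, edit_plan = edit_plan,
              transfer_plan = transfer_plan,
              divergence_plan = divergence_plan,
              read_profile = read_profile)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Default feature plans
#'
#' The default plans emulate the repeat landscape reported for Camellia
#' mitogenomes at toy scale: SSR classes across unit lengths 1-6 (kept
#' short of the tandem score floor so the two detectors stay disjoint),
#' perfect tandem repeats with periods 10-30 bp, and direct plus inverted
#' dispersed repeats of 30-300 bp.
#'
#' @name default_plans
#' @export
default_ssr_plan <- function() {
  data.frame(
    motif = c("A", "T", "C", "AG", "AT", "TC", "AAG", "CTT", "TTG",
              "AAAG", "TTCT", "TCAT", "GGCTT", "AATCT", "TTGCGC"),
    copies = c(10L, 12L, 10L, 5L, 6L, 5L, 4L, 4L, 5L,
               3L, 4L, 3L, 3L, 3L, 3L),
    start = NA_integer_, stringsAsFactors = FALSE)
}

#' @rdname default_plans
#' @export
default_tandem_plan <- function() {
  data.frame(unit = c("CCGGCGCAGGCTCAGCAGGAGGGG", "GAAGGGAAGATACCATCCTA",
                      "TCATATTGATTCTATTTT", "AGGTTCGGCTAGCTTAGCTATT"),
              copies = c(3L, 3L, 4L, 3L),
              start = NA_integer_, stringsAsFactors = FALSE)
}

#' @rdname default_plans
#' @export
default_dispersed_plan <- function() {
  data.frame(length = c(200L, 120L, 60L, 45L),
              orientation = c("direct", "inverted", "direct", "inverted"),
              stringsAsFactors = FALSE)
}

#' @rdname default_plans
#' @export
default_transfer_plan <- function() {
  data.frame(length = c(800L, 400L, 150L, 100L),
              identity = c(1.0, 0.95, 0.9, 0.85), stringsAsFactors = FALSE)
}

#' @rdname default_plans
#' @export
default_divergence_plan <- function() {
  data.frame(species = c("sp1", "sp2"), ks = c(0.2, 0.05),
              ka = c(0.02, 0.005), stringsAsFactors = FALSE)
}

#' @rdname default_plans
#' @export
default_read_profile <- function() {
  list(depth = 25, mean_len = 3000, sd_len = 800, min_len = 500,
       contaminant_fraction = 0, error_rate = 0,
       rna_read_len = 150L, rna_depth = 20, edit_fraction = 0.9)
}

validate_config <- function(cfg) {
  sp <- cfg$ssr_plan
  if (!is.null(sp) && nrow(sp)) {
    u <- nchar(sp$motif)
    if (any(u < 1 | u > 6)) stop("planning error: SSR motifs must be 1-6 bp")
    if (any(!vapply(sp$motif, is_primitive_motif, TRUE)))
      stop("planning error: SSR motif is a repetition of a shorter unit")
    minr <- MISA_DEFAULT_MIN[as.character(u)]
    if (any(sp$copies < minr))
      stop("planning error: SSR copies below the detection class minimum")
    if (any(2 * (sp$copies * u - u) >= 50))
      stop("planning error: SSR tract reaches the tandem score floor; shorten it")
  }
  tp <- cfg$tandem_plan
  if (!is.null(tp) && nrow(tp)) {
    per <- nchar(tp$unit)
    if (any((tp$copies - 1) * per < 25))
      stop("planning error: tandem locus below the score floor ((copies-1)*period >= 25)")
    if (any(!vapply(tp$unit, is_primitive_motif, TRUE)))
      stop("planning error: tandem unit is itself periodic")
    if (any(per <= 6))
      stop("planning error: tandem periods of 6 bp or less belong in ssr_plan")
  }
  dp <- cfg$dispersed_plan
  if (!is.null(dp) && nrow(dp) && any(dp$length < 30))
    stop("planning error: dispersed repeats must be at least 30 bp")
  trp <- cfg$transfer_plan
  if (!is.null(trp) && nrow(trp)) {
    if (any(trp$length < 30)) stop("range error: transfer length below 30 bp")
    if (any(trp$identity < 0.5))
      stop("range error: transfer identity below 0.5 is undetectable by design")
    if (any(trp$identity > 1)) stop("range error: identity above 1")
  }
  # rough capacity check
  need <- 0
  if (!is.null(sp) && nrow(sp)) need <- need + sum(nchar(sp$motif) * sp$copies)
  if (!is.null(tp) && nrow(tp)) need <- need + sum(nchar(tp$unit) * tp$copies)
  if (!is.null(dp) && nrow(dp)) need <- need + 2 * sum(dp$length)
  need <- need + cfg$n_genes * max(cfg$gene_length_range)
  if (need * 1.3 + 60L * (cfg$n_genes + 20L) > cfg$genome_length)
    stop("capacity error: genome too short for the plan")
  invisible(TRUE)
}

# random in-frame CDS: ATG + non-stop codons + stop; repeat-free
random_cds <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  w <- vapply(sense, function(cod) {
    g <- sum(strsplit(cod, "")[[1]] %in% c("G", "C"))
    (gc / 3)^g * ((1 - gc) / 3)^(3 - g)
  }, 0)
  repeat {
    body <- sample(sense, len / 3L - 2L, replace = TRUE, prob = w)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    if (nrow(find_ssrs(cds)) == 0L) return(cds)
  }
}

# resample SSR/tandem-bearing windows of a background string until clean
clean_background <- function(s, gc, max_iter = 30L) {
  for (it in seq_len(max_iter)) {
    bad_s <- integer(0); bad_e <- integer(0)
    ss <- find_ssrs(s)
    if (nrow(ss)) { bad_s <- c(bad_s, ss$start); bad_e <- c(bad_e, ss$end) }
    tr <- find_tandem_repeats(s)
    if (nrow(tr)) { bad_s <- c(bad_s, tr$start); bad_e <- c(bad_e, tr$end) }
    if (!length(bad_s)) return(s)
    iv <- merge_intervals(pmax(1L, bad_s - 3L),
                          pmin(nchar(s), bad_e + 3L))
    for (r in seq_len(nrow(iv))) {
      w <- iv[r, "end"] - iv[r, "start"] + 1L
      substr(s, iv[r, "start"], iv[r, "end"]) <- rand_dna(w, gc)
    }
  }
  stop("could not scrub background of incidental repeats")
}

# break tandem periodicity at the flanks of a planted [s,e] locus of unit u
break_flanks <- function(genome, s, e, u) {
  n <- nchar(genome)
  if (s > 1L) {
    inside <- substr(genome, s + u - 1L, s + u - 1L)
    cur <- substr(genome, s - 1L, s - 1L)
    if (cur == inside) {
      avoid <- c(inside, if (s > 2L) substr(genome, s - 2L, s - 2L))
      substr(genome, s - 1L, s - 1L) <- sample(setdiff(DNA_BASES, avoid), 1L)
    }
  }
  if (e < n) {
    inside <- substr(genome, e + 1L - u, e + 1L - u)
    cur <- substr(genome, e + 1L, e + 1L)
    if (cur == inside) {
      avoid <- c(inside, if (e + 2L <= n) substr(genome, e + 2L, e + 2L))
      substr(genome, e + 1L, e + 1L) <- sample(setdiff(DNA_BASES, avoid), 1L)
    }
  }
  genome
}

#' Generate the synthetic mitogenome, annotation and truth
#'
#' @param config a [generator_config()].
#' @return list: `genome` ([seq_record()], circular), `annotation`
#'   ([gene_annotation()]), `cds` (named vector of reference CDS),
#'   `truth` (class `synthetic_truth`).
#' @export
generate_genome <- function(config) {
  stopifnot(is(config, "generator_config"))
  with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(cfg) {
  L <- cfg$genome_length
  genome <- clean_background(rand_dna(L, cfg$gc_target), cfg$gc_target)
  occupied_s <- integer(0); occupied_e <- integer(0)
  margin <- 150L; gap <- 25L
  reserve <- function(s, e) {
    occupied_s <<- c(occupied_s, s); occupied_e <<- c(occupied_e, e)
  }
  free_span <- function(s, e) {
    s >= margin && e <= L - margin &&
      !any(spans_overlap(s - gap, e + gap, occupied_s, occupied_e))
  }
  place <- function(len, want = NA_integer_) {
    if (!is.na(want)) {
      if (!free_span(want, want + len - 1L))
        stop("planning error: requested span overlaps another feature")
      reserve(want, want + len - 1L)
      return(want)
    }
    for (try in 1:500) {
      s <- sample.int(L - len - 2L * margin, 1L) + margin
      if (free_span(s, s + len - 1L)) { reserve(s, s + len - 1L); return(s) }
    }
    stop("capacity error: could not place a feature of length ", len)
  }

  # genes
  genes <- list(); cds <- character(0)
  gl <- cfg$gene_length_range
  edit_plan <- cfg$edit_plan
  if (cfg$n_genes > 0) for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%02d", i)
    len <- 3L * sample(seq(gl[1] %/% 3L, gl[2] %/% 3L), 1L)
    g <- random_cds(len, cfg$gc_target)
    if (!is.null(edit_plan)) {
      ep <- edit_plan[edit_plan$gene == gid, , drop = FALSE]
      for (r in seq_len(nrow(ep))) {
        ci <- ep$codon_index[r]; cp <- ep$codon_pos[r]
        if (ci >= len %/% 3L) stop("planning error: edit in stop codon of ", gid)
        pos <- (ci - 1L) * 3L + cp
        if (ci == 1L) {
          if (cp != 2L) stop("planning error: codon-1 edits must be at position 2 (ACG start)")
          substr(g, 1L, 3L) <- "ACG"
        } else {
          substr(g, pos, pos) <- "C"
          # avoid creating an internal stop via later editing context checks
        }
      }
    }
    strand <- sample(c("+", "-"), 1L)
    s <- place(len)
    planted <- if (strand == "+") g else revcomp(g)
    substr(genome, s, s + len - 1L) <- planted
    genes[[gid]] <- list(gene = gid, start = s, end = s + len - 1L,
                         strand = strand)
    cds[gid] <- g
  }

  # SSRs
  ssr_truth <- NULL
  sp <- cfg$ssr_plan
  if (!is.null(sp) && nrow(sp)) {
    rows <- list()
    for (r in seq_len(nrow(sp))) {
      u <- nchar(sp$motif[r]); len <- u * sp$copies[r]
      s <- place(len, if ("start" %in% names(sp)) sp$start[r] else NA_integer_)
      substr(genome, s, s + len - 1L) <-
        paste(rep(sp$motif[r], sp$copies[r]), collapse = "")
      genome <- break_flanks(genome, s, s + len - 1L, u)
      rows[[r]] <- data.frame(motif = sp$motif[r], unit_length = u,
                              repeat_count = sp$copies[r], start = s,
                              end = s + len - 1L, stringsAsFactors = FALSE)
    }
    ssr_truth <- do.call(rbind, rows)
  }

  # tandem repeats
  tand_truth <- NULL
  tp <- cfg$tandem_plan
  if (!is.null(tp) && nrow(tp)) {
    rows <- list()
    for (r in seq_len(nrow(tp))) {
      per <- nchar(tp$unit[r]); len <- per * tp$copies[r]
      s <- place(len, if ("start" %in% names(tp)) tp$start[r] else NA_integer_)
      substr(genome, s, s + len - 1L) <-
        paste(rep(tp$unit[r], tp$copies[r]), collapse = "")
      genome <- break_flanks(genome, s, s + len - 1L, per)
      rows[[r]] <- data.frame(unit = tp$unit[r], period = per,
                              copies = tp$copies[r], start = s,
                              end = s + len - 1L, stringsAsFactors = FALSE)
    }
    tand_truth <- do.call(rbind, rows)
  }

  # dispersed repeats: duplicate clean background segments
  disp_truth <- NULL
  dp <- cfg$dispersed_plan
  if (!is.null(dp) && nrow(dp)) {
    rows <- list()
    for (r in seq_len(nrow(dp))) {
      len <- dp$length[r]
      s1 <- place(len); s2 <- place(len)
      seg <- substr(genome, s1, s1 + len - 1L)
      copy <- if (dp$orientation[r] == "inverted") revcomp(seg) else seg
      substr(genome, s2, s2 + len - 1L) <- copy
      a <- min(s1, s2); b <- max(s1, s2)
      rows[[r]] <- data.frame(a_start = a, a_end = a + len - 1L,
                              b_start = b, b_end = b + len - 1L,
                              orientation = dp$orientation[r], length = len,
                              identity = 1, stringsAsFactors = FALSE)
    }
    disp_truth <- do.call(rbind, rows)
  }

  # verification sweep: any detector output not in truth is scrubbed by
  # breaking a base outside all planted spans
  planted_s <- c(occupied_s); planted_e <- c(occupied_e)
  for (it in 1:50) {
    found <- find_ssrs(genome)
    key_found <- if (nrow(found))
      paste(found$motif, found$start, found$end) else character(0)
    key_truth <- if (!is.null(ssr_truth))
      paste(ssr_truth$motif, ssr_truth$start, ssr_truth$end) else character(0)
    extra <- found[!(key_found %in% key_truth), , drop = FALSE]
    tfound <- find_tandem_repeats(genome)
    if (nrow(tfound) && !is.null(tand_truth)) {
      ok <- vapply(seq_len(nrow(tfound)), function(i)
        any(spans_overlap(tfound$start[i], tfound$end[i],
                          tand_truth$start, tand_truth$end)), TRUE)
      tfound <- tfound[!ok, , drop = FALSE]
    }
    if (!nrow(extra) && !nrow(tfound)) break
    bad <- rbind(
      if (nrow(extra)) data.frame(start = extra$start, end = extra$end,
                                  u = extra$unit_length),
      if (nrow(tfound)) data.frame(start = tfound$start, end = tfound$end,
                                   u = tfound$period))
    for (r in seq_len(nrow(bad))) {
      cand <- setdiff(seq(bad$start[r], bad$end[r]),
                      unlist(mapply(seq, planted_s, planted_e,
                                    SIMPLIFY = FALSE)))
      if (!length(cand))
        stop("incidental repeat entirely inside planted features")
      p <- cand[ceiling(length(cand) / 2)]
      avoid <- unique(c(substr(genome, p, p),
                        if (p > 1L) substr(genome, p - 1L, p - 1L),
                        if (p < nchar(genome)) substr(genome, p + 1L, p + 1L)))
      repl <- setdiff(DNA_BASES, avoid)
      if (!length(repl)) repl <- setdiff(DNA_BASES, substr(genome, p, p))
      substr(genome, p, p) <- sample(repl, 1L)
    }
  }

  gene_df <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g$gene, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)))
  ann <- if (length(genes))
    gene_annotation(gene_id = gene_df$gene, feature_type = "mRNA",
                    strand = gene_df$strand, start = gene_df$start,
                    end = gene_df$end)
  else gene_annotation(character(0), character(0), character(0),
                       integer(0), integer(0))
  edit_truth <- NULL
  if (!is.null(cfg$edit_plan) && nrow(cfg$edit_plan)) {
    ep <- cfg$edit_plan
    fr <- if ("fraction" %in% names(ep)) ep$fraction
          else rep(cfg$read_profile$edit_fraction, nrow(ep))
    edit_truth <- data.frame(gene = ep$gene, codon_index = ep$codon_index,
                             codon_pos = ep$codon_pos,
                             cds_pos = (ep$codon_index - 1L) * 3L + ep$codon_pos,
                             fraction = fr, stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    seed = cfg$seed, genome_length = nchar(genome),
    gc_target = cfg$gc_target,
    genes = gene_df, ssrs = ssr_truth, tandems = tand_truth,
    dispersed = disp_truth, edits = edit_truth,
    transfers = NULL, read_origins = NULL, homologs = NULL),
    class = "synthetic_truth")
  list(genome = seq_record("mito_synth", genome, circular = TRUE),
       annotation = ann, cds = cds, truth = truth)
}

#' Simulate long DNA reads and RNA reads
#'
#' Long reads are sampled uniformly from the circular genome (wrap-around
#' allowed, random strand) plus labelled contaminant reads drawn from
#' independent random nuclear and plastid decoy sequences. RNA reads are
#' sampled from the sense strand of each reference CDS with planted C-to-T
#' substitutions at the truth's editing sites at their planted fractions.
#'
#' @param genome [seq_record()] from [generate_genome()].
#' @param truth the matching `synthetic_truth` (supplies edit sites; read
#'   origin labels are appended to the returned truth).
#' @param cds named vector of reference CDS (required for RNA reads).
#' @param profile read profile (see [generator_config()]).
#' @param seed RNG seed.
#' @return list: `dna_reads`, `rna_reads` (named character vectors),
#'   `dna_truth` (read_id, origin, start, length, strand), `rna_truth`
#'   (read_id, gene, start), updated `truth`.
#' @export
generate_reads <- function(genome, truth, cds = NULL,
                           profile = default_read_profile(), seed = 1L) {
  stopifnot(seq_len_bp(genome) > 0L, profile$depth > 0)
  with_seed(seed, {
    L <- seq_len_bp(genome)
    doubled <- paste0(genome$seq, genome$seq)
    n_mito <- ceiling(profile$depth * L / profile$mean_len)
    f <- profile$contaminant_fraction
    n_cont <- if (f > 0) round(n_mito * f / (1 - f)) else 0L
    draw_len <- function(n) {
      l <- round(rnorm(n, profile$mean_len, profile$sd_len))
      pmin(pmax(l, profile$min_len), L)
    }
    mut <- function(s, rate) {
      if (rate <= 0) return(s)
      ch <- strsplit(s, "")[[1]]
      hit <- runif(length(ch)) < rate
      if (any(hit))
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
      paste(ch, collapse = "")
    }
    lens <- draw_len(n_mito)
    starts <- sample.int(L, n_mito, replace = TRUE)
    strands <- sample(c("+", "-"), n_mito, replace = TRUE)
    dna <- character(0); origin <- character(0)
    rstart <- integer(0); rlen <- integer(0); rstrand <- character(0)
    for (i in seq_len(n_mito)) {
      s <- substr(doubled, starts[i], starts[i] + lens[i] - 1L)
      if (strands[i] == "-") s <- revcomp(s)
      dna <- c(dna, mut(s, profile$error_rate))
      origin <- c(origin, "mito")
      rstart <- c(rstart, starts[i]); rlen <- c(rlen, lens[i])
      rstrand <- c(rstrand, strands[i])
    }
    if (n_cont > 0) {
      nuc <- rand_dna(L, 0.40)
      pla <- rand_dna(max(20000L, L %/% 2L), 0.37)
      srcs <- sample(c("nuclear", "plastid"), n_cont, replace = TRUE)
      clens <- draw_len(n_cont)
      for (i in seq_len(n_cont)) {
        src <- if (srcs[i] == "nuclear") nuc else pla
        maxs <- nchar(src) - clens[i] + 1L
        st <- sample.int(max(1L, maxs), 1L)
        s <- substr(src, st, st + clens[i] - 1L)
        if (sample(c(TRUE, FALSE), 1L)) s <- revcomp(s)
        dna <- c(dna, mut(s, profile$error_rate))
        origin <- c(origin, srcs[i])
        rstart <- c(rstart, NA_integer_); rlen <- c(rlen, clens[i])
        rstrand <- c(rstrand, NA_character_)
      }
    }
    ord <- sample(seq_along(dna))
    dna <- dna[ord]; origin <- origin[ord]
    rstart <- rstart[ord]; rlen <- rlen[ord]; rstrand <- rstrand[ord]
    names(dna) <- sprintf("read_%05d", seq_along(dna))
    dna_truth <- data.frame(read_id = names(dna), origin = origin,
                            start = rstart, length = rlen,
                            strand = rstrand, stringsAsFactors = FALSE)
    rna <- character(0)
    rna_truth <- data.frame(read_id = character(0), gene = character(0),
                            start = integer(0), stringsAsFactors = FALSE)
    if (!is.null(cds) && length(cds)) {
      rl <- profile$rna_read_len
      edits <- truth$edits
      rid <- 0L
      for (g in names(cds)) {
        cl <- nchar(cds[[g]])
        this_rl <- min(rl, cl)
        n <- ceiling(profile$rna_depth * cl / this_rl)
        sts <- sample.int(cl - this_rl + 1L, n, replace = TRUE)
        ge <- if (!is.null(edits)) edits[edits$gene == g, , drop = FALSE]
              else NULL
        for (s in sts) {
          rid <- rid + 1L
          rd <- substr(cds[[g]], s, s + this_rl - 1L)
          if (!is.null(ge) && nrow(ge)) {
            cover <- which(ge$cds_pos >= s & ge$cds_pos <= s + this_rl - 1L)
            for (j in cover) {
              if (runif(1) < ge$fraction[j]) {
                off <- ge$cds_pos[j] - s + 1L
                substr(rd, off, off) <- "T"
              }
            }
          }
          rd <- mut(rd, profile$error_rate)
          nm <- sprintf("rna_%05d", rid)
          rna[nm] <- rd
          rna_truth <- rbind(rna_truth,
                             data.frame(read_id = nm, gene = g, start = s,
                                        stringsAsFactors = FALSE))
        }
      }
    }
    truth$read_origins <- dna_truth
    list(dna_reads = dna, rna_reads = rna, dna_truth = dna_truth,
         rna_truth = rna_truth, truth = truth)
  })
}

# invert the Kimura-2P distance for uniform substitution choice
# (ts:tv = 1:2): returns the per-site substitution probability giving the
# requested expected distance
invert_k2p_uniform <- function(d) {
  if (d <= 0) return(0)
  f <- function(p) {
    P <- p / 3; Q <- 2 * p / 3
    (0.5 * log(1 / (1 - 2 * P - Q)) - 0.25 * log(1 / (1 - 2 * Q))) +
      0.5 * log(1 / (1 - 2 * Q)) - d
  }
  uniroot(f, c(1e-9, 0.74))$root
}

#' Generate a homolog set with controlled divergence
#'
#' Each planned "species" is a mutated copy of the input CDS produced by
#' codon-aware substitution: synonymous changes are planted at four-fold
#' degenerate third positions and nonsynonymous changes at nondegenerate
#' sites, with per-site substitution probabilities chosen so the LWL-style
#' estimator's expected Ks and Ka equal the plan (multiple-hit corrected).
#' Substitutions that would create a stop codon are resampled.
#'
#' @param cds in-frame coding sequence (no internal stops).
#' @param divergence_plan data.frame(`species`, `ks`, `ka`).
#' @param seed RNG seed.
#' @return list: `sequences` (named vector, input first as `ref`), `truth`
#'   data.frame (species, target Ks/Ka, realized substitution counts and
#'   per-class site totals).
#' @export
generate_homolog_set <- function(cds, divergence_plan, seed = 1L) {
  stopifnot(nchar(cds) %% 3L == 0L)
  aa <- codon_to_aa(split_codons(cds))
  if (any(aa[-length(aa)] == "*")) stop("internal stop in input CDS")
  if (any(divergence_plan$ks > 0.75) || any(divergence_plan$ka > 0.75))
    stop("range error: requested divergence saturates the site class")
  with_seed(seed, {
    cods <- split_codons(cds)
    has_stop <- aa[length(aa)] == "*"
    body_idx <- if (has_stop) seq_len(length(cods) - 1L) else seq_along(cods)
    # site classification on the reference
    L <- c(`0` = 0, `2s` = 0, `2v` = 0, `4` = 0)
    four_sites <- list(); zero_sites <- list()
    for (i in body_idx) {
      row <- degeneracy_table()[[cods[i]]]
      for (p in 1:3) {
        e <- row[[p]]
        key <- if (e$fold == 2L) e$subtype else as.character(e$fold)
        L[key] <- L[key] + 1
        if (e$fold == 4L) four_sites[[length(four_sites) + 1L]] <- c(i, p)
        if (e$fold == 0L) zero_sites[[length(zero_sites) + 1L]] <- c(i, p)
      }
    }
    L0 <- L[["0"]]; L2 <- L[["2s"]] + L[["2v"]]; L4 <- L[["4"]]
    out <- character(0); rows <- list()
    for (r in seq_len(nrow(divergence_plan))) {
      ks <- divergence_plan$ks[r]; ka <- divergence_plan$ka[r]
      K4 <- if (L4 > 0) ks * (L2 / 3 + L4) / L4 else 0
      K0 <- if (L0 > 0) ka * (L0 + 2 * L2 / 3) / L0 else 0
      if (K4 >= 0.75 || K0 >= 0.75)
        stop("range error: per-class divergence saturates (>0.75)")
      p4 <- invert_k2p_uniform(K4)
      p0 <- invert_k2p_uniform(K0)
      mut <- cods
      n_syn <- 0L; n_non <- 0L
      for (sp_ in four_sites) if (runif(1) < p4) {
        i <- sp_[1]; p <- sp_[2]
        b <- substr(mut[i], p, p)
        nb <- sample(setdiff(DNA_BASES, b), 1L)
        substr(mut[i], p, p) <- nb
        n_syn <- n_syn + 1L
      }
      for (sp_ in zero_sites) if (runif(1) < p0) {
        i <- sp_[1]; p <- sp_[2]
        b <- substr(mut[i], p, p)
        cand <- sample(setdiff(DNA_BASES, b))
        for (nb in cand) {
          trial <- mut[i]; substr(trial, p, p) <- nb
          if (codon_to_aa(trial) != "*") {
            mut[i] <- trial; n_non <- n_non + 1L
            break
          }
        }
      }
      sq <- paste(mut, collapse = "")
      nm <- divergence_plan$species[r]
      out[nm] <- sq
      rows[[r]] <- data.frame(species = nm, target_ks = ks, target_ka = ka,
                              n_syn_sub = n_syn, n_nonsyn_sub = n_non,
                              p_syn_site = p4, p_nonsyn_site = p0,
                              L0 = L0, L2 = unname(L2), L4 = unname(L4),
                              stringsAsFactors = FALSE)
    }
    list(sequences = c(ref = cds, out), truth = do.call(rbind, rows))
  })
}

#' Generate a plastid genome carrying mitochondrial transfer fragments
#'
#' @param mito mitochondrial [seq_record()].
#' @param transfer_plan data.frame(`length`, `identity`); lengths >= 30 bp,
#'   identities in \[0.5, 1\].
#' @param plastid_length plastid genome size.
#' @param gc plastid background GC.
#' @param seed RNG seed.
#' @return list: `plastid` [seq_record()], `truth` data.frame with donor
#'   (mt) and acceptor (cp) spans, planned and realized identity.
#' @export
generate_plastid_with_transfers <- function(mito, transfer_plan = NULL,
                                            plastid_length = 30000L,
                                            gc = 0.37, seed = 1L) {
  if (!is.null(transfer_plan) && nrow(transfer_plan)) {
    if (any(transfer_plan$length < 30)) stop("range error: transfer < 30 bp")
    if (any(transfer_plan$identity < 0.5))
      stop("range error: identity < 0.5 is undetectable by design thresholds")
  }
  with_seed(seed, {
    cp <- rand_dna(plastid_length, gc)
    truth <- NULL
    if (!is.null(transfer_plan) && nrow(transfer_plan)) {
      Lm <- seq_len_bp(mito); Lc <- plastid_length
      used_m <- cbind(start = integer(0), end = integer(0))
      used_c <- cbind(start = integer(0), end = integer(0))
      pick <- function(len, L, used) {
        for (try in 1:500) {
          s <- sample.int(L - len - 200L, 1L) + 100L
          if (!any(spans_overlap(s - 50L, s + len + 49L,
                                 used[, "start"], used[, "end"]))) return(s)
        }
        stop("capacity error: could not place transfer fragment")
      }
      rows <- list()
      for (r in seq_len(nrow(transfer_plan))) {
        len <- transfer_plan$length[r]; idt <- transfer_plan$identity[r]
        ms <- pick(len, Lm, used_m)
        used_m <- rbind(used_m, c(ms, ms + len - 1L))
        seg <- substr(mito$seq, ms, ms + len - 1L)
        n_mm <- 0L
        if (idt < 1) {
          ch <- strsplit(seg, "")[[1]]
          if (idt >= 0.7) {
            hit <- which(runif(len) < (1 - idt))
          } else {
            # deeply diverged fragments are degraded with a bounded clean
            # run (max 10 bp between mismatches): identity is uniform along
            # the fragment, modelling ancient divergence rather than a
            # mosaic of intact and shattered stretches
            hit <- integer(0)
            pos <- 0L
            repeat {
              gap <- min(stats::rgeom(1L, 1 - idt), 10L)
              pos <- pos + gap + 1L
              if (pos > len) break
              hit <- c(hit, pos)
            }
          }
          if (length(hit)) {
            ch[hit] <- vapply(ch[hit], function(b)
              sample(setdiff(DNA_BASES, b), 1L), "")
            n_mm <- length(hit)
          }
          seg <- paste(ch, collapse = "")
        }
        cs <- pick(len, Lc, used_c)
        used_c <- rbind(used_c, c(cs, cs + len - 1L))
        substr(cp, cs, cs + len - 1L) <- seg
        rows[[r]] <- data.frame(mt_start = ms, mt_end = ms + len - 1L,
                                cp_start = cs, cp_end = cs + len - 1L,
                                length = len, planned_identity = idt,
                                realized_identity = (len - n_mm) / len,
                                mismatches = n_mm, stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
    }
    list(plastid = seq_record("plastid_synth", cp, circular = TRUE),
         truth = truth)
  })
}

#' Serialize / restore a synthetic truth object
#'
#' Truth is written as JSON (full structure) plus BED files of planted
#' feature spans (0-based half-open, the BED convention).
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bed <- function(df, name, label_col) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    out <- data.frame(chrom = "mito_synth", start = df$start - 1L,
                      end = df$end, name = df[[label_col]])
    write.table(out, file.path(dir, paste0(name, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(truth$ssrs)) bed(truth$ssrs, "ssrs", "motif")
  if (!is.null(truth$tandems)) bed(truth$tandems, "tandems", "unit")
  if (!is.null(truth$genes)) bed(truth$genes, "genes", "gene")
  invisible(dir)
}

#' @param dir directory written by [write_truth()].
#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  for (nm in c("genes", "ssrs", "tandems", "dispersed", "edits",
               "transfers", "read_origins", "homologs"))
    if (!is.null(x[[nm]]) && !is.data.frame(x[[nm]]))
      x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  structure(x, class = "synthetic_truth")
}
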