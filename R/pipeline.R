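#' Run the full comparative-analysis pipeline over a configuration
#'
#' Orchestrates every stage over a config of input paths and parameter
#' blocks, writing per-stage TSV/JSON outputs and a consolidated JSON
#' report. Missing optional inputs skip their stage with an explicit log
#' entry. Reruns with the same config and seed produce identical reports.
#'
#' @param config list (see [pipeline_config()]).
#' @return the report list, invisibly; written to
#'   `file.path(out_dir, "report.json")`.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' Defaults are the conventional thresholds of the organelle workflow:
#' core-gene hit > 50 bp, recruitment overlap > 1 kb, ORF >= 102 bp, SSR
#' minima 1-10/2-5/3-4/4-3/5-3/6-3, tandem scoring 2/7/7 with score floor
#' 50 and max period 2000, dispersed repeats >= 30 bp at word size 7 and
#' E <= 1e-5, transfer detection E <= 1e-5 at identity >= 70%, shared-CDS
#' fraction 0.7.
#'
#' @param genome_fasta path to the assembled mitogenome FASTA (required).
#' @param annotation_gff3 optional GFF3 of gene models.
#' @param cds_fasta optional multi-FASTA of coding sequences.
#' @param dna_reads_fastq,core_genes_fasta optional read-baiting inputs.
#' @param rna_reads_fastq optional RNA reads for editing calls.
#' @param plastid_fasta optional plastid genome for transfer detection.
#' @param homolog_dir optional directory of per-gene multi-FASTA homolog
#'   sets for Ka/Ks and pi.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param params overrides for stage parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, annotation_gff3 = NULL,
                            cds_fasta = NULL, dna_reads_fastq = NULL,
                            core_genes_fasta = NULL, rna_reads_fastq = NULL,
                            plastid_fasta = NULL, homolog_dir = NULL,
                            out_dir = "mitokit_out", seed = 1L,
                            params = list()) {
  defaults <- list(min_hit = 50L, min_overlap = 1000L, orf_min_len = 102L,
                   ssr_min = MISA_DEFAULT_MIN,
                   tandem = list(match = 2, mismatch = 7, indel = 7,
                                 min_score = 50, max_period = 2000L),
                   dispersed = list(min_len = 30L, word_size = 7L,
                                    evalue = 1e-5),
                   transfer = list(evalue = 1e-5, min_identity = 70),
                   editing = list(min_depth = 5L, min_fraction = 0.1),
                   shared_cds = 0.7)
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(list(genome_fasta = genome_fasta,
                 annotation_gff3 = annotation_gff3, cds_fasta = cds_fasta,
                 dna_reads_fastq = dna_reads_fastq,
                 core_genes_fasta = core_genes_fasta,
                 rna_reads_fastq = rna_reads_fastq,
                 plastid_fasta = plastid_fasta, homolog_dir = homolog_dir,
                 out_dir = out_dir, seed = as.integer(seed),
                 params = defaults),
            class = "pipeline_config")
}

#' @param config a [pipeline_config()].
#' @rdname pipeline
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  if (!file.exists(config$genome_fasta))
    stop("genome FASTA not found: ", config$genome_fasta)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  loglines <- character(0)
  logmsg <- function(...) {
    line <- paste0(...)
    loglines <<- c(loglines, line)
    message(line)
  }
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(parameters = config$params, seed = config$seed,
                 stages = list())
  p <- config$params
  logmsg("mitokit pipeline; seed=", config$seed)

  genome <- read_fasta(config$genome_fasta, circular = TRUE)[[1]]
  comp <- base_composition(genome)
  report$genome_stats <- list(id = genome$id, length = comp$length,
                              gc = comp$gc,
                              base_fractions = as.list(comp$fractions))
  report$stages$composition <- "done"
  logmsg("composition: ", comp$length, " bp, GC ",
         sprintf("%.2f%%", 100 * comp$gc))

  orfs <- find_orfs(genome, min_len = p$orf_min_len)
  tsv(orfs, "orfs")
  report$stages$orfs <- "done"
  report$orf_count <- nrow(orfs)

  ssrs <- find_ssrs(genome$seq, min_repeats = p$ssr_min)
  tand <- find_tandem_repeats(genome$seq, match = p$tandem$match,
                              mismatch = p$tandem$mismatch,
                              indel = p$tandem$indel,
                              min_score = p$tandem$min_score,
                              max_period = p$tandem$max_period)
  disp <- find_dispersed_repeats(genome$seq,
                                 min_len = p$dispersed$min_len,
                                 word_size = p$dispersed$word_size,
                                 evalue = p$dispersed$evalue,
                                 exclude = rbind(ssrs[, c("start", "end")],
                                                 tand[, c("start", "end")]))
  tsv(ssrs, "ssrs"); tsv(tand, "tandem_repeats"); tsv(disp, "dispersed_repeats")
  rs <- repeat_summary(ssrs, tand, disp, comp$length)
  report$repeats <- list(ssr_total = rs$ssr$total,
                         ssr_classes = rs$ssr$table,
                         tandem_count = rs$tandem$count,
                         dispersed_count = rs$dispersed$count,
                         dispersed_bp = rs$dispersed$total_bp)
  report$stages$repeats <- "done"
  logmsg("repeats: ", rs$ssr$total, " SSRs, ", rs$tandem$count,
         " tandem, ", rs$dispersed$count, " dispersed")

  cds <- NULL
  if (!is.null(config$cds_fasta) && file.exists(config$cds_fasta)) {
    cds <- vapply(read_fasta(config$cds_fasta), function(r) r$seq, "")
    counts <- count_codons(cds)
    rscu <- compute_rscu(counts)
    rscu$rscu <- round(rscu$rscu, 2)
    tsv(rscu, "rscu")
    bias <- rscu_bias_summary(compute_rscu(counts))
    tsv(check_start_stop(cds), "start_stop")
    report$codon_usage <- list(total_codons = counts$total,
                               n_over_1 = bias$n_over_1,
                               third_base = bias$third_base)
    report$stages$codon_usage <- "done"
    logmsg("codon usage: ", counts$total, " codons, ",
           bias$n_over_1, " codons with RSCU > 1")
  } else {
    report$stages$codon_usage <- "skipped (no CDS input)"
    logmsg("codon usage: skipped (no CDS input)")
  }

  if (!is.null(config$rna_reads_fastq) && !is.null(cds) &&
      file.exists(config$rna_reads_fastq)) {
    rna <- read_fastq(config$rna_reads_fastq)
    sites <- call_editing_sites(rna, cds,
                                min_depth = p$editing$min_depth,
                                min_fraction = p$editing$min_fraction)
    tsv(sites, "editing_sites")
    if (nrow(sites)) {
      es <- editing_summary(sites)
      tsv(es$by_category, "editing_categories")
      report$editing <- list(total = es$total, by_category = es$by_category)
    } else report$editing <- list(total = 0L)
    report$stages$editing <- "done"
    logmsg("editing: ", nrow(sites), " sites called")
  } else {
    report$stages$editing <- "skipped (no RNA reads or no CDS)"
    logmsg("editing: skipped (no RNA reads or no CDS)")
  }

  if (!is.null(config$dna_reads_fastq) &&
      !is.null(config$core_genes_fasta) &&
      file.exists(config$dna_reads_fastq)) {
    reads <- read_fastq(config$dna_reads_fastq)
    core <- vapply(read_fasta(config$core_genes_fasta),
                   function(r) r$seq, "")
    seeds <- select_seed_reads(reads, core, min_hit = p$min_hit)
    bait <- recruit_reads_iterative(reads, seeds,
                                    min_overlap = p$min_overlap)
    write_fastq(reads[bait$recruited],
                file.path(config$out_dir, "recruited.fastq"))
    jsonlite::write_json(
      list(n_reads = length(reads), n_seeds = length(seeds$seeds),
           n_recruited = length(bait$recruited),
           iterations = bait$iterations,
           per_iteration = bait$per_iteration,
           converged = bait$converged),
      file.path(config$out_dir, "baiting.json"), auto_unbox = TRUE)
    report$baiting <- list(n_seeds = length(seeds$seeds),
                           n_recruited = length(bait$recruited),
                           iterations = bait$iterations)
    report$stages$baiting <- "done"
    logmsg("baiting: ", length(bait$recruited), "/", length(reads),
           " reads recruited in ", bait$iterations, " iterations")
  } else {
    report$stages$baiting <- "skipped (no reads or core genes)"
    logmsg("baiting: skipped (no reads or core genes)")
  }

  if (!is.null(config$homolog_dir) && dir.exists(config$homolog_dir)) {
    files <- list.files(config$homolog_dir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    kk <- list(); pp <- list()
    for (f in files) {
      gid <- sub("\\.fa(sta)?$", "", basename(f))
      seqs <- vapply(read_fasta(f), function(r) r$seq, "")
      if (length(seqs) < 2L) next
      for (j in 2:length(seqs)) {
        res <- try(compute_kaks(c(seqs[[1]], seqs[[j]]),
                                gene_id = paste0(gid, ":", names(seqs)[j])),
                   silent = TRUE)
        if (!inherits(res, "try-error")) kk[[length(kk) + 1L]] <- res
      }
      if (length(unique(nchar(seqs))) == 1L)
        pp[[length(pp) + 1L]] <- nucleotide_diversity(seqs, gene_id = gid)
    }
    if (length(kk)) tsv(do.call(rbind, kk), "kaks")
    if (length(pp)) tsv(do.call(rbind, pp), "pi")
    report$evolution <- list(n_kaks = length(kk), n_pi = length(pp))
    report$stages$evolution <- "done"
    logmsg("evolution: ", length(kk), " Ka/Ks pairs, ", length(pp),
           " pi genes")
  } else {
    report$stages$evolution <- "skipped (no homolog sets)"
    logmsg("evolution: skipped (no homolog sets)")
  }

  if (!is.null(config$plastid_fasta) && file.exists(config$plastid_fasta)) {
    cp <- read_fasta(config$plastid_fasta, circular = TRUE)[[1]]
    frags <- find_homologous_fragments(cp, genome,
                                       evalue = p$transfer$evalue,
                                       min_identity = p$transfer$min_identity)
    ann <- NULL
    if (!is.null(config$annotation_gff3) &&
        file.exists(config$annotation_gff3))
      ann <- read_gff3(config$annotation_gff3)
    frags <- assign_genes_to_fragments(frags, NULL, ann)
    tsv(frags, "transfer_fragments")
    fs <- fragment_summary(frags, cp_length = seq_len_bp(cp),
                           mt_length = comp$length)
    report$transfer <- fs
    report$stages$transfer <- "done"
    logmsg("transfer: ", fs$count, " fragments, ", fs$total_bp, " bp")
  } else {
    report$stages$transfer <- "skipped (no plastid genome)"
    logmsg("transfer: skipped (no plastid genome)")
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeLines(loglines, logfile)
  invisible(report)
}
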