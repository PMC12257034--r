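test_that("planted features appear verbatim at recorded coordinates", {
  plan <- data.frame(motif = "AT", copies = 6L, start = 1100L)
  cfg <- generator_config(seed = 51, genome_length = 8000, n_genes = 0,
                          ssr_plan = plan, tandem_plan = NULL,
                          dispersed_plan = NULL, transfer_plan = NULL)
  g <- generate_genome(cfg)
  expect_identical(substr(g$genome$seq, 1100, 1111), "ATATATATATAT")
  expect_equal(g$truth$ssrs$start, 1100L)
  expect_equal(g$truth$ssrs$end, 1111L)
  expect_true(g$genome$circular)
})

test_that("identical configuration gives byte-identical outputs", {
  cfg <- generator_config(seed = 52, genome_length = 9000, n_genes = 2)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$cds, g2$cds)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("truth lists exactly the planned number of SSRs", {
  motifs <- c("A", "T", "AG", "AT", "TC", "CT", "GA", "TA", "AAG", "CTT")
  plan <- data.frame(motif = rep(motifs, 5),
                     copies = rep(c(10L, 11L, 5L, 6L, 7L, 5L, 6L, 5L, 4L, 4L), 5),
                     start = NA_integer_)
  cfg <- generator_config(seed = 53, genome_length = 25000, n_genes = 0,
                          ssr_plan = plan, tandem_plan = NULL,
                          dispersed_plan = NULL, transfer_plan = NULL)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$truth$ssrs), 50L)
  expect_equal(nrow(find_ssrs(g$genome$seq)), 50L)
})

test_that("plan validation raises planning and capacity errors", {
  expect_error(generator_config(seed = 1, ssr_plan = data.frame(
    motif = "A", copies = 5L)), "class minimum")
  expect_error(generator_config(seed = 1, tandem_plan = data.frame(
    unit = "ACGTACGTAA", copies = 2L)), "score floor")
  expect_error(generator_config(seed = 1, genome_length = 5000,
                                n_genes = 10), "capacity")
  expect_error(generator_config(seed = 1, transfer_plan = data.frame(
    length = 100, identity = 0.4)), "range error")
  # explicit overlapping spans
  plan <- data.frame(motif = c("AT", "TC"), copies = c(6L, 6L),
                     start = c(1000L, 1005L))
  cfg <- generator_config(seed = 1, genome_length = 8000, n_genes = 0,
                          ssr_plan = plan, tandem_plan = NULL,
                          dispersed_plan = NULL, transfer_plan = NULL)
  expect_error(generate_genome(cfg), "overlaps")
})

test_that("read simulation respects origin labels, depth and edit fraction", {
  cfg <- generator_config(seed = 54, genome_length = 12000, n_genes = 2,
                          edit_plan = data.frame(gene = "gene01",
                                                 codon_index = 60,
                                                 codon_pos = 2,
                                                 fraction = 1.0))
  g <- generate_genome(cfg)

  prof <- default_read_profile()
  prof$contaminant_fraction <- 0
  prof$depth <- 10; prof$mean_len <- 1500; prof$sd_len <- 300
  rd <- generate_reads(g$genome, g$truth, cds = NULL, profile = prof,
                       seed = 2)
  expect_true(all(rd$dna_truth$origin == "mito"))

  # emitted bases within 10% of depth x genome length
  total <- sum(nchar(rd$dna_reads))
  expect_lt(abs(total - 10 * 12000) / (10 * 12000), 0.10)

  # fully edited site: every covering RNA read carries T
  prof$depth <- 0.1
  rd2 <- generate_reads(g$genome, g$truth, cds = g$cds, profile = prof,
                        seed = 3)
  pos <- g$truth$edits$cds_pos[1]
  cover <- rd2$rna_truth[rd2$rna_truth$gene == "gene01" &
                           rd2$rna_truth$start <= pos &
                           rd2$rna_truth$start + prof$rna_read_len - 1 >= pos, ]
  expect_gte(nrow(cover), 10)
  for (i in seq_len(nrow(cover))) {
    off <- pos - cover$start[i] + 1
    expect_identical(substr(rd2$rna_reads[[cover$read_id[i]]], off, off), "T")
  }
})

test_that("wrap-around long reads come from the circular genome", {
  cfg <- generator_config(seed = 55, genome_length = 10000, n_genes = 0,
                          ssr_plan = NULL, tandem_plan = NULL,
                          dispersed_plan = NULL, transfer_plan = NULL)
  g <- generate_genome(cfg)
  prof <- default_read_profile()
  prof$depth <- 6; prof$mean_len <- 2000; prof$sd_len <- 200
  rd <- generate_reads(g$genome, g$truth, profile = prof, seed = 9)
  doubled <- paste0(g$genome$seq, g$genome$seq)
  tr <- rd$dna_truth
  for (i in seq_len(nrow(tr))) {
    expected <- substr(doubled, tr$start[i], tr$start[i] + tr$length[i] - 1)
    got <- rd$dna_reads[[tr$read_id[i]]]
    if (tr$strand[i] == "-") got <- rc(got)
    expect_identical(got, expected)
  }
  expect_true(any(tr$start + tr$length - 1 > 10000))  # some reads wrap
})

test_that("homolog generation honours the divergence plan", {
  cds <- paste0("ATG", paste(random_sense_codons(400, seed = 56),
                             collapse = ""), "TAA")
  # zero divergence: identical copy
  h0 <- generate_homolog_set(cds, data.frame(species = "s", ks = 0, ka = 0),
                             seed = 1)
  expect_identical(h0$sequences[["s"]], cds)

  # synonymous-only: proteins identical, nucleotides not
  hs <- generate_homolog_set(cds, data.frame(species = "s", ks = 0.2, ka = 0),
                             seed = 2)
  p1 <- Biostrings::translate(Biostrings::DNAString(cds))
  p2 <- Biostrings::translate(Biostrings::DNAString(hs$sequences[["s"]]))
  expect_identical(as.character(p1), as.character(p2))
  expect_false(identical(hs$sequences[["s"]], cds))

  # realized substitution count within 3 SD of the binomial expectation
  tr <- hs$truth
  n4 <- tr$L4
  expected <- n4 * tr$p_syn_site
  expect_lt(abs(tr$n_syn_sub - expected),
            3 * sqrt(n4 * tr$p_syn_site * (1 - tr$p_syn_site)) + 1e-9)

  expect_error(generate_homolog_set(cds, data.frame(species = "s", ks = 0.9,
                                                    ka = 0)), "range error")
  bad <- paste0("ATG", "TAA", "AAA", "TAA")
  expect_error(generate_homolog_set(bad, data.frame(species = "s", ks = 0,
                                                    ka = 0)), "internal stop")
})

test_that("plastid transfers are planted at the planned identity", {
  cfg <- generator_config(seed = 57, genome_length = 15000, n_genes = 0,
                          ssr_plan = NULL, tandem_plan = NULL,
                          dispersed_plan = NULL, transfer_plan = NULL)
  g <- generate_genome(cfg)

  pl <- generate_plastid_with_transfers(
    g$genome, data.frame(length = 500, identity = 1.0), seed = 4)
  seg <- substr(g$genome$seq, pl$truth$mt_start, pl$truth$mt_end)
  expect_true(grepl(seg, pl$plastid$seq, fixed = TRUE))

  pl2 <- generate_plastid_with_transfers(
    g$genome, data.frame(length = 1000, identity = 0.85), seed = 5)
  mm <- pl2$truth$mismatches
  expect_lt(abs(mm - 1000 * 0.15), 3 * sqrt(1000 * 0.15 * 0.85) + 1e-9)

  # empty plan: no shared 30-mer between the genomes (exhaustive k-mer check)
  pl3 <- generate_plastid_with_transfers(g$genome, NULL, seed = 6,
                                         plastid_length = 15000)
  km <- function(s, k) {
    n <- nchar(s)
    unique(substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
  }
  expect_length(intersect(km(g$genome$seq, 30), km(pl3$plastid$seq, 30)), 0)

  expect_error(generate_plastid_with_transfers(
    g$genome, data.frame(length = 20, identity = 1)), "range error")
  expect_error(generate_plastid_with_transfers(
    g$genome, data.frame(length = 100, identity = 0.3)), "range error")
})

test_that("truth serialization round-trips", {
  b <- synth_bundle()
  d <- withr::local_tempdir()
  write_truth(b$truth, d)
  expect_true(file.exists(file.path(d, "truth.json")))
  expect_true(file.exists(file.path(d, "ssrs.bed")))
  back <- read_truth(d)
  expect_equal(back$genome_length, b$truth$genome_length)
  expect_equal(as.data.frame(back$ssrs), as.data.frame(b$truth$ssrs))
  expect_equal(as.data.frame(back$tandems), as.data.frame(b$truth$tandems))
  expect_equal(as.data.frame(back$genes), as.data.frame(b$truth$genes))
  expect_equal(as.data.frame(back$edits), as.data.frame(b$truth$edits))
})
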