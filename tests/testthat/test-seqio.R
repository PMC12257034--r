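test_that("FASTA IO round-trips and enforces the alphabet", {
  recs <- lapply(1:20, function(i)
    seq_record(paste0("s", i), rand_seq(80 + i, seed = i)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(unname(vapply(back, function(r) r$id, "")),
                   vapply(recs, function(r) r$id, ""))
  expect_identical(vapply(back, function(r) r$seq, ""),
                   setNames(vapply(recs, function(r) r$seq, ""),
                            vapply(recs, function(r) r$id, "")))

  expect_identical(seq_record("x", "acgt")$seq, "ACGT")
  expect_error(seq_record("x", "ACRT"), "invalid characters")
  expect_identical(seq_record("x", "ACRT", mask_invalid = TRUE)$seq, "ACNT")
})

test_that("FASTQ IO round-trips read sequences", {
  reads <- setNames(c("ACGTACGTAA", "TTTTGGGGCC"), c("r1", "r2"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_identical(read_fastq(f), reads)
})

test_that("base composition is exact, GC-correct and permutation-invariant", {
  expect_equal(base_composition(seq_record("g", "GGCC"))$gc, 1.0)
  expect_equal(base_composition(seq_record("a", "ATAT"))$gc, 0.0)
  expect_error(base_composition(seq_record("n", "NNNN")), "all N")

  s <- rand_seq(10000, seed = 3, gc = 0.4579)
  gc <- base_composition(seq_record("r", s))$gc
  expect_lt(abs(gc - 0.4579), 3 * sqrt(0.4579 * (1 - 0.4579) / 10000))

  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_identical(base_composition(seq_record("p", perm))$counts,
                   base_composition(seq_record("r", s))$counts)
})

test_that("extract_cds honours strand, exon order and the circular origin", {
  g <- seq_record("g", paste0("ATGAAA", rand_seq(200, seed = 4)),
                  circular = TRUE)
  ann <- gene_annotation("x", "mRNA", "+", 1, 6)
  expect_identical(as.character(extract_cds(g, ann)), "ATGAAA")
  ann_m <- gene_annotation("x", "mRNA", "-", 1, 6)
  expect_identical(as.character(extract_cds(g, ann_m)), rc("ATGAAA"))

  # two-exon gene crossing the origin equals the rotation-based extraction
  L <- nchar(g$seq)
  ann_c <- gene_annotation(rep("w", 2), "mRNA", "+",
                           start = c(L - 20, 40), end = c(30, 60),
                           exon_rank = 1:2)
  got <- as.character(extract_cds(g, ann_c))
  rot <- paste0(substr(g$seq, L - 20, L), substr(g$seq, 1, nchar(g$seq)))
  expect_identical(got, paste0(substr(rot, 1, 51), substr(rot, 21 + 40, 21 + 60)))
  # linear sequence rejects wrap-around exons
  lin <- seq_record("l", g$seq, circular = FALSE)
  expect_error(extract_cds(lin, ann_c), "wrap-around")
})

test_that("find_orfs applies the 102 bp floor and matches a direct-walk oracle", {
  s1 <- paste0("ATG", strrep("AAA", 33), "TAA")   # 105 bp
  r1 <- find_orfs(seq_record("x", s1))
  expect_true(any(r1$length == 105 & r1$strand == "+" & r1$start == 1))
  s2 <- paste0("ATG", strrep("AAA", 32), "TAA")   # 102 bp: kept at boundary
  r2 <- find_orfs(seq_record("x", s2))
  expect_true(any(r2$length == 102))
  s3 <- paste0("ATG", strrep("AAA", 31), "TAA")   # 99 bp: below floor
  expect_false(any(find_orfs(seq_record("x", s3))$length == 99))
  expect_error(find_orfs(seq_record("x", s1), min_len = 100), "%%")

  for (sd in 1:2) {
    s <- rand_seq(20000, seed = 20 + sd)
    got <- find_orfs(seq_record("x", s))
    exp <- orf_oracle(s)
    expect_equal(got[, c("start", "end", "strand")],
                 exp[, c("start", "end", "strand")],
                 ignore_attr = TRUE)
  }
})

test_that("GFF3 writer and reader are mutual inverses on gene models", {
  ann <- gene_annotation(gene_id = c("a", "a", "b"),
                         feature_type = c("mRNA", "mRNA", "tRNA"),
                         strand = c("+", "+", "-"),
                         start = c(10, 100, 500), end = c(50, 160, 570),
                         exon_rank = c(1, 2, 1))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, "chr", f)
  back <- read_gff3(f)
  o <- order(back$gene_id, back$exon_rank)
  expect_equal(back$start[o], ann$start)
  expect_equal(back$end[o], ann$end)
  expect_equal(back$strand[o], ann$strand)
  expect_equal(back$feature_type[o], ann$feature_type)
})

test_that("transfer_annotation recovers planted genes and skips absent ones", {
  set.seed(9)
  bg <- rand_seq(12000, seed = 9)
  gene <- rand_seq(900, seed = 10)
  genome <- seq_record("t", paste0(substr(bg, 1, 4000), gene,
                                   substr(bg, 4001, 12000)))
  refs <- list(seq_record("geneA", gene), seq_record("geneB", rand_seq(800, 77)))
  ann <- transfer_annotation(genome, refs)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$gene_id, "geneA")
  expect_equal(c(ann$start, ann$end), c(4001, 4900))
  expect_equal(ann$identity, 1)

  # 85% identity copy recovered with identity within 2 points of planted
  ch <- strsplit(gene, "")[[1]]
  mut <- sample(900, 135)
  ch[mut] <- vapply(ch[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  genome2 <- seq_record("t2", paste0(substr(bg, 1, 4000),
                                     paste(ch, collapse = ""),
                                     substr(bg, 4001, 12000)))
  ann2 <- transfer_annotation(genome2, refs[1])
  expect_equal(nrow(ann2), 1L)
  expect_lt(abs(ann2$identity - 0.85), 0.02)
})
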