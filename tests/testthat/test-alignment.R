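test_that("k-mer index stores verified positions and masks repeats", {
  r <- seq_record("x", "ACGTACGTACGT")
  idx <- build_index(r, k = 7)
  hit <- index_lookup(idx, "ACGTACG")
  expect_equal(sort(hit$pos), c(1, 5))

  polyA <- seq_record("a", strrep("A", 300))
  idx2 <- build_index(polyA, k = 7, occ_cap = 10)
  expect_equal(nrow(index_lookup(idx2, strrep("A", 7))), 0L)

  s <- rand_seq(10000, seed = 5)
  idx3 <- build_index(seq_record("g", s), k = 11)
  set.seed(6)
  probe <- sample(10000 - 10, 50)
  for (p in probe) {
    km <- substr(s, p, p + 10)
    found <- index_lookup(idx3, km)
    expect_true(all(substring(s, found$pos, found$pos + 10) == km))
    expect_true(p %in% found$pos)
  }

  expect_error(build_index(r, k = 6), "7..21")
  expect_error(build_index(seq_record("t", "ACGT"), k = 11), "larger")
})

test_that("local_align finds exact, reverse-complement and degraded hits", {
  s <- rand_seq(20000, seed = 7)
  t <- seq_record("t", s)
  idx <- build_index(t, k = 11)

  h <- local_align(substr(s, 1001, 1200), idx)
  expect_equal(h$identity[1], 1)
  expect_equal(h$aligned_length[1], 200)
  expect_equal(c(h$t_start[1], h$t_end[1]), c(1001, 1200))
  expect_equal(h$strand[1], "+")

  h2 <- local_align(rc(substr(s, 2001, 2300)), idx)
  expect_equal(h2$strand[1], "-")
  expect_equal(c(h2$t_start[1], h2$t_end[1]), c(2001, 2300))
  expect_equal(h2$identity[1], 1)

  set.seed(8)
  q <- strsplit(substr(s, 5001, 5500), "")[[1]]
  mut <- sample(500, 50)
  q[mut] <- vapply(q[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  h3 <- local_align(paste(q, collapse = ""), idx, min_score = 50)
  expect_lt(abs(h3$identity[1] - 0.90), 0.02)
})

test_that("alignment is symmetric and scores are bounded", {
  a <- rand_seq(3000, seed = 11)
  b <- paste0(rand_seq(800, seed = 12), substr(a, 1001, 1600),
              rand_seq(700, seed = 13))
  hab <- local_align(a, build_index(seq_record("b", b), k = 11),
                     query_id = "a")
  hba <- local_align(b, build_index(seq_record("a", a), k = 11),
                     query_id = "b")
  expect_equal(hab$score[1], hba$score[1])
  expect_equal(c(hab$q_start[1], hab$q_end[1]),
               c(hba$t_start[1], hba$t_end[1]))
  expect_equal(c(hab$t_start[1], hab$t_end[1]),
               c(hba$q_start[1], hba$q_end[1]))
  expect_true(all(hab$score <= hab$aligned_length * 1))
})

test_that("any shared exact substring of length >= 2k-1 produces a hit", {
  set.seed(14)
  for (i in 1:5) {
    t <- rand_seq(4000, seed = 30 + i)
    core <- substr(t, 2000, 2000 + 20)   # 21 = 2*11 - 1
    q <- paste0(rand_seq(150, seed = 60 + i), core,
                rand_seq(150, seed = 90 + i))
    h <- local_align(q, build_index(seq_record("t", t), k = 11),
                     min_score = 15)
    expect_gte(nrow(h), 1)
    expect_true(any(h$t_start <= 2000 & h$t_end >= 2020))
  }
})

test_that("pileup counts covering bases per target column", {
  cds <- c(gene = rand_seq(600, seed = 15))
  idx <- build_index(cds, k = 11)
  reads <- setNames(rep(substr(cds[["gene"]], 101, 250), 5),
                    paste0("r", 1:5))
  hits <- do.call(rbind, lapply(names(reads), function(n)
    local_align(reads[[n]], idx, traceback = TRUE, query_id = n)))
  p <- pileup(hits, cds)
  expect_equal(nrow(p), 150)
  expect_true(all(p$depth == 5))
  refs <- strsplit(substr(cds[["gene"]], 101, 250), "")[[1]]
  for (b in c("A", "C", "G", "T"))
    expect_equal(p[[b]], ifelse(refs == b, 5L, 0L))
  expect_false(100 %in% p$pos)   # uncovered positions are absent

  # planted alternate allele at known fraction: binomial oracle bound
  set.seed(16)
  depth <- 20
  off <- which(refs == "C")[5]           # a mid-read reference C
  alt_reads <- lapply(1:depth, function(i) {
    r <- substr(cds[["gene"]], 101, 250)
    if (i <= 10) substr(r, off, off) <- "T"   # planted fraction 0.5
    r
  })
  names(alt_reads) <- paste0("a", 1:depth)
  hits2 <- do.call(rbind, lapply(names(alt_reads), function(n)
    local_align(alt_reads[[n]], idx, traceback = TRUE, query_id = n)))
  p2 <- pileup(hits2, cds)
  row <- p2[p2$pos == 100 + off, ]
  expect_equal(row$depth, depth)
  expect_equal(row$T + row$C, depth)
  expect_lt(abs(row$T - depth * 0.5), 3 * sqrt(depth * 0.25) + 1e-9)
})

test_that("hits export in outfmt-6 shape", {
  s <- rand_seq(5000, seed = 17)
  h <- local_align(substr(s, 101, 400),
                   build_index(seq_record("t", s), k = 11))
  tab <- hits_to_outfmt6(h)
  expect_named(tab, c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore"))
  expect_equal(tab$pident[1], 100)
})
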