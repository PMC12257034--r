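test_that("site degeneracy matches genetic-code facts and an exhaustive oracle", {
  expect_equal(as.character(classify_site_degeneracy("GGG", 3)), "4-fold")
  expect_equal(as.character(classify_site_degeneracy("ATG", 1)), "0-fold")
  expect_equal(as.character(classify_site_degeneracy("ATG", 2)), "0-fold")
  expect_equal(as.character(classify_site_degeneracy("TTT", 3)), "2-fold")
  expect_error(classify_site_degeneracy("TAA", 1), "stop")

  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  for (cod in sense) for (p in 1:3) {
    syn <- 0
    for (nb in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
      m <- cod; substr(m, p, p) <- nb
      if (gc_map[[m]] == gc_map[[cod]]) syn <- syn + 1
    }
    want <- if (syn == 0) "0-fold" else if (syn == 3) "4-fold" else "2-fold"
    expect_equal(as.character(classify_site_degeneracy(cod, p)), want)
  }
  # transversional two-fold sites: the classic Arg/Ile cases
  expect_equal(attr(classify_site_degeneracy("AGA", 1), "subtype"), "2v")
  expect_equal(attr(classify_site_degeneracy("ATA", 3), "subtype"), "2v")
  expect_equal(attr(classify_site_degeneracy("TTT", 3), "subtype"), "2s")
})

test_that("Ka/Ks basics: zero on identical input, synonymous-only, symmetry", {
  cods <- random_sense_codons(120, seed = 61)
  a <- paste(cods, collapse = "")
  r0 <- compute_kaks(c(a, a))
  expect_equal(c(r0$Ka, r0$Ks), c(0, 0))
  expect_true(is.na(r0$ratio))

  i <- which(substr(cods, 1, 2) == "GG")[1]   # Gly: 4-fold third position
  b <- a
  pos <- i * 3
  substr(b, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, pos, pos))[1]
  r1 <- compute_kaks(c(a, b))
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)

  set.seed(62)
  bb <- strsplit(a, "")[[1]]
  mut <- sample(length(bb), 15)
  bb[mut] <- vapply(bb[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  b2 <- paste(bb, collapse = "")
  f <- compute_kaks(codon_align(a, b2))
  r <- compute_kaks(codon_align(b2, a))
  expect_lt(abs(f$Ka - r$Ka), 1e-12)
  expect_lt(abs(f$Ks - r$Ks), 1e-12)
  expect_error(compute_kaks(c("ATGAAA", "ATGAAA")), "10 gap-free")
})

test_that("LWL bookkeeping equals an independent pathway-enumeration oracle", {
  for (sd in 1:12) {
    n <- sample(15:30, 1)
    ca <- random_sense_codons(n, seed = 300 + sd)
    set.seed(400 + sd)
    cb <- ca
    nmut <- sample(2:6, 1)
    for (j in sample(n, nmut)) {
      repeat {
        cod <- cb[j]
        p <- sample(3, 1)
        nb <- sample(setdiff(c("A", "C", "G", "T"), substr(cod, p, p)), 1)
        substr(cod, p, p) <- nb
        if (Biostrings::GENETIC_CODE[[cod]] != "*") { cb[j] <- cod; break }
      }
    }
    aln <- structure(list(codons_a = ca, codons_b = cb, n_codons = n),
                     class = "codon_alignment")
    got <- compute_kaks(aln, method = "LWL")
    ora <- lwl_oracle(ca, cb)
    expect_equal(got$L0, ora$L[["0"]], tolerance = 1e-9)
    expect_equal(got$L2, ora$L[["2"]], tolerance = 1e-9)
    expect_equal(got$L4, ora$L[["4"]], tolerance = 1e-9)
    expect_equal(got$ts_total, sum(unlist(ora$S)), tolerance = 1e-9)
    expect_equal(got$tv_total, sum(unlist(ora$V)), tolerance = 1e-9)
    if (!got$saturated && !is.na(ora$Ka) && !is.na(ora$Ks)) {
      expect_equal(got$Ka, ora$Ka, tolerance = 1e-9)
      expect_equal(got$Ks, ora$Ks, tolerance = 1e-9)
    }
  }
})

test_that("MLWL collapses to LWL without transversional 2-fold sites at R = 0.5", {
  # codons free of transversional two-fold sites, checked programmatically
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  no2v <- Filter(function(cod) {
    !any(vapply(1:3, function(p)
      identical(attr(classify_site_degeneracy(cod, p), "subtype"), "2v"),
      TRUE))
  }, sense)
  set.seed(63)
  ca <- sample(no2v, 60, replace = TRUE)
  four <- which(vapply(ca, function(cod)
    as.character(classify_site_degeneracy(cod, 3)) == "4-fold", TRUE))
  cb <- ca
  # one transition and two transversions at 4-fold sites: R = 0.5
  tsmap <- c(A = "G", G = "A", C = "T", T = "C")
  tvmap <- c(A = "C", G = "C", C = "A", T = "A")
  j <- four[1:3]
  substr(cb[j[1]], 3, 3) <- tsmap[[substr(ca[j[1]], 3, 3)]]
  substr(cb[j[2]], 3, 3) <- tvmap[[substr(ca[j[2]], 3, 3)]]
  substr(cb[j[3]], 3, 3) <- tvmap[[substr(ca[j[3]], 3, 3)]]
  aln <- structure(list(codons_a = ca, codons_b = cb, n_codons = 60),
                   class = "codon_alignment")
  lwl <- compute_kaks(aln, method = "LWL")
  mlwl <- compute_kaks(aln, method = "MLWL")
  expect_equal(mlwl$Ks, lwl$Ks, tolerance = 1e-12)
  expect_equal(mlwl$Ka, lwl$Ka, tolerance = 1e-12)
})

test_that("estimator recovers planted divergence within 20% on a 10 kb CDS", {
  cds <- paste0("ATG", paste(random_sense_codons(3331, seed = 64),
                             collapse = ""), "TAA")
  h <- generate_homolog_set(cds, data.frame(species = "s", ks = 0.2,
                                            ka = 0.02), seed = 65)
  r <- compute_kaks(c(h$sequences[["ref"]], h$sequences[["s"]]))
  expect_lt(abs(r$Ks - 0.2) / 0.2, 0.20)
  expect_lt(abs(r$Ka - 0.02) / 0.02, 0.20)
  expect_lt(r$ratio, 1)   # purifying by construction
})

test_that("pi matches closed forms, brute force, and ape's estimator", {
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAC"))$pi, 0)
  s <- strrep("A", 100)
  s2 <- paste0(strrep("A", 99), "C")
  expect_equal(nucleotide_diversity(c(s, s2))$pi, 0.01)
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
  expect_error(nucleotide_diversity(c("ACGT", "ACG")), "equal length")

  set.seed(66)
  seqs <- vapply(1:5, function(i) rand_seq(200, seed = 70 + i), "")
  got <- nucleotide_diversity(seqs)$pi
  # hand pairwise average
  d <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    d <- d + mean(a != b)
  }
  expect_equal(got, d / 10, tolerance = 1e-12)

  skip_if_not_installed("ape")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  dd <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  expect_equal(got, mean(dd), tolerance = 1e-12)

  # order and column-permutation invariance
  expect_equal(nucleotide_diversity(rev(seqs))$pi, got)
  perm <- sample(200)
  seqs_p <- vapply(seqs, function(x)
    paste(strsplit(x, "")[[1]][perm], collapse = ""), "")
  expect_equal(nucleotide_diversity(unname(seqs_p))$pi, got)

  # pairwise gap deletion
  g1 <- "AC-TAC"
  g2 <- "ACGTAC"
  expect_equal(nucleotide_diversity(c(g1, g2))$pi, 0)
})

test_that("shared-CDS selection applies the 70% species threshold", {
  m <- matrix(0, nrow = 3, ncol = 25,
              dimnames = list(c("atp6", "nad1", "rps3"), NULL))
  m["atp6", 1:18] <- 1   # 72%
  m["nad1", 1:17] <- 1   # 68%
  m["rps3", ] <- 1
  expect_equal(shared_cds_selection(m), c("atp6", "rps3"))
  all1 <- matrix(1, 4, 10,
                 dimnames = list(c("d", "a", "c", "b"), NULL))
  expect_equal(shared_cds_selection(all1), c("a", "b", "c", "d"))
  expect_error(shared_cds_selection(matrix(numeric(0), 0, 0)))
})
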