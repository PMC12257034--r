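# Shared fixtures (memoised: built once per test run) and small utilities.

.fx <- new.env(parent = emptyenv())

rand_seq <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc <- function(x) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(x, "")[[1]]), collapse = ""))

spans_overlap_t <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# one synthetic study bundle shared by repeat/editing/transfer tests
synth_bundle <- function() {
  if (!is.null(.fx$bundle)) return(.fx$bundle)
  ep <- data.frame(gene = rep(sprintf("gene%02d", 1:4), each = 4),
                   codon_index = rep(c(60, 75, 90, 110), 4),
                   codon_pos = rep(c(2, 1, 2, 1), 4),
                   fraction = rep(c(0.9, 0.5, 1.0, 0.7), 4))
  cfg <- generator_config(seed = 101, genome_length = 22000, n_genes = 4,
                          gene_length_range = c(600, 900), edit_plan = ep)
  g <- generate_genome(cfg)
  .fx$bundle <- c(g, list(config = cfg))
  .fx$bundle
}

# --- independent oracles -----------------------------------------------------

# brute-force regex SSR scan (MISA semantics): all primitive motifs of unit
# 1-6, maximal regex matches, earliest phase kept among overlapping calls
ssr_oracle <- function(seq, min_repeats = c(`1` = 10, `2` = 5, `3` = 4,
                                            `4` = 3, `5` = 3, `6` = 3)) {
  n <- nchar(seq)
  prim <- function(m) {
    u <- nchar(m)
    if (u == 1) return(TRUE)
    for (d in seq_len(u - 1)) {
      if (u %% d) next
      if (strrep(substr(m, 1, d), u / d) == m) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (u in 1:6) {
    minrep <- min_repeats[[as.character(u)]]
    if (n < u * minrep) next
    # candidate motifs: u-mers that start at least one adjacent repetition
    starts <- seq_len(n - 2 * u + 1)
    cand <- unique(substring(seq, starts, starts + u - 1)[
      substring(seq, starts, starts + u - 1) ==
        substring(seq, starts + u, starts + 2 * u - 1)])
    cand <- cand[!grepl("N", cand) & vapply(cand, prim, TRUE)]
    rows <- list()
    for (m in cand) {
      g <- gregexpr(paste0("(?:", m, "){", minrep, ",}"), seq)[[1]]
      if (g[1] == -1) next
      len <- attr(g, "match.length")
      for (i in seq_along(g)) {
        copies <- len[i] %/% u
        rows[[length(rows) + 1]] <- data.frame(
          motif = m, unit_length = u, repeat_count = copies,
          start = as.integer(g[i]),
          end = as.integer(g[i]) + copies * u - 1,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df <- df[order(df$start, -df$repeat_count), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(df)) > i)
      ov <- df$start[later] <= df$end[i] & df$end[later] >= df$start[i]
      keep[later[ov]] <- FALSE
    }
    out[[length(out) + 1]] <- df[keep, , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(motif = character(0), unit_length = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# direct-walk ORF oracle: from every ATG, step codons to the first stop
orf_oracle <- function(seq, min_len = 102) {
  scan1 <- function(s, strand, n_fwd) {
    n <- nchar(s)
    res <- list()
    atg <- unlist(gregexpr("ATG", s, fixed = TRUE))
    atg <- atg[atg > 0]
    for (a in atg) {
      p <- a
      repeat {
        if (p + 2 > n) break
        cod <- substr(s, p, p + 2)
        if (cod %in% c("TAA", "TAG", "TGA") && p > a) {
          len <- p + 2 - a + 1
          if (len >= min_len) {
            if (strand == "+")
              res[[length(res) + 1]] <- c(a, p + 2)
            else
              res[[length(res) + 1]] <- c(n_fwd - (p + 2) + 1, n_fwd - a + 1)
          }
          break
        }
        p <- p + 3
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    data.frame(start = m[, 1], end = m[, 2], strand = strand)
  }
  n <- nchar(seq)
  out <- rbind(scan1(seq, "+", n), scan1(rc(seq), "-", n))
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0)))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# independent LWL bookkeeping: site classes, pathway-averaged transition /
# transversion counts, and the LWL Ka/Ks composition, written from scratch
lwl_oracle <- function(codons_a, codons_b) {
  gc <- Biostrings::GENETIC_CODE
  aa <- function(cod) unname(gc[cod])
  bases <- c("A", "C", "G", "T")
  is_ts <- function(x, y) {
    pur <- c("A", "G")
    ((x %in% pur) == (y %in% pur)) && x != y
  }
  site_class <- function(cod, p) {
    b <- substr(cod, p, p)
    syn <- 0
    for (nb in setdiff(bases, b)) {
      m <- cod
      substr(m, p, p) <- nb
      if (aa(m) == aa(cod)) syn <- syn + 1
    }
    if (syn == 0) "0" else if (syn == 3) "4" else "2"
  }
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  S <- L; V <- L
  perms_of <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (rest in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
    out
  }
  for (i in seq_along(codons_a)) {
    c1 <- codons_a[i]; c2 <- codons_b[i]
    for (p in 1:3)
      L[[site_class(c1, p)]] <- L[[site_class(c1, p)]] + 0.5
    for (p in 1:3)
      L[[site_class(c2, p)]] <- L[[site_class(c2, p)]] + 0.5
    dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dif)) next
    paths <- perms_of(dif)
    ok <- vapply(paths, function(pp) {
      cur <- c1
      for (p in pp) {
        substr(cur, p, p) <- substr(c2, p, p)
        if (aa(cur) == "*") return(FALSE)
      }
      TRUE
    }, TRUE)
    use <- if (any(ok)) paths[ok] else paths
    w <- 1 / length(use)
    for (pp in use) {
      cur <- c1
      for (p in pp) {
        from <- substr(cur, p, p); to <- substr(c2, p, p)
        cls <- c(site_class(c1, p), site_class(c2, p))
        for (cl in cls) {
          if (is_ts(from, to)) S[[cl]] <- S[[cl]] + 0.5 * w
          else V[[cl]] <- V[[cl]] + 0.5 * w
        }
        substr(cur, p, p) <- to
      }
    }
  }
  k2p <- function(P, Q) {
    a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) return(c(NA_real_, NA_real_))
    c(0.5 * log(1 / a1) - 0.25 * log(1 / a2), 0.5 * log(1 / a2))
  }
  AB <- lapply(c("0", "2", "4"), function(cl) {
    if (L[[cl]] == 0) return(c(0, 0))
    k2p(S[[cl]] / L[[cl]], V[[cl]] / L[[cl]])
  })
  names(AB) <- c("0", "2", "4")
  Ks <- (L[["2"]] * AB[["2"]][1] + L[["4"]] * sum(AB[["4"]])) /
    (L[["2"]] / 3 + L[["4"]])
  Ka <- (L[["0"]] * sum(AB[["0"]]) + L[["2"]] * AB[["2"]][2]) /
    (L[["0"]] + 2 * L[["2"]] / 3)
  list(L = L, S = S, V = V, Ka = Ka, Ks = Ks)
}

random_sense_codons <- function(n, seed) {
  set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sample(sense, n, replace = TRUE)
}
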