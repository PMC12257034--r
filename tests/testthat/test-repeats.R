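test_that("SSR scanner applies MISA class minima at the boundaries", {
  # flanked by breakers so runs cannot extend
  r1 <- find_ssrs(paste0("CC", strrep("A", 10), "GG"))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$motif, "A")
  expect_equal(r1$repeat_count, 10L)
  expect_equal(c(r1$start, r1$end), c(3L, 12L))

  expect_equal(nrow(find_ssrs(paste0("CC", strrep("A", 9), "GG"))), 0L)

  r2 <- find_ssrs(paste0("CC", strrep("AT", 5), "GG"))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$motif, "AT")
  expect_equal(r2$unit_length, 2L)
  expect_equal(r2$repeat_count, 5L)

  # a dimer run is not additionally reported as a non-primitive tetramer
  expect_equal(nrow(find_ssrs(paste0("CC", strrep("AT", 6), "GG"))), 1L)
  # interruptions split runs
  broken <- paste0("CC", strrep("A", 6), "G", strrep("A", 6), "CC")
  expect_equal(nrow(find_ssrs(broken)), 0L)
})

test_that("every reported SSR span re-validates as an exact tandem", {
  s <- rand_seq(30000, seed = 41)
  found <- find_ssrs(s)
  for (i in seq_len(nrow(found))) {
    sp <- substr(s, found$start[i], found$end[i])
    expect_identical(sp, strrep(found$motif[i], found$repeat_count[i]))
  }
})

test_that("SSR scanner equals the brute-force regex oracle on random DNA", {
  for (sd in c(42, 43, 44)) {
    s <- rand_seq(20000, seed = sd, gc = 0.45)
    got <- find_ssrs(s)
    exp <- ssr_oracle(s)
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("tandem detector reports period, copy number and percent match", {
  set.seed(45)
  bg <- rand_seq(3000, seed = 45)
  # G flanks cannot extend loci whose units contain no G
  s <- paste0(substr(bg, 1, 1000), "G", strrep("TATAA", 12), "G",
              substr(bg, 1001, 2000), "G", strrep("ATTAA", 6), "G",
              substr(bg, 2001, 3000))
  tr <- find_tandem_repeats(s)
  r1 <- tr[tr$period == 5 & tr$copy_number == 12, ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$consensus, "TATAA")
  expect_equal(r1$percent_match, 100)
  expect_equal(r1$end - r1$start + 1L, 60L)       # span = period x copies
  r2 <- tr[tr$period == 5 & tr$copy_number == 6, ]
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$consensus, "ATTAA")

  # approximate locus: one mismatch in 4 copies of a 20-mer
  unit <- substr(bg, 1, 20)
  locus <- strrep(unit, 4)
  substr(locus, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                   substr(locus, 30, 30))[1]
  fl <- setdiff(c("A", "C", "G", "T"),           # flanks that cannot extend
                c(substr(unit, 20, 20), substr(unit, 1, 1)))[1]
  s2 <- paste0(substr(bg, 1, 500), fl, locus, fl, substr(bg, 501, 1500))
  tr2 <- find_tandem_repeats(s2)
  expect_true(any(tr2$period == 20 & tr2$percent_match < 100 &
                    tr2$percent_match >= 90))
})

test_that("repeat detectors recover exactly the planted landscape", {
  b <- synth_bundle()
  g <- b$genome$seq

  ssr <- find_ssrs(g)
  truth <- b$truth$ssrs
  expect_equal(nrow(ssr), nrow(truth))
  expect_setequal(paste(ssr$motif, ssr$repeat_count, ssr$start, ssr$end),
                  paste(truth$motif, truth$repeat_count, truth$start,
                        truth$end))

  tnd <- find_tandem_repeats(g)
  tt <- b$truth$tandems
  expect_equal(nrow(tnd), nrow(tt))
  o1 <- order(tnd$start); o2 <- order(tt$start)
  expect_equal(tnd$period[o1], tt$period[o2])
  expect_equal(tnd$copy_number[o1], as.numeric(tt$copies[o2]))
  expect_equal(tnd$start[o1], tt$start[o2])
  expect_equal(tnd$end[o1], tt$end[o2])
  expect_true(all(tnd$percent_match == 100))

  excl <- rbind(ssr[, c("start", "end")], tnd[, c("start", "end")])
  dsp <- find_dispersed_repeats(g, exclude = excl)
  dt_ <- b$truth$dispersed
  # every planted pair is recovered (spans may extend a few bases)
  for (i in seq_len(nrow(dt_))) {
    hit <- dsp[dsp$orientation == dt_$orientation[i] &
                 spans_overlap(dsp$a_start, dsp$a_end,
                               dt_$a_start[i], dt_$a_end[i]) &
                 spans_overlap(dsp$b_start, dsp$b_end,
                               dt_$b_start[i], dt_$b_end[i]), ]
    expect_gte(nrow(hit), 1)
    expect_gte(max(hit$length), dt_$length[i])
  }
  # and nothing is reported away from planted pairs
  for (j in seq_len(nrow(dsp))) {
    near <- any(spans_overlap(dsp$a_start[j], dsp$a_end[j],
                              dt_$a_start, dt_$a_end) |
                spans_overlap(dsp$a_start[j], dsp$a_end[j],
                              dt_$b_start, dt_$b_end))
    expect_true(near)
  }
})

test_that("short duplications below 30 bp are not reported as dispersed", {
  bg <- rand_seq(4000, seed = 46)
  dup <- substr(bg, 1000, 1024)                    # 25 bp
  s <- paste0(substr(bg, 1, 2000), dup, substr(bg, 2001, 4000))
  dsp <- find_dispersed_repeats(s)
  expect_equal(nrow(dsp), 0L)
})

test_that("dispersed detection is strand-symmetric", {
  bg <- rand_seq(5000, seed = 47)
  blk <- substr(bg, 2000, 2179)
  s <- paste0(substr(bg, 1, 500), blk, substr(bg, 501, 1500),
              rc(substr(bg, 3000, 3139)), substr(bg, 1501, 5000))
  s <- paste0(s, "")  # direct pair: blk vs original at 2000+; inverted pair
  d1 <- find_dispersed_repeats(s)
  d2 <- find_dispersed_repeats(rc(s))
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(sort(d1$orientation), sort(d2$orientation))
  expect_equal(sort(d1$length), sort(d2$length))
  n <- nchar(s)
  # coordinates mirror: a span [x,y] maps to [n-y+1, n-x+1]
  m1 <- sort(c(d1$a_start, d1$b_start))
  m2 <- sort(n - c(d2$a_end, d2$b_end) + 1)
  expect_equal(m1, m2)
})

test_that("repeat summaries compute class shares and totals", {
  cls <- ssr_class_summary(c(`1` = 29, `2` = 70, `3` = 37, `4` = 98,
                             `5` = 16, `6` = 4))
  expect_equal(attr(cls, "total"), 254)
  expect_equal(cls$pct[cls$unit_length == 4], 38.6)

  single <- ssr_class_summary(c(`3` = 1))
  expect_equal(single$pct[single$unit_length == 3], 100)

  none <- ssr_class_summary(integer(0))
  expect_true(all(is.na(none$pct)))

  b <- synth_bundle()
  ssr <- find_ssrs(b$genome$seq)
  tnd <- find_tandem_repeats(b$genome$seq)
  dsp <- find_dispersed_repeats(b$genome$seq,
                                exclude = rbind(ssr[, c("start", "end")],
                                                tnd[, c("start", "end")]))
  sm <- repeat_summary(ssr, tnd, dsp, nchar(b$genome$seq))
  plan_cnt <- table(factor(b$truth$ssrs$unit_length, levels = 1:6))
  expect_equal(sm$ssr$table$count, as.integer(plan_cnt))
  expect_equal(sm$tandem$count, nrow(b$truth$tandems))
  expect_equal(sm$dispersed$count, nrow(b$truth$dispersed))
})
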