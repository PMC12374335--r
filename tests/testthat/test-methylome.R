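test_that("context classification follows the strand-oriented definition", {
  ref <- c(chr1 = "ACGT", chr2 = "CAGT", chr3 = "CATT")
  expect_equal(classify_context(ref, "chr1", 1, "+"), "CpG")
  expect_equal(classify_context(ref, "chr2", 0, "+"), "CHG")
  expect_equal(classify_context(ref, "chr3", 0, "+"), "CHH")
  # G opposite a CpG reads C-then-G on the minus strand
  expect_equal(classify_context(ref, "chr1", 2, "-"), "CpG")
  expect_equal(classify_context(ref, "chr1", 0, "+"), "not_cytosine")

  # undeterminable near the oriented end: C-H with no third base
  expect_error(classify_context(c(x = "AACA"), "x", 2, "+"), "end")
  expect_equal(classify_context(c(x = "AACA"), "x", 2, "+",
                                end_policy = "truncate_as_CHH"), "CHH")
  # C as the last base: even CpG cannot be decided
  expect_error(classify_context(c(x = "AAC"), "x", 2, "+"), "end")
})

test_that("site enumeration agrees with a regex oracle on random sequence", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  got <- methinherit:::site_contexts(s)

  regex_pos <- function(seq, pattern) {
    # all match starts, including overlapping ones
    starts <- integer()
    from <- 1L
    repeat {
      m <- regexpr(pattern, substr(seq, from, nchar(seq)), perl = TRUE)
      if (m == -1L) break
      starts <- c(starts, from + m - 1L)
      from <- from + m
    }
    starts - 1L
  }
  # lookahead regexes count overlapping occurrences
  plus_cpg <- regex_pos(s, "C(?=G)")
  plus_chg <- regex_pos(s, "C(?=[ACT]G)")
  plus_chh <- regex_pos(s, "C(?=[ACT][ACT])")
  expect_equal(sort(got$pos[got$strand == "+" & got$context == "CpG"]),
               plus_cpg)
  expect_equal(sort(got$pos[got$strand == "+" & got$context == "CHG"]),
               plus_chg)
  expect_equal(sort(got$pos[got$strand == "+" & got$context == "CHH"]),
               plus_chh)

  # minus strand via the reverse complement
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  L <- nchar(s)
  to_plus <- function(p_rc) sort(L - 1L - p_rc)
  expect_equal(sort(got$pos[got$strand == "-" & got$context == "CpG"]),
               to_plus(regex_pos(rc, "C(?=G)")))
  expect_equal(sort(got$pos[got$strand == "-" & got$context == "CHG"]),
               to_plus(regex_pos(rc, "C(?=[ACT]G)")))
  expect_equal(sort(got$pos[got$strand == "-" & got$context == "CHH"]),
               to_plus(regex_pos(rc, "C(?=[ACT][ACT])")))

  # classify_context agrees with the enumeration on sampled positions
  ref <- c(chr = s)
  take <- got[sample(nrow(got), 200), ]
  expect_equal(classify_context(ref, "chr", take$pos, take$strand,
                                end_policy = "truncate_as_CHH"),
               take$context)
})

test_that("CpG strand merging sums pairs and conserves totals", {
  sites <- rbind(
    sites_df(pos = 10, strand = "+", n_meth = 3, n_total = 10),
    sites_df(pos = 11, strand = "-", n_meth = 4, n_total = 10),
    sites_df(pos = 50, strand = "+", n_meth = 1, n_total = 5),  # unpaired
    sites_df(pos = 70, strand = "+", context = "CHH", n_meth = 2,
             n_total = 9))
  m <- merge_cpg_strands(methylome_sample(sites, "s"))
  merged <- m$sites[m$sites$pos == 10, ]
  expect_equal(merged$n_meth, 7L)
  expect_equal(merged$n_total, 20L)
  expect_true(all(c(50, 70) %in% m$sites$pos))
  expect_equal(nrow(m$sites), 3L)
  # conservation
  expect_equal(sum(m$sites$n_meth), sum(sites$n_meth))
  expect_equal(sum(m$sites$n_total), sum(sites$n_total))

  # property: conservation on a random sample
  set.seed(3)
  cfg <- small_config(seed = 3, chrom_length = 20000L, n_genes = 5L,
                      n_dmrs = 2L, control_length = 5000L)
  ref <- simulate_reference(cfg)
  sm <- simulate_methylome(ref, "A", sample_id = "x")
  mm <- merge_cpg_strands(sm)
  tot <- function(s) {
    dt <- s$sites
    c(sum(dt$n_meth), sum(dt$n_total))
  }
  expect_equal(tot(mm), tot(sm))
  # no remaining complementary CpG pair
  ms <- mm$sites
  plus <- ms[ms$context == "CpG" & ms$strand == "+", ]
  minus <- ms[ms$context == "CpG" & ms$strand == "-", ]
  expect_false(any(paste(minus$chrom, minus$pos - 1) %in%
                     paste(plus$chrom, plus$pos)))
})

test_that("context summaries compute pooled and mean-of-site levels", {
  s <- methylome_sample(rbind(
    sites_df(pos = 1, n_meth = 9, n_total = 10),
    sites_df(pos = 5, n_meth = 3, n_total = 10)), "s")
  sm <- context_summaries(s)
  cpg <- sm[sm$context == "CpG", ]
  expect_equal(cpg$pooled_level, 0.6)
  expect_equal(cpg$mean_site_level, 0.6)
  # uncovered contexts flagged
  expect_equal(sm$n_sites_covered[sm$context == "CHH"], 0L)
  expect_true(is.na(sm$pooled_level[sm$context == "CHH"]))

  s2 <- methylome_sample(rbind(
    sites_df(pos = 1, n_meth = 10, n_total = 10),
    sites_df(pos = 5, n_meth = 0, n_total = 10)), "s2")
  expect_equal(context_summaries(s2)$pooled_level[1], 0.5)
})

test_that("pooled level is invariant under splitting counts across sites", {
  s1 <- methylome_sample(sites_df(pos = c(1, 5), n_meth = c(12, 0),
                                  n_total = c(20, 10)), "a")
  s2 <- methylome_sample(sites_df(pos = c(1, 3, 5, 7),
                                  n_meth = c(6, 6, 0, 0),
                                  n_total = c(10, 10, 5, 5)), "b")
  expect_equal(context_summaries(s1)$pooled_level[1],
               context_summaries(s2)$pooled_level[1])
})

test_that("conversion rate comes from control-sequence sites", {
  ctl <- methylome_sample(
    sites_df(chrom = "lambda", pos = c(1, 10), n_meth = c(2, 0),
             n_total = c(600, 400)), "s")
  expect_equal(conversion_rate(ctl, "lambda"), 0.998)

  perfect <- methylome_sample(
    sites_df(chrom = "lambda", pos = 1, n_meth = 0, n_total = 100), "s")
  expect_equal(conversion_rate(perfect, "lambda"), 1.0)

  expect_error(conversion_rate(ctl, "missing_contig"), "control")
})
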