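test_that("simulation config validates its stated world", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(dispersion = 1.2))
  expect_error(simulation_config(inheritance_fraction = -0.1))
  expect_error(simulation_config(dmr_level_low = 0.9,
                                 dmr_level_high = 0.4))
  expect_error(simulation_config(chrom_length = 100, dmr_width = 1000))
})

test_that("reference simulation packs disjoint genes at the right GC", {
  cfg <- simulation_config(seed = 5, n_chroms = 1,
                           chrom_length = 500000L, n_genes = 50L,
                           control_length = 10000L)
  ref <- simulate_reference(cfg)
  g <- ref$genes
  expect_equal(nrow(g), 50L)
  expect_true(all(g$tx_start < g$tx_end))
  ord <- g[order(g$tx_start), ]
  expect_true(all(ord$tx_start[-1] >= ord$tx_end[-nrow(ord)]))  # disjoint

  # control contig in the FASTA world, absent from gene models
  expect_true(ref$control_chrom %in% names(ref$sequences))
  expect_false(ref$control_chrom %in% g$chrom)

  # GC recovery within 3 binomial s.e.
  cfg2 <- simulation_config(seed = 6, n_chroms = 1,
                            chrom_length = 100000L, gc_fraction = 0.5,
                            n_genes = 10L, control_length = 5000L,
                            n_dmrs = 10L)
  ref2 <- simulate_reference(cfg2)
  gc <- mean(strsplit(ref2$sequences[["chr1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))

  # infeasible packing errors
  expect_error(simulate_reference(
    simulation_config(seed = 1, n_chroms = 1, chrom_length = 100000L,
                      n_genes = 50L, gene_length_range = c(3000L, 4000L))),
    "packing")
})

test_that("planted DMR levels appear in the right condition", {
  cfg <- small_config(seed = 9)
  ref <- simulate_reference(cfg)
  a <- simulate_methylome(ref, "A", sample_id = "a")
  b <- simulate_methylome(ref, "B", sample_id = "b")
  pl <- ref$planted
  pooled_in <- function(s, row) {
    st <- s$sites
    sel <- st$chrom == row$chrom & st$pos >= row$start &
      st$pos < row$end & st$context == row$context
    sum(st$n_meth[sel]) / sum(st$n_total[sel])
  }
  for (i in seq_len(nrow(pl))) {
    expect_lt(abs(pooled_in(a, pl[i, ]) - pl$level_A[i]), 0.12)
    expect_lt(abs(pooled_in(b, pl[i, ]) - pl$level_B[i]), 0.12)
  }
  # control contig is essentially unmethylated (conversion failure only)
  ctl <- a$sites[a$sites$chrom == ref$control_chrom, ]
  expect_lt(sum(ctl$n_meth) / sum(ctl$n_total), 0.02)
})

test_that("rho = 0 counts are exact binomial (chi-square GOF)", {
  cfg <- simulation_config(seed = 4, n_chroms = 1,
                           chrom_length = 620000L, n_genes = 50L,
                           dispersion = 0, conversion_failure = 0,
                           n_dmrs = 0L, control_length = 5000L)
  ref <- simulate_reference(cfg)
  s <- simulate_methylome(ref, "A", sample_id = "a")
  st <- s$sites[s$sites$context == "CHH" & s$sites$n_total == 30L &
                  s$sites$chrom == "chr1", ]
  expect_gt(nrow(st), 10000)
  p0 <- unname(cfg$baseline_levels["CHH"])
  expected <- dbinom(0:30, 30, p0) * nrow(st)
  observed <- tabulate(st$n_meth + 1L, nbins = 31L)
  # pool the sparse right tail so expected counts are >= 5
  cut <- max(which(expected >= 5))
  obs <- c(observed[1:cut], sum(observed[-(1:cut)]))
  exp <- c(expected[1:cut], sum(expected[-(1:cut)]))
  stat <- sum((obs - exp)^2 / exp)
  p <- pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("inheritance fraction selects exactly floor(f * n) DMRs", {
  cfg1 <- small_config(seed = 2, inheritance_fraction = 1.0)
  ref1 <- simulate_reference(cfg1)
  inh1 <- simulate_inheritance(ref1)
  expect_equal(inh1$inherited, ref1$planted)

  cfg0 <- small_config(seed = 2, inheritance_fraction = 0.0)
  ref0 <- simulate_reference(cfg0)
  inh0 <- simulate_inheritance(ref0)
  expect_equal(nrow(inh0$inherited), 0L)

  cfg6 <- small_config(seed = 2, inheritance_fraction = 0.6)
  ref6 <- simulate_reference(cfg6)
  inh6 <- simulate_inheritance(ref6)
  expect_equal(nrow(inh6$inherited), floor(0.6 * 20))
  keys <- function(d) paste(d$chrom, d$start)
  expect_true(all(keys(inh6$inherited) %in% keys(ref6$planted)))
  # non-inherited regions carry the fresh level in the stored embryo
  not_inh <- !keys(inh6$planted_stored) %in% keys(inh6$inherited)
  expect_equal(inh6$planted_stored$level_B[not_inh],
               inh6$planted_stored$level_A[not_inh])
})

test_that("expression simulation couples DEGs to inherited DMR genes", {
  cfg <- small_config(seed = 13, p_coupled_to_dmr = 1.0, n_degs = 5L)
  ref <- simulate_reference(cfg)
  inh <- simulate_inheritance(ref)
  expr <- simulate_expression(ref, inh$inherited)

  dmg_genes <- unique(assign_dmrs_to_genes(inh$inherited,
                                           ref$genes)$gene_id)
  expect_true(all(expr$degs$gene_id %in% dmg_genes))
  expect_true(all(expr$degs$coupled))

  # planted DEGs pass the stated filter, nothing else does
  kept <- filter_degs(expr$deg_table)
  expect_setequal(kept$gene_id, expr$degs$gene_id)
  expect_equal(kept$direction[match(expr$degs$gene_id, kept$gene_id)],
               expr$degs$direction)
  # and the protein layer mirrors it at its own thresholds
  keptp <- suppressMessages(filter_deps(expr$dep_table,
                                        gene_map = expr$gene_map))
  expect_setequal(keptp$gene_id, expr$deps$gene_id)

  expect_error(
    simulate_expression(
      simulate_reference(small_config(seed = 1, n_degs = 100L)),
      inh$inherited),
    "n_degs")
})

test_that("identical seeds give byte-identical simulation outputs", {
  cfg <- small_config(seed = 123, chrom_length = 60000L, n_genes = 12L,
                      n_dmrs = 5L, n_degs = 2L, n_deps = 2L,
                      control_length = 5000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_simulation(simulate_dataset(cfg), d1)
  f2 <- write_simulation(simulate_dataset(cfg), d2)
  expect_equal(unname(tools::md5sum(unname(f1))),
               unname(tools::md5sum(unname(f2))))

  # a different seed changes the world
  f3 <- write_simulation(simulate_dataset(
    small_config(seed = 124, chrom_length = 60000L, n_genes = 12L,
                 n_dmrs = 5L, n_degs = 2L, n_deps = 2L,
                 control_length = 5000L)), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(unname(f1[["truth"]]))),
                         unname(tools::md5sum(unname(f3[["truth"]])))))
})
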