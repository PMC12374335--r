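# Shared fixtures and independent oracles.  Everything is built in code;
# no binary data.

# -- site tables -------------------------------------------------------------

sites_df <- function(chrom = "chr1", pos, strand = "+", context = "CpG",
                     n_meth, n_total) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_total = as.integer(n_total), stringsAsFactors = FALSE)
}

write_report_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# One-chromosome sample pair with identical generating levels, one window
# per `width` bp containing `sites_per_window` CpG sites.
null_sample_pair <- function(n_windows, sites_per_window = 10L,
                             width = 1000L, coverage_mean = 30,
                             level = 0.3, seed = 1L) {
  set.seed(seed)
  pos <- as.integer(outer((0:(sites_per_window - 1)) *
                            (width %/% sites_per_window),
                          (0:(n_windows - 1)) * width, "+"))
  gen <- function(id) {
    n <- length(pos)
    cov <- stats::rpois(n, coverage_mean)
    methylome_sample(
      sites_df(pos = pos, n_meth = stats::rbinom(n, cov, level),
               n_total = cov),
      sample_id = id)
  }
  list(A = gen("null_A"), B = gen("null_B"))
}

# -- independent oracles -----------------------------------------------------

# Fisher two-sided P by direct enumeration with choose(); normalised point
# probabilities, no dhyper.
oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  k <- max(0, r1 - (N - c1)):min(r1, c1)
  pr <- choose(r1, k) * choose(N - r1, c1 - k)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[k == a] * (1 + 1e-7)])
}

# Quadratic all-pairs DMR -> gene assignment with its own promoter
# arithmetic (upstream mode, clip at 0).
oracle_assign <- function(dmrs, genes, promoter_size = 1000L) {
  recs <- list()
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      if (overlaps(dmrs$start[i], dmrs$end[i],
                   genes$tx_start[j], genes$tx_end[j])) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene_id = genes$gene_id[j], region_class = "gene_body",
          direction = dmrs$direction[i],
          dmr_id = paste0(dmrs$chrom[i], ":", dmrs$start[i], "-",
                          dmrs$end[i]), stringsAsFactors = FALSE)
      }
      if (genes$strand[j] == "+") {
        ps <- max(0L, genes$tx_start[j] - promoter_size)
        pe <- genes$tx_start[j]
      } else {
        ps <- genes$tx_end[j]
        pe <- genes$tx_end[j] + promoter_size
      }
      if (ps < pe && overlaps(dmrs$start[i], dmrs$end[i], ps, pe)) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene_id = genes$gene_id[j], region_class = "promoter",
          direction = dmrs$direction[i],
          dmr_id = paste0(dmrs$chrom[i], ":", dmrs$start[i], "-",
                          dmrs$end[i]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) return(methinherit:::empty_dmg_table())
  all <- unique(do.call(rbind, recs))
  agg <- aggregate(dmr_id ~ gene_id + region_class + direction, all,
                   function(x) paste(sort(x), collapse = ","))
  names(agg)[names(agg) == "dmr_id"] <- "dmr_ids"
  agg$n_supporting_dmrs <- lengths(strsplit(agg$dmr_ids, ","))
  agg[order(agg$gene_id, agg$region_class, agg$direction),
      c("gene_id", "region_class", "direction", "n_supporting_dmrs",
        "dmr_ids")]
}

# random DMG record table for integration fixtures
random_dmg_records <- function(n_genes, n_records, seed) {
  set.seed(seed)
  data.frame(
    gene_id = sprintf("g%03d", sample(n_genes, n_records, replace = TRUE)),
    region_class = sample(c("gene_body", "promoter"), n_records,
                          replace = TRUE),
    direction = sample(c("hyper", "hypo"), n_records, replace = TRUE),
    n_supporting_dmrs = 1L, dmr_ids = "x", stringsAsFactors = FALSE)
}

# canonical record-set key for comparing DMG tables
dmg_key <- function(records) {
  sort(paste(records$gene_id, records$region_class, records$direction,
             records$n_supporting_dmrs, records$dmr_ids, sep = "|"))
}

small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chroms = 1L, chrom_length = 150000L,
                   control_length = 10000L, n_genes = 40L, n_dmrs = 20L,
                   n_degs = 6L, n_deps = 6L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
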