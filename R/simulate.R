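# Synthetic WGBS data generator.
#
# The generator states a small but complete world: a random reference
# genome with non-overlapping gene models and one fully unmethylated
# control contig; per-cytosine counts with Poisson coverage and
# beta-binomial overdispersion around context baselines (CpG 0.93,
# CHG 0.014, CHH 0.04); planted hyper/hypo DMRs between a fresh (A) and a
# stored (B) condition; an embryo generation inheriting a configurable
# fraction of the sperm DMRs; and coupled expression/protein tables.
# All randomness flows from `config$seed`; identical seeds give
# byte-identical outputs.

#' Build a simulation configuration
#'
#' Defaults encode the stated world: global methylation baselines
#' CpG 0.93 / CHG 0.014 / CHH 0.04, Poisson mean coverage 30,
#' beta-binomial overdispersion `rho = 0.05`, bisulphite conversion
#' failure 0.5%, 100 planted 1-kb CpG DMRs switching levels between 0.40
#' and 0.93 (half hyper, half hypo), and an inheritance fraction of 0.6.
#'
#' @param seed Integer master seed.
#' @param n_chroms,chrom_length Number and length (bp) of data
#'   chromosomes.
#' @param gc_fraction GC content of the random sequence.
#' @param control_length Length of the unmethylated control contig.
#' @param n_genes Total number of non-overlapping gene models.
#' @param gene_length_range Min/max gene length (bp).
#' @param baseline_levels Named vector of context baselines.
#' @param coverage_mean Poisson mean per-site coverage.
#' @param dispersion Beta-binomial overdispersion rho in `[0, 1)`;
#'   0 gives exact binomial counts.
#' @param conversion_failure Probability that an unmethylated molecule
#'   escapes conversion and reads as methylated.
#' @param n_dmrs Number of planted DMRs.
#' @param dmr_width Planted DMR width (one caller window by default).
#' @param dmr_level_low,dmr_level_high The two methylation levels a
#'   planted DMR switches between (chosen so the level ratio exceeds the
#'   two-fold calling threshold).
#' @param hyper_fraction Fraction of planted DMRs that are
#'   hypermethylated in the stored condition.
#' @param min_cpg_per_dmr Minimum CpG sites (both strands) required in a
#'   window for DMR placement (rejection sampling).
#' @param inheritance_fraction Fraction of sperm DMRs retained by the
#'   embryo of the stored condition.
#' @param n_degs Number of planted differentially expressed genes.
#' @param p_coupled_to_dmr Probability that a planted DEG sits on a gene
#'   carrying an inherited DMR.
#' @param deg_fc_range Fold-change range for planted DEGs.
#' @param n_deps Number of planted differential proteins (identity
#'   protein-to-gene map).
#' @param dep_fc_range Fold-change range for planted DEPs.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L, chrom_length = 500000L,
                              gc_fraction = 0.4, control_length = 20000L,
                              n_genes = 200L,
                              gene_length_range = c(1000L, 4000L),
                              baseline_levels = c(CpG = 0.93, CHG = 0.014,
                                                  CHH = 0.04),
                              coverage_mean = 30, dispersion = 0.05,
                              conversion_failure = 0.005,
                              n_dmrs = 100L, dmr_width = 1000L,
                              dmr_level_low = 0.40, dmr_level_high = 0.93,
                              hyper_fraction = 0.5, min_cpg_per_dmr = 10L,
                              inheritance_fraction = 0.6,
                              n_degs = 20L, p_coupled_to_dmr = 0.5,
                              deg_fc_range = c(2, 6),
                              n_deps = 20L, dep_fc_range = c(1.5, 3)) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_fraction = gc_fraction,
              control_length = as.integer(control_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              baseline_levels = baseline_levels,
              coverage_mean = coverage_mean, dispersion = dispersion,
              conversion_failure = conversion_failure,
              n_dmrs = as.integer(n_dmrs), dmr_width = as.integer(dmr_width),
              dmr_level_low = dmr_level_low,
              dmr_level_high = dmr_level_high,
              hyper_fraction = hyper_fraction,
              min_cpg_per_dmr = as.integer(min_cpg_per_dmr),
              inheritance_fraction = inheritance_fraction,
              n_degs = as.integer(n_degs),
              p_coupled_to_dmr = p_coupled_to_dmr,
              deg_fc_range = deg_fc_range, n_deps = as.integer(n_deps),
              dep_fc_range = dep_fc_range)
  with(cfg, {
    stopifnot(n_chroms >= 1L, chrom_length >= dmr_width,
              gc_fraction > 0, gc_fraction < 1,
              all(baseline_levels >= 0), all(baseline_levels <= 1),
              setequal(names(baseline_levels), c("CpG", "CHG", "CHH")),
              coverage_mean > 0, dispersion >= 0, dispersion < 1,
              conversion_failure >= 0, conversion_failure <= 1,
              dmr_level_low >= 0, dmr_level_high <= 1,
              dmr_level_low < dmr_level_high,
              hyper_fraction >= 0, hyper_fraction <= 1,
              inheritance_fraction >= 0, inheritance_fraction <= 1,
              p_coupled_to_dmr >= 0, p_coupled_to_dmr <= 1)
  })
  structure(cfg, class = "sim_config")
}

random_sequence <- function(length, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# Non-overlapping gene placement on one chromosome by stick-breaking the
# free space into random gaps.
place_genes <- function(n, chrom_length, length_range) {
  if (n == 0L) return(data.frame(tx_start = integer(), tx_end = integer()))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  free <- chrom_length - sum(lens)
  if (free < 0) stop("infeasible packing of genes: ", sum(lens),
                     " bp of genes on a ", chrom_length, " bp chromosome")
  u <- stats::runif(n + 1)
  gaps <- floor(free * u / sum(u))
  starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lens[-n]))
  data.frame(tx_start = as.integer(starts),
             tx_end = as.integer(starts + lens))
}

#' Simulate a reference genome, gene models and planted DMRs
#'
#' Generates random chromosome sequences at the requested GC content,
#' non-overlapping stranded gene models, one designated fully
#' unmethylated control contig (present in the FASTA, absent from the
#' gene models), enumerates every cytosine site with its context, and
#' plants `n_dmrs` non-overlapping window-aligned CpG DMRs by rejection
#' sampling windows with at least `min_cpg_per_dmr` CpG sites.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_reference`: `sequences` (named character),
#'   `genes`, `control_chrom`, `sites` (per-chromosome context tables),
#'   `planted` (DMR truth: chrom, start, end, context, level_A, level_B,
#'   direction) and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- stats::setNames(
    vapply(chroms, function(x)
      random_sequence(config$chrom_length, config$gc_fraction), ""),
    chroms)
  ctrl <- "ctrl_unmeth"
  seqs[ctrl] <- random_sequence(config$control_length, config$gc_fraction)

  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    g <- place_genes(per_chrom[i], config$chrom_length,
                     config$gene_length_range)
    g$chrom <- rep(chroms[i], nrow(g))
    g
  }))
  genes <- genes[, c("chrom", "tx_start", "tx_end")]
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end")]

  sites <- lapply(seqs, site_contexts)
  planted <- plant_dmrs(sites[chroms], config)
  structure(list(sequences = seqs, genes = genes, control_chrom = ctrl,
                 sites = sites, planted = planted, config = config),
            class = "sim_reference")
}

plant_dmrs <- function(data_sites, config) {
  w <- config$dmr_width
  if (config$n_dmrs == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      level_A = numeric(), level_B = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  cand <- data.table::rbindlist(lapply(names(data_sites), function(ch) {
    s <- data_sites[[ch]]
    cpg <- s$pos[s$context == "CpG"]
    n_win <- config$chrom_length %/% w
    cnt <- tabulate(cpg %/% w + 1L, nbins = n_win)
    data.table::data.table(chrom = ch, win = which(cnt >=
                                                     config$min_cpg_per_dmr) - 1L)
  }))
  if (nrow(cand) < config$n_dmrs) {
    stop("cannot place ", config$n_dmrs, " DMRs: only ", nrow(cand),
         " windows have >= ", config$min_cpg_per_dmr, " CpG sites")
  }
  pick <- cand[sample(.N, config$n_dmrs)]
  n_hyper <- round(config$n_dmrs * config$hyper_fraction)
  direction <- c(rep("hyper", n_hyper),
                 rep("hypo", config$n_dmrs - n_hyper))
  out <- data.frame(
    chrom = pick$chrom, start = pick$win * w, end = pick$win * w + w,
    context = "CpG",
    level_A = ifelse(direction == "hyper", config$dmr_level_low,
                     config$dmr_level_high),
    level_B = ifelse(direction == "hyper", config$dmr_level_high,
                     config$dmr_level_low),
    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one methylome from a reference
#'
#' Every determinable cytosine site (both strands) receives its true
#' level: the context baseline, overridden inside planted DMRs by
#' `level_A` (condition A, fresh) or `level_B` (condition B, stored), and
#' zero on the control contig.  Coverage is Poisson; the per-site success
#' probability is drawn from a beta distribution with mean equal to the
#' true level and overdispersion `dispersion` (exact binomial when 0);
#' conversion failure converts unmethylated molecules to apparent
#' methylated calls with the configured probability.
#'
#' @param reference A `sim_reference`.
#' @param condition `"A"` (fresh) or `"B"` (stored).
#' @param planted Planted-DMR table to apply (defaults to the sperm
#'   truth in `reference$planted`; the embryo generator passes its own).
#' @param sample_id,group Labels for the resulting sample.
#' @param seed Seed for this sample's counts (default derived from the
#'   configuration seed and the condition).
#' @return A [methylome_sample()].
#' @export
simulate_methylome <- function(reference, condition = c("A", "B"),
                               planted = reference$planted,
                               sample_id = paste0("sim_", condition),
                               group = condition, seed = NULL) {
  condition <- match.arg(condition)
  cfg <- reference$config
  if (is.null(seed)) seed <- cfg$seed + 101L + match(condition, c("A", "B"))
  set.seed(seed)
  lvl_col <- if (condition == "A") "level_A" else "level_B"

  tabs <- lapply(names(reference$sequences), function(ch) {
    s <- reference$sites[[ch]]
    mu <- unname(cfg$baseline_levels[s$context])
    if (ch == reference$control_chrom) mu[] <- 0
    pl <- planted[planted$chrom == ch, , drop = FALSE]
    if (nrow(pl)) {
      for (i in seq_len(nrow(pl))) {
        sel <- s$pos >= pl$start[i] & s$pos < pl$end[i] &
          s$context == pl$context[i]
        mu[sel] <- pl[[lvl_col]][i]
      }
    }
    n <- nrow(s)
    cov <- stats::rpois(n, cfg$coverage_mean)
    p <- mu
    if (cfg$dispersion > 0) {
      shape_tot <- 1 / cfg$dispersion - 1
      inner <- mu > 0 & mu < 1
      p[inner] <- stats::rbeta(sum(inner), mu[inner] * shape_tot,
                               (1 - mu[inner]) * shape_tot)
    }
    p_obs <- p + (1 - p) * cfg$conversion_failure
    data.table::data.table(chrom = ch, pos = s$pos, strand = s$strand,
                           context = s$context,
                           n_meth = stats::rbinom(n, cov, p_obs),
                           n_total = cov)
  })
  methylome_sample(data.table::rbindlist(tabs), sample_id = sample_id,
                   group = group)
}

#' Select the sperm DMRs inherited by the embryo generation
#'
#' Samples `floor(inheritance_fraction * n)` of the planted sperm DMRs
#' without replacement.  The embryo of the stored condition retains the
#' condition-B level inside inherited DMRs; non-inherited DMRs revert to
#' the fresh-condition level so the embryo pair differs only at inherited
#' regions (which makes the embryo truth exactly the inherited set).
#'
#' @param reference A `sim_reference`.
#' @param seed Seed for the inheritance draw (default derived from the
#'   configuration seed).
#' @return List: `inherited` (truth table, subset of
#'   `reference$planted`), `planted_fresh` and `planted_stored` (the
#'   planted tables to use for the two embryo methylomes).
#' @export
simulate_inheritance <- function(reference, seed = NULL) {
  cfg <- reference$config
  if (is.null(seed)) seed <- cfg$seed + 104L
  set.seed(seed)
  planted <- reference$planted
  n_inh <- floor(cfg$inheritance_fraction * nrow(planted))
  idx <- sort(sample(nrow(planted))[seq_len(n_inh)])
  inherited <- planted[idx, , drop = FALSE]
  # fresh embryo keeps the fresh-condition (A) level everywhere;
  # the stored embryo keeps B only where inherited
  planted_stored <- planted
  not_inh <- setdiff(seq_len(nrow(planted)), idx)
  planted_stored$level_B[not_inh] <- planted_stored$level_A[not_inh]
  rownames(inherited) <- NULL
  list(inherited = inherited, planted_fresh = planted,
       planted_stored = planted_stored)
}

#' Simulate the embryo methylome pair with partial DMR inheritance
#'
#' @param reference A `sim_reference`.
#' @param seed Base seed for the embryo generation (default derived from
#'   the configuration seed).
#' @return List: `fresh` and `stored` ([methylome_sample()]s) and
#'   `inherited` (the inherited-DMR truth table).
#' @export
simulate_inherited_embryo <- function(reference, seed = NULL) {
  cfg <- reference$config
  if (is.null(seed)) seed <- cfg$seed + 104L
  inh <- simulate_inheritance(reference, seed = seed)
  fresh <- simulate_methylome(reference, "A", planted = inh$planted_fresh,
                              sample_id = "embryo_fresh",
                              group = "embryo_fresh", seed = seed + 1L)
  stored <- simulate_methylome(reference, "B",
                               planted = inh$planted_stored,
                               sample_id = "embryo_stored",
                               group = "embryo_stored", seed = seed + 2L)
  list(fresh = fresh, stored = stored, inherited = inh$inherited)
}

# Direction rule coupling an inherited methylation change to expression:
# gene-body support follows the methylation direction, promoter support
# follows the repressive reading (promoter hyper -> down).
deg_direction_rule <- function(meth, note) {
  promoter <- grepl("^promoter", note)
  ifelse(promoter, ifelse(meth == "up", "down", "up"), meth)
}

#' Simulate coupled expression and protein tables
#'
#' Draws `n_degs` differentially expressed genes; a fraction
#' `p_coupled_to_dmr` of them are placed on genes carrying an inherited
#' DMR, with direction given by the concordance rule (gene-body
#' methylation direction carries over; promoter methylation acts
#' repressively).  Planted DEGs get fold changes in `deg_fc_range`
#' (reciprocal for down) and Q values below 0.001; all other genes fail
#' at least one threshold.  A protein table with the 1.3/1.5-fold
#' threshold in mind is generated the same way on the same genes, with an
#' identity protein-to-gene map.
#'
#' @param reference A `sim_reference`.
#' @param inherited Inherited-DMR truth table
#'   ([simulate_inherited_embryo()]`$inherited`).
#' @param seed Seed (default derived from the configuration seed).
#' @return List: `deg_table`, `dep_table`, `gene_map`, and truth tables
#'   `degs` / `deps` (gene_id, direction, coupled).
#' @export
simulate_expression <- function(reference, inherited, seed = NULL) {
  cfg <- reference$config
  if (is.null(seed)) seed <- cfg$seed + 107L
  set.seed(seed)
  genes <- reference$genes
  if (cfg$n_degs > nrow(genes)) {
    stop("n_degs exceeds the number of simulated genes")
  }
  dmgs <- assign_dmrs_to_genes(inherited, genes)
  meth_dir <- gene_meth_direction(dmgs)
  eligible <- meth_dir[meth_dir$meth != "mixed", , drop = FALSE]

  n_coupled <- round(cfg$p_coupled_to_dmr * cfg$n_degs)
  if (n_coupled > nrow(eligible)) {
    stop("cannot couple ", n_coupled, " DEGs to inherited DMRs: only ",
         nrow(eligible), " genes carry a direction-consistent inherited DMR")
  }
  coupled_ids <- sort(eligible$gene_id[sample(nrow(eligible))[
    seq_len(n_coupled)]])
  free_pool <- setdiff(genes$gene_id, meth_dir$gene_id)
  if (cfg$n_degs - n_coupled > length(free_pool)) {
    stop("not enough DMR-free genes for uncoupled DEGs")
  }
  uncoupled_ids <- sort(free_pool[sample(length(free_pool))[
    seq_len(cfg$n_degs - n_coupled)]])

  sel <- match(coupled_ids, eligible$gene_id)
  coupled_dir <- deg_direction_rule(eligible$meth[sel],
                                    eligible$note[sel])
  uncoupled_dir <- sample(c("up", "down"), length(uncoupled_ids),
                          replace = TRUE)
  deg_truth <- data.frame(
    gene_id = c(coupled_ids, uncoupled_ids),
    direction = c(coupled_dir, uncoupled_dir),
    coupled = rep(c(TRUE, FALSE), c(length(coupled_ids),
                                    length(uncoupled_ids))),
    stringsAsFactors = FALSE)
  deg_truth <- deg_truth[order(deg_truth$gene_id), , drop = FALSE]
  rownames(deg_truth) <- NULL

  deg_table <- expression_table(genes$gene_id, deg_truth,
                                fc_range = cfg$deg_fc_range,
                                sig_max = 5e-4, null_sig = c(0.01, 1),
                                null_fc = c(-0.5, 0.5))
  names(deg_table) <- c("gene_id", "fold_change", "q_value")

  # proteins: planted on the same truth (identity protein->gene map)
  dep_truth <- deg_truth
  dep_table <- expression_table(genes$gene_id, dep_truth,
                                fc_range = cfg$dep_fc_range,
                                sig_max = 0.04, null_sig = c(0.1, 1),
                                null_fc = c(-0.2, 0.2))
  names(dep_table) <- c("protein_id", "fold_change", "adj_p")
  gene_map <- data.frame(protein_id = genes$gene_id,
                         gene_id = genes$gene_id, stringsAsFactors = FALSE)
  list(deg_table = deg_table, dep_table = dep_table, gene_map = gene_map,
       degs = deg_truth, deps = dep_truth)
}

expression_table <- function(all_ids, truth, fc_range, sig_max, null_sig,
                             null_fc) {
  n <- length(all_ids)
  fc <- 2^stats::runif(n, null_fc[1], null_fc[2])
  q <- stats::runif(n, null_sig[1], null_sig[2])
  i <- match(truth$gene_id, all_ids)
  mag <- stats::runif(nrow(truth), fc_range[1], fc_range[2])
  fc[i] <- ifelse(truth$direction == "up", mag, 1 / mag)
  q[i] <- stats::runif(nrow(truth), 0, sig_max)
  data.frame(id = all_ids, fold_change = fc, q = q,
             stringsAsFactors = FALSE)
}

#' Simulate a complete multi-omics dataset
#'
#' Orchestrates [simulate_reference()], the sperm methylome pair, the
#' embryo pair with partial DMR inheritance, and the coupled
#' expression/protein tables.  All stage seeds are derived from
#' `config$seed`, so the whole dataset is reproducible from one integer.
#'
#' @param config A [simulation_config()].
#' @return List: `reference`, `sperm` (`$fresh`, `$stored`), `embryo`
#'   (`$fresh`, `$stored`), `tables` (`$deg_table`, `$dep_table`,
#'   `$gene_map`) and `truth` (`$planted`, `$inherited`, `$degs`,
#'   `$deps`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ref <- simulate_reference(config)
  sperm_fresh <- simulate_methylome(ref, "A", sample_id = "sperm_fresh",
                                    group = "fresh",
                                    seed = config$seed + 102L)
  sperm_stored <- simulate_methylome(ref, "B", sample_id = "sperm_stored",
                                     group = "stored",
                                     seed = config$seed + 103L)
  emb <- simulate_inherited_embryo(ref, seed = config$seed + 104L)
  expr <- simulate_expression(ref, emb$inherited,
                              seed = config$seed + 107L)
  list(reference = ref,
       sperm = list(fresh = sperm_fresh, stored = sperm_stored),
       embryo = list(fresh = emb$fresh, stored = emb$stored),
       tables = expr[c("deg_table", "dep_table", "gene_map")],
       truth = list(planted = ref$planted, inherited = emb$inherited,
                    degs = expr$degs, deps = expr$deps))
}

#' Write a simulated dataset to disk
#'
#' Emits the reference FASTA, the gene models as GFF3, the four cytosine
#' reports, the DEG/DEP/protein-map TSVs and `truth.json`.  Outputs are
#' plain text and byte-identical for identical seeds.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(outdir, x)
  ref <- dataset$reference
  fa <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(fa, p("reference.fa"))
  write_gene_models_gff3(ref$genes, p("genes.gff3"))
  write_cytosine_report(dataset$sperm$fresh, p("sperm_fresh.cx.tsv"))
  write_cytosine_report(dataset$sperm$stored, p("sperm_stored.cx.tsv"))
  write_cytosine_report(dataset$embryo$fresh, p("embryo_fresh.cx.tsv"))
  write_cytosine_report(dataset$embryo$stored, p("embryo_stored.cx.tsv"))
  write_tsv_table(dataset$tables$deg_table, p("deg.tsv"))
  write_tsv_table(dataset$tables$dep_table, p("dep.tsv"))
  write_tsv_table(dataset$tables$gene_map, p("protein_gene_map.tsv"))
  truth <- c(dataset$truth,
             list(control_chrom = ref$control_chrom,
                  seed = ref$config$seed))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(reference = p("reference.fa"), genes = p("genes.gff3"),
             sperm_fresh = p("sperm_fresh.cx.tsv"),
             sperm_stored = p("sperm_stored.cx.tsv"),
             embryo_fresh = p("embryo_fresh.cx.tsv"),
             embryo_stored = p("embryo_stored.cx.tsv"),
             deg = p("deg.tsv"), dep = p("dep.tsv"),
             gene_map = p("protein_gene_map.tsv"),
             truth = p("truth.json"))
  invisible(files)
}
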