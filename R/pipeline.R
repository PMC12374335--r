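# End-to-end pipeline and command-line interface.

#' Run the full demo pipeline
#'
#' simulate -> summarise methylomes -> call DMRs (sperm pair and embryo
#' pair) -> annotate to genes -> integrate (Venn strata + concordance
#' table).  Every output is plain text and reproducible from
#' `config$seed`; a `provenance.json` records parameters, package
#' version and input checksums.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory.
#' @param window_size,step,min_sites,fc_threshold,alpha,padjust DMR
#'   calling parameters (see [call_dmrs()]).
#' @param promoter_size,promoter_mode Annotation parameters (see
#'   [assign_dmrs_to_genes()]).
#' @return Invisibly, the list of written files.
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         window_size = 1000L, step = window_size,
                         min_sites = 5L, fc_threshold = 2, alpha = 0.05,
                         padjust = "none", promoter_size = 1000L,
                         promoter_mode = "upstream") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(outdir, x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ds <- stage("simulate", simulate_dataset(config))
  files <- stage("simulate", write_simulation(ds, outdir))
  chrom_lengths <- vapply(ds$reference$sequences, nchar, 1L)
  ctrl <- ds$reference$control_chrom

  summaries <- stage("summarize", data.table::rbindlist(lapply(
    list(ds$sperm$fresh, ds$sperm$stored, ds$embryo$fresh,
         ds$embryo$stored),
    sample_summary, control_chroms = ctrl)))
  write_tsv_table(summaries, p("methylome_summary.tsv"))

  # spike-in control sequences are for conversion-rate estimation only;
  # they are excluded from DMR calling
  drop_ctrl <- function(s) {
    methylome_sample(s$sites[s$sites$chrom != ctrl, , drop = FALSE],
                     sample_id = s$sample_id, group = s$group)
  }
  call_pair <- function(pair, label) {
    res <- stage(paste0("call-dmrs[", label, "]"),
                 call_dmrs(drop_ctrl(pair$fresh), drop_ctrl(pair$stored),
                           window_size = window_size, step = step,
                           min_sites = min_sites,
                           fc_threshold = fc_threshold, alpha = alpha,
                           padjust = padjust,
                           chrom_lengths = chrom_lengths))
    write_dmr_bed(res$dmrs, p(paste0(label, "_dmrs.bed")))
    write_tsv_table(res$summary, p(paste0(label, "_dmr_summary.tsv")))
    res
  }
  sperm_res <- call_pair(ds$sperm, "sperm")
  embryo_res <- call_pair(ds$embryo, "embryo")

  annotate_one <- function(res, label) {
    dmgs <- stage(paste0("annotate[", label, "]"),
                  assign_dmrs_to_genes(res$dmrs, ds$reference$genes,
                                       promoter_size = promoter_size,
                                       mode = promoter_mode,
                                       chrom_lengths = chrom_lengths))
    write_tsv_table(dmgs, p(paste0(label, "_dmgs.tsv")))
    dmgs
  }
  sperm_dmgs <- annotate_one(sperm_res, "sperm")
  embryo_dmgs <- annotate_one(embryo_res, "embryo")

  venn <- stage("integrate", venn_summary(sperm_dmgs, embryo_dmgs))
  write_tsv_table(venn, p("venn_summary.tsv"))
  degs <- stage("integrate", filter_degs(ds$tables$deg_table))
  deps <- stage("integrate",
                suppressMessages(filter_deps(ds$tables$dep_table,
                                             gene_map = ds$tables$gene_map)))
  conc <- stage("integrate",
                concordance_table(sperm_dmgs, embryo_dmgs, degs, deps))
  write_tsv_table(conc$rows, p("concordance.tsv"))
  write_tsv_table(conc$mixed, p("concordance_mixed.tsv"))

  prov <- list(
    package = "methinherit",
    version = as.character(utils::packageVersion("methinherit")),
    parameters = list(
      seed = config$seed, window_size = window_size, step = step,
      min_sites = min_sites, fc_threshold = fc_threshold, alpha = alpha,
      padjust = padjust, promoter_size = promoter_size,
      promoter_mode = promoter_mode,
      simulation = unclass(config)),
    input_checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(files = files, sperm = sperm_res, embryo = embryo_res,
                 sperm_dmgs = sperm_dmgs, embryo_dmgs = embryo_dmgs,
                 venn = venn, concordance = conc, outdir = outdir))
}

# ---------------------------------------------------------------------------
# Command-line interface.  Exit codes: 0 success, 2 usage error,
# 1 runtime error.

cli_usage <- function() {
  paste(
    "usage: methinherit <subcommand> [options]",
    "subcommands:",
    "  simulate   generate a synthetic multi-omics dataset",
    "  summarize  per-context methylation summary of a cytosine report",
    "  call-dmrs  window-based DMR calling between two reports",
    "  annotate   assign DMRs (BED) to gene bodies/promoters",
    "  integrate  Venn strata and concordance table",
    "  run-all    simulate + full pipeline",
    sep = "\n")
}

cli_condition <- function(status, msg) {
  structure(class = c("cli_exit", "condition"),
            list(message = msg, call = NULL, status = status))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `summarize`, `call-dmrs`,
#' `annotate`, `integrate` and `run-all`.  Designed to be called from a
#' wrapper script (see `inst/scripts/methinherit`); returns the exit
#' status (0 success, 2 usage error, 1 runtime error) instead of calling
#' `quit()` so it is testable in-process.
#'
#' @param argv Character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L || argv[1] %in% c("-h", "--help")) {
      message(cli_usage())
      return(invisible(if (length(argv)) 0L else 2L))
    }
    sub <- argv[1]
    rest <- argv[-1]
    handler <- switch(sub,
                      "simulate" = cli_simulate,
                      "summarize" = cli_summarize,
                      "call-dmrs" = cli_call_dmrs,
                      "annotate" = cli_annotate,
                      "integrate" = cli_integrate,
                      "run-all" = cli_run_all,
                      NULL)
    if (is.null(handler)) {
      message("unknown subcommand: ", sub, "\n", cli_usage())
      return(invisible(2L))
    }
    handler(rest)
    0L
  }, cli_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

usage_stop <- function(...) {
  stop(structure(class = c("cli_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

cli_parse <- function(args, option_list, required = character()) {
  parser <- optparse::OptionParser(option_list = option_list,
                                   add_help_option = TRUE)
  opt <- tryCatch(optparse::parse_args(parser, args = args),
                  error = function(e) usage_stop(conditionMessage(e)))
  for (r in required) {
    if (is.null(opt[[r]])) usage_stop("missing required option --",
                                      gsub("_", "-", r))
  }
  opt
}

require_file <- function(path, what) {
  if (!file.exists(path)) stop("missing ", what, ": ", path)
  path
}

cli_simulate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--outdir", type = "character"),
    optparse::make_option("--n-chroms", dest = "n_chroms",
                          type = "integer", default = 2L),
    optparse::make_option("--chrom-length", dest = "chrom_length",
                          type = "integer", default = 500000L),
    optparse::make_option("--n-genes", dest = "n_genes",
                          type = "integer", default = 200L),
    optparse::make_option("--n-dmrs", dest = "n_dmrs",
                          type = "integer", default = 100L),
    optparse::make_option("--n-degs", dest = "n_degs",
                          type = "integer", default = 20L)),
    required = "outdir")
  cfg <- simulation_config(seed = opt$seed, n_chroms = opt$n_chroms,
                           chrom_length = opt$chrom_length,
                           n_genes = opt$n_genes, n_dmrs = opt$n_dmrs,
                           n_degs = opt$n_degs, n_deps = opt$n_degs)
  ds <- simulate_dataset(cfg)
  files <- write_simulation(ds, opt$outdir)
  message("wrote ", length(files), " files to ", opt$outdir)
}

cli_summarize <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--report", type = "character"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--min-coverage", dest = "min_coverage",
                          type = "integer", default = 1L),
    optparse::make_option("--control-chroms", dest = "control_chroms",
                          type = "character", default = NULL)),
    required = c("report", "out"))
  sites <- read_cytosine_report(require_file(opt$report, "cytosine report"),
                                min_coverage = opt$min_coverage)
  sample <- methylome_sample(sites, sample_id = basename(opt$report))
  ctl <- if (!is.null(opt$control_chroms)) {
    strsplit(opt$control_chroms, ",")[[1]]
  } else NULL
  write_tsv_table(sample_summary(sample, control_chroms = ctl), opt$out)
}

cli_call_dmrs <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--report-a", dest = "report_a",
                          type = "character"),
    optparse::make_option("--report-b", dest = "report_b",
                          type = "character"),
    optparse::make_option("--out-bed", dest = "out_bed",
                          type = "character"),
    optparse::make_option("--summary-out", dest = "summary_out",
                          type = "character", default = NULL),
    optparse::make_option("--window-size", dest = "window_size",
                          type = "integer", default = 1000L),
    optparse::make_option("--step", type = "integer", default = NULL),
    optparse::make_option("--min-sites", dest = "min_sites",
                          type = "integer", default = 5L),
    optparse::make_option("--fold-change", dest = "fold_change",
                          type = "double", default = 2),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--padjust", type = "character",
                          default = "none"),
    optparse::make_option("--contexts", type = "character",
                          default = "CpG,CHG,CHH")),
    required = c("report_a", "report_b", "out_bed"))
  a <- methylome_sample(
    read_cytosine_report(require_file(opt$report_a, "report A")), "A")
  b <- methylome_sample(
    read_cytosine_report(require_file(opt$report_b, "report B")), "B")
  res <- call_dmrs(a, b, window_size = opt$window_size,
                   step = if (is.null(opt$step)) opt$window_size else
                     opt$step,
                   min_sites = opt$min_sites,
                   fc_threshold = opt$fold_change, alpha = opt$alpha,
                   contexts = strsplit(opt$contexts, ",")[[1]],
                   padjust = opt$padjust)
  write_dmr_bed(res$dmrs, opt$out_bed)
  if (!is.null(opt$summary_out)) {
    write_tsv_table(res$summary, opt$summary_out)
  }
}

cli_annotate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--dmrs", type = "character"),
    optparse::make_option("--genes", type = "character"),
    optparse::make_option("--format", type = "character",
                          default = "gff3"),
    optparse::make_option("--promoter-size", dest = "promoter_size",
                          type = "integer", default = 1000L),
    optparse::make_option("--promoter-mode", dest = "promoter_mode",
                          type = "character", default = "upstream"),
    optparse::make_option("--out", type = "character")),
    required = c("dmrs", "genes", "out"))
  dmrs <- read_dmr_bed(require_file(opt$dmrs, "DMR BED"))
  genes <- read_gene_models(require_file(opt$genes, "gene models"),
                            format = opt$format)
  dmgs <- assign_dmrs_to_genes(dmrs, genes,
                               promoter_size = opt$promoter_size,
                               mode = opt$promoter_mode)
  write_tsv_table(dmgs, opt$out)
}

cli_integrate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--sperm-dmgs", dest = "sperm_dmgs",
                          type = "character"),
    optparse::make_option("--embryo-dmgs", dest = "embryo_dmgs",
                          type = "character"),
    optparse::make_option("--degs", type = "character"),
    optparse::make_option("--deps", type = "character", default = NULL),
    optparse::make_option("--map", type = "character", default = NULL),
    optparse::make_option("--loose", action = "store_true",
                          default = FALSE),
    optparse::make_option("--outdir", type = "character")),
    required = c("sperm_dmgs", "embryo_dmgs", "degs", "outdir"))
  sperm <- read_tsv_table(require_file(opt$sperm_dmgs, "sperm DMG table"))
  embryo <- read_tsv_table(require_file(opt$embryo_dmgs,
                                        "embryo DMG table"))
  degs <- filter_degs(require_file(opt$degs, "DEG table"))
  deps <- if (!is.null(opt$deps)) {
    filter_deps(require_file(opt$deps, "DEP table"), gene_map = opt$map)
  } else NULL
  dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(venn_summary(sperm, embryo),
                  file.path(opt$outdir, "venn_summary.tsv"))
  conc <- concordance_table(sperm, embryo, degs, deps,
                            loose = opt$loose)
  write_tsv_table(conc$rows, file.path(opt$outdir, "concordance.tsv"))
  write_tsv_table(conc$mixed,
                  file.path(opt$outdir, "concordance_mixed.tsv"))
}

cli_run_all <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--outdir", type = "character"),
    optparse::make_option("--n-chroms", dest = "n_chroms",
                          type = "integer", default = 2L),
    optparse::make_option("--chrom-length", dest = "chrom_length",
                          type = "integer", default = 500000L),
    optparse::make_option("--n-genes", dest = "n_genes",
                          type = "integer", default = 200L),
    optparse::make_option("--n-dmrs", dest = "n_dmrs",
                          type = "integer", default = 100L),
    optparse::make_option("--n-degs", dest = "n_degs",
                          type = "integer", default = 20L),
    optparse::make_option("--window-size", dest = "window_size",
                          type = "integer", default = 1000L),
    optparse::make_option("--min-sites", dest = "min_sites",
                          type = "integer", default = 5L),
    optparse::make_option("--fold-change", dest = "fold_change",
                          type = "double", default = 2),
    optparse::make_option("--alpha", type = "double", default = 0.05)),
    required = "outdir")
  cfg <- simulation_config(seed = opt$seed, n_chroms = opt$n_chroms,
                           chrom_length = opt$chrom_length,
                           n_genes = opt$n_genes, n_dmrs = opt$n_dmrs,
                           n_degs = opt$n_degs, n_deps = opt$n_degs)
  run_pipeline(cfg, opt$outdir, window_size = opt$window_size,
               min_sites = opt$min_sites,
               fc_threshold = opt$fold_change, alpha = opt$alpha)
  message("pipeline complete: ", opt$outdir)
}
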