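# All on-disk <-> internal coordinate conversions live in this file.
# Internal convention: 0-based half-open intervals, 0-based site positions.
# On disk: cytosine reports and GFF3 are 1-based; BED is 0-based half-open.

#' Default column mapping of a cytosine report
#'
#' The canonical dialect is the Bismark-style "CX report": one row per
#' reference cytosine with columns chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count, context and (optionally)
#' the trinucleotide.  Other per-cytosine formats (e.g. methratio-style
#' output) can be read by passing a different mapping of column indices.
#'
#' @return Named integer vector of 1-based column indices.
#' @export
cx_report_columns <- function() {
  c(chrom = 1L, pos = 2L, strand = 3L, count_methylated = 4L,
    count_unmethylated = 5L, context = 6L, trinucleotide = 7L)
}

# Normalise context tokens to CpG/CHG/CHH; unknown tokens -> NA.
normalize_context <- function(x) {
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[up %in% c("CPG", "CG")] <- "CpG"
  out[up == "CHG"] <- "CHG"
  out[up == "CHH"] <- "CHH"
  out
}

#' Read a per-cytosine methylation report
#'
#' Parses a tab-separated cytosine report (default: Bismark CX dialect, see
#' [cx_report_columns()]) into a site table with internal 0-based positions.
#' The methylation level of a site is `n_meth / n_total`, i.e. the mC/C
#' ratio at that reference cytosine.
#'
#' @param path Path to the tab-separated report.
#' @param min_coverage Sites with `n_meth + n_unmeth < min_coverage` are
#'   dropped.  Default 1 (no floor beyond having at least one read).
#' @param columns Named integer vector mapping field names to column
#'   indices, as returned by [cx_report_columns()].  `trinucleotide` may be
#'   absent from the file.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_total` (and `trinucleotide` when present),
#'   sorted by (chrom, pos, strand).
#' @export
read_cytosine_report <- function(path, min_coverage = 1L,
                                 columns = cx_report_columns()) {
  stopifnot(length(path) == 1L, file.exists(path), min_coverage >= 0)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) == 0L) {
    return(empty_site_table())
  }
  need <- c("chrom", "pos", "strand", "count_methylated",
            "count_unmethylated", "context")
  if (ncol(raw) < max(columns[need])) {
    stop("cytosine report has ", ncol(raw), " columns; need at least ",
         max(columns[need]))
  }
  get_col <- function(name) raw[[columns[[name]]]]

  pos1 <- suppressWarnings(as.integer(get_col("pos")))
  nm <- suppressWarnings(as.integer(get_col("count_methylated")))
  nu <- suppressWarnings(as.integer(get_col("count_unmethylated")))
  strand <- get_col("strand")
  bad <- which(is.na(pos1) | pos1 < 1L | is.na(nm) | nm < 0L |
                 is.na(nu) | nu < 0L | !(strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed cytosine report line ", bad[1], " in ", path)
  }
  context <- normalize_context(get_col("context"))
  if (anyNA(context)) {
    stop("unknown context token at line ", which(is.na(context))[1],
         " in ", path)
  }
  sites <- data.table::data.table(
    chrom = get_col("chrom"), pos = pos1 - 1L, strand = strand,
    context = context, n_meth = nm, n_total = nm + nu)
  if (!is.na(columns["trinucleotide"]) &&
      ncol(raw) >= columns[["trinucleotide"]]) {
    sites[, trinucleotide := raw[[columns[["trinucleotide"]]]]]
  }
  sites <- sites[n_total >= min_coverage]
  if (is.unsorted_sites(sites)) {
    message("cytosine report ", path,
            " is not (chrom, pos)-sorted; sorting records")
  }
  data.table::setorder(sites, chrom, pos, strand)
  as.data.frame(sites)
}

empty_site_table <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             context = character(), n_meth = integer(), n_total = integer(),
             stringsAsFactors = FALSE)
}

is.unsorted_sites <- function(sites) {
  # radix = C locale, matching data.table::setorder
  o <- order(sites$chrom, sites$pos, sites$strand, method = "radix")
  !identical(o, seq_len(nrow(sites)))
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: emits the canonical tab-separated
#' dialect with 1-based positions.  `write` then `read` round-trips all
#' counts and contexts exactly.
#'
#' @param sites Site table (see [read_cytosine_report()]) or a
#'   `MethylomeSample`.
#' @param path Output path.
#' @export
write_cytosine_report <- function(sites, path) {
  if (inherits(sites, "MethylomeSample")) sites <- sites$sites
  out <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos + 1L, strand = sites$strand,
    n_meth = sites$n_meth, n_unmeth = sites$n_total - sites$n_meth,
    context = sites$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' Produces one record per gene with internal 0-based half-open transcript
#' span coordinates.  GFF3 input uses features of type `gene` when present;
#' otherwise transcript-level features are unioned per gene id (union span,
#' requiring a consistent strand).  BED input must carry a strand column
#' (BED6 or wider) because promoter derivation needs it.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start` (0-based inclusive), `tx_end` (exclusive).
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  genes <- if (format == "gff3") read_genes_gff3(path) else read_genes_bed(path)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene model without strand in ", path,
         " (promoter derivation requires strand)")
  }
  stopifnot(all(genes$tx_start < genes$tx_end))
  genes[order(genes$chrom, genes$tx_start, genes$gene_id), , drop = FALSE]
}

read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- if ("type" %in% colnames(md)) as.character(md$type) else
    rep("gene", length(gr))
  pick_id <- function(g) {
    m <- S4Vectors::mcols(g)
    for (f in c("gene_id", "ID", "Name", "locus_tag")) {
      if (f %in% colnames(m) && !all(is.na(m[[f]]))) {
        return(as.character(m[[f]]))
      }
    }
    stop("no gene identifier attribute found in ", path)
  }
  if (any(type == "gene")) {
    g <- gr[type == "gene"]
    data.frame(gene_id = pick_id(g),
               chrom = as.character(GenomicRanges::seqnames(g)),
               strand = as.character(GenomicRanges::strand(g)),
               tx_start = GenomicRanges::start(g) - 1L,
               tx_end = GenomicRanges::end(g),
               stringsAsFactors = FALSE)
  } else {
    # transcript-level only: union span per gene id
    ids <- pick_id(gr)
    dt <- data.table::data.table(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      s = GenomicRanges::start(gr) - 1L, e = GenomicRanges::end(gr))
    un <- dt[, {
      if (length(unique(strand)) != 1L || length(unique(chrom)) != 1L)
        stop("inconsistent strand/chrom for gene ", gene_id[1])
      list(chrom = chrom[1], strand = strand[1],
           tx_start = min(s), tx_end = max(e))
    }, by = gene_id]
    as.data.frame(un)
  }
}

read_genes_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) {
    stop("BED gene input ", path, " lacks a strand column (need BED6+)")
  }
  data.frame(gene_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             strand = as.character(bed[[6]]),
             tx_start = as.integer(bed[[2]]), tx_end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits minimal `gene` features (1-based inclusive, per the GFF3 spec)
#' from the internal 0-based representation.
#'
#' @param genes Gene model table (see [read_gene_models()]).
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\tmethinherit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$tx_start + 1L, genes$tx_end,
                     genes$strand, genes$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write DMRs to BED6+
#'
#' BED columns: chrom, start, end (0-based half-open), name = direction
#' (`hyper`/`hypo`), score = -log10(P) capped at 1000, strand = `.`,
#' then context, level_A, level_B and fold_change as extra columns.
#'
#' @param dmrs DMR table as produced by [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- -log10(dmrs$p_value)
  score[!is.finite(score) | score > 1000] <- 1000
  out <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$direction, score = signif(score, 6), strand = ".",
    context = dmrs$context,
    level_A = signif(dmrs$level_A, 6), level_B = signif(dmrs$level_B, 6),
    fold_change = signif(dmrs$fold_change, 6))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6+ DMR file written by [write_dmr_bed()]
#'
#' @param path Path to the BED file.
#' @return DMR table with columns `chrom`, `start`, `end`, `direction`,
#'   `p_value` (back-computed from the score; capped values come back as
#'   `1e-1000` i.e. 0), `context`, `level_A`, `level_B`, `fold_change`.
#' @export
read_dmr_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      p_value = numeric(), context = character(),
                      level_A = numeric(), level_B = numeric(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(ncol(bed) >= 10L)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), direction = as.character(bed[[4]]),
             p_value = 10^(-as.numeric(bed[[5]])),
             context = as.character(bed[[7]]),
             level_A = as.numeric(bed[[8]]), level_B = as.numeric(bed[[9]]),
             fold_change = as.numeric(bed[[10]]), stringsAsFactors = FALSE)
}

# Deterministic TSV writer used by all table outputs.
write_tsv_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
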