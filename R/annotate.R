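# DMR -> gene assignment: gene bodies and promoters.
#
# Gene body = full transcript span [tx_start, tx_end).  Promoter = the
# 1-kb region at the transcription start site; by default upstream-only
# (`mode = "upstream"`), optionally 1 kb on each side (`mode = "both"`).
# Overlap rule is >= 1 bp on half-open intervals, so abutting intervals
# do not overlap.

#' Derive promoter intervals from gene models
#'
#' Upstream mode (default): for a `+` strand gene the promoter is
#' `[tx_start - size, tx_start)`; for a `-` strand gene it is
#' `[tx_end, tx_end + size)`.  `mode = "both"` extends `size` bp on each
#' side of the TSS.  Intervals are clipped to `[0, chrom_length)`.
#'
#' @param genes Gene model table (see [read_gene_models()]).
#' @param promoter_size Promoter width in bp (default 1000).
#' @param mode `"upstream"` or `"both"`.
#' @param chrom_lengths Optional named vector for right clipping.
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_interval <- function(genes, promoter_size = 1000L,
                              mode = c("upstream", "both"),
                              chrom_lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(promoter_size > 0)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  if (mode == "upstream") {
    start <- ifelse(genes$strand == "+", tss - promoter_size, tss)
    end <- ifelse(genes$strand == "+", tss, tss + promoter_size)
  } else {
    start <- tss - promoter_size
    end <- tss + promoter_size
  }
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, unname(chrom_lengths[genes$chrom]))
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  out[out$start < out$end, , drop = FALSE]
}

#' Assign DMRs to gene bodies and promoters
#'
#' A DMR overlapping a gene's `[tx_start, tx_end)` by at least 1 bp yields
#' a (gene, `gene_body`, direction) record; a DMR overlapping the gene's
#' promoter yields a (gene, `promoter`, direction) record.  A gene may
#' carry both directions (through distinct DMRs) and both region classes.
#' Records are de-duplicated on (gene, region_class, direction) with
#' supporting DMR ids accumulated.
#'
#' @param dmrs DMR table (from [call_dmrs()]'s `$dmrs` or
#'   [read_dmr_bed()]); needs `chrom`, `start`, `end`, `direction`.
#' @param genes Gene model table.
#' @param promoter_size,mode Passed to [promoter_interval()].
#' @param chrom_lengths Optional named chromosome lengths.
#' @return `data.frame` of DMR-associated gene (DMG) records: `gene_id`,
#'   `region_class`, `direction`, `n_supporting_dmrs`, `dmr_ids`
#'   (comma-separated `chrom:start-end` identifiers).
#' @export
assign_dmrs_to_genes <- function(dmrs, genes, promoter_size = 1000L,
                                 mode = c("upstream", "both"),
                                 chrom_lengths = NULL) {
  mode <- match.arg(mode)
  dmrs <- as.data.frame(dmrs)
  if (nrow(dmrs) == 0L) return(empty_dmg_table())
  unknown <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("DMRs on sequences absent from the gene models are left ",
            "unassigned: ", paste(unknown, collapse = ", "))
  }
  dmr_gr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  dmr_id <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end)

  hit_records <- function(intervals, region_class) {
    if (nrow(intervals) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start + 1L,
                                        intervals$end))
    # seqlevel-merge chatter is redundant with the unassigned warning above
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(dmr_gr, gr, minoverlap = 1L,
                                  ignore.strand = TRUE))
    if (length(ov) == 0L) return(NULL)
    data.table::data.table(
      gene_id = intervals$gene_id[S4Vectors::subjectHits(ov)],
      region_class = region_class,
      direction = dmrs$direction[S4Vectors::queryHits(ov)],
      dmr_id = dmr_id[S4Vectors::queryHits(ov)])
  }
  body <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = genes$tx_start, end = genes$tx_end,
                     stringsAsFactors = FALSE)
  prom <- promoter_interval(genes, promoter_size, mode, chrom_lengths)
  hits <- data.table::rbindlist(list(
    hit_records(body, "gene_body"), hit_records(prom, "promoter")))
  if (is.null(hits) || nrow(hits) == 0L) return(empty_dmg_table())
  hits <- unique(hits)
  out <- hits[, .(n_supporting_dmrs = .N,
                  dmr_ids = paste(sort(dmr_id), collapse = ",")),
              by = .(gene_id, region_class, direction)]
  data.table::setorder(out, gene_id, region_class, direction)
  as.data.frame(out)
}

empty_dmg_table <- function() {
  data.frame(gene_id = character(), region_class = character(),
             direction = character(), n_supporting_dmrs = integer(),
             dmr_ids = character(), stringsAsFactors = FALSE)
}

#' Extract a directional DMG gene set
#'
#' @param records DMG record table from [assign_dmrs_to_genes()].
#' @param region_class `"gene_body"` or `"promoter"`.
#' @param direction `"hyper"` or `"hypo"`.
#' @return Character vector of unique gene ids in the stratum.
#' @export
dmg_sets <- function(records, region_class = c("gene_body", "promoter"),
                     direction = c("hyper", "hypo")) {
  region_class <- match.arg(region_class)
  direction <- match.arg(direction)
  sel <- records$region_class == region_class &
    records$direction == direction
  sort(unique(records$gene_id[sel]))
}
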