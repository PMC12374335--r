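# Cross-generation and cross-omics integration.

read_table_arg <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    read_tsv_table(table)
  } else {
    as.data.frame(table)
  }
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps genes with `q_value <= q_threshold` and a fold change of at least
#' `fc_threshold` in either direction (`fold_change >= fc_threshold` is
#' "up"; `fold_change <= 1/fc_threshold` is "down").
#'
#' @param table `data.frame` or path to a TSV with columns `gene_id`,
#'   `fold_change`, `q_value`.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param q_threshold Corrected-P (Q value) threshold (default 0.001).
#' @param log2_fc Set TRUE when `fold_change` is on the log2 scale.
#' @return The passing records with a `direction` column (`up`/`down`).
#' @export
filter_degs <- function(table, fc_threshold = 2, q_threshold = 0.001,
                        log2_fc = FALSE) {
  df <- read_table_arg(table)
  need <- c("gene_id", "fold_change", "q_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fc <- df$fold_change
  if (log2_fc) fc <- 2^fc
  if (any(!is.finite(fc) | fc <= 0)) {
    stop("non-positive fold change in expression table")
  }
  keep <- df$q_value <= q_threshold &
    (fc >= fc_threshold | fc <= 1 / fc_threshold)
  out <- df[keep, , drop = FALSE]
  out$fold_change <- fc[keep]
  out$direction <- ifelse(out$fold_change >= fc_threshold, "up", "down")
  rownames(out) <- NULL
  out
}

#' Filter a differential-protein table to significant proteins
#'
#' Same shape as [filter_degs()] but keyed by `protein_id` with an FDR
#' column `adj_p`; default thresholds `|fold change| >= 1.3` and
#' `adj_p <= 0.05` (set `fc_threshold = 1.5` for the stricter variant).
#' Proteins are mapped to genes through `gene_map`; unmapped proteins are
#' kept with `gene_id = NA` and reported via a message and the
#' `"unmapped"` attribute, never silently dropped.
#'
#' @param table `data.frame` or TSV path with `protein_id`, `fold_change`,
#'   `adj_p` (an optional `gene_id` column is used when no map is given).
#' @param fc_threshold Fold-change threshold (default 1.3).
#' @param alpha Adjusted-P threshold (default 0.05).
#' @param gene_map Optional `data.frame`/TSV path with columns
#'   `protein_id`, `gene_id`.
#' @return Passing records with `direction` and `gene_id` columns.
#' @export
filter_deps <- function(table, fc_threshold = 1.3, alpha = 0.05,
                        gene_map = NULL) {
  df <- read_table_arg(table)
  need <- c("protein_id", "fold_change", "adj_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$fold_change) | df$fold_change <= 0)) {
    stop("non-positive fold change in protein table")
  }
  keep <- df$adj_p <= alpha &
    abs(log2(df$fold_change)) >= log2(fc_threshold)
  out <- df[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change >= 1, "up", "down")
  if (!is.null(gene_map)) {
    gm <- read_table_arg(gene_map)
    out$gene_id <- gm$gene_id[match(out$protein_id, gm$protein_id)]
  } else if (!"gene_id" %in% names(out)) {
    out$gene_id <- NA_character_
  }
  unmapped <- out$protein_id[is.na(out$gene_id)]
  if (length(unmapped)) {
    message(length(unmapped), " significant protein(s) without a gene ",
            "mapping: ", paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ..." else "")
  }
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Partition two DMG sets into shared/unique genes
#'
#' @param setA,setB Character vectors of gene ids from the same
#'   (region_class, direction) stratum of two samples.
#' @return List with `shared`, `only_a`, `only_b` and a `sizes` vector
#'   suitable for Venn rendering.
#' @export
shared_dmgs <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- sort(intersect(setA, setB))
  only_a <- sort(setdiff(setA, setB))
  only_b <- sort(setdiff(setB, setA))
  list(shared = shared, only_a = only_a, only_b = only_b,
       sizes = c(only_a = length(only_a), shared = length(shared),
                 only_b = length(only_b)))
}

#' Venn summary over all four DMG strata
#'
#' Applies [shared_dmgs()] to each (region_class, direction) stratum of
#' two DMG record tables (e.g. sperm vs derived embryos).
#'
#' @param records_a,records_b DMG tables from [assign_dmrs_to_genes()].
#' @return `data.frame` with columns `region_class`, `direction`,
#'   `only_a`, `shared`, `only_b`.
#' @export
venn_summary <- function(records_a, records_b) {
  out <- expand.grid(region_class = c("gene_body", "promoter"),
                     direction = c("hyper", "hypo"),
                     stringsAsFactors = FALSE)
  sizes <- t(apply(out, 1, function(row) {
    shared_dmgs(dmg_sets(records_a, row[["region_class"]],
                         row[["direction"]]),
                dmg_sets(records_b, row[["region_class"]],
                         row[["direction"]]))$sizes
  }))
  cbind(out, as.data.frame(sizes))
}

# Gene-level methylation direction from DMG records.  Gene-body records
# take precedence; promoter-only support falls back with a region note.
# A gene whose supporting region class carries both directions is "mixed".
gene_meth_direction <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    return(data.frame(gene_id = character(), meth = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  per_gene <- dt[, {
    body_dirs <- unique(direction[region_class == "gene_body"])
    prom_dirs <- unique(direction[region_class == "promoter"])
    if (length(body_dirs)) {
      used <- body_dirs; cls <- "gene body"
    } else {
      used <- prom_dirs; cls <- "promoter"
    }
    meth <- if (length(used) > 1L) "mixed" else
      c(hyper = "up", hypo = "down")[used]
    note <- if (meth == "mixed") paste(cls, "mixed") else
      paste(cls, used)
    list(meth = unname(meth), note = note)
  }, by = gene_id]
  as.data.frame(per_gene)
}

#' Cross-omics direction-concordance table
#'
#' Builds one row per gene found in the sperm DMGs, the embryo DMGs and
#' the differentially expressed genes (strict mode: the triple
#' intersection), recording the methylation direction in each generation
#' and the mRNA (and optionally protein) direction.  With `loose = TRUE`
#' genes present in any two of the three layers are also included.  Genes
#' with both hyper and hypo support in one layer are annotated `mixed`
#' and returned separately.
#'
#' @param sperm_dmgs,embryo_dmgs DMG record tables
#'   ([assign_dmrs_to_genes()]).
#' @param degs Filtered expression records ([filter_degs()]).
#' @param deps Optional filtered protein records ([filter_deps()]).
#' @param loose Include genes present in only two layers.
#' @return List of class `concordance`: `rows` (clean directional rows
#'   with columns `gene_id`, `sperm_meth`, `embryo_meth`, `mrna`,
#'   `protein`, `region_notes`) and `mixed` (rows where a methylation
#'   layer is direction-mixed).
#' @export
concordance_table <- function(sperm_dmgs, embryo_dmgs, degs, deps = NULL,
                              loose = FALSE) {
  sp <- gene_meth_direction(sperm_dmgs)
  em <- gene_meth_direction(embryo_dmgs)
  dg <- as.data.frame(degs)
  layers <- list(sp$gene_id, em$gene_id, dg$gene_id)
  genes <- if (loose) {
    counts <- table(unlist(lapply(layers, unique)))
    sort(names(counts)[counts >= 2])
  } else {
    sort(Reduce(intersect, layers))
  }
  look <- function(tab, ids, col) tab[[col]][match(ids, tab$gene_id)]
  rows <- data.frame(
    gene_id = genes,
    sperm_meth = or_none(look(sp, genes, "meth")),
    embryo_meth = or_none(look(em, genes, "meth")),
    mrna = or_none(dg$direction[match(genes, dg$gene_id)]),
    stringsAsFactors = FALSE)
  rows$protein <- if (!is.null(deps)) {
    dp <- as.data.frame(deps)
    or_none(dp$direction[match(genes, dp$gene_id)])
  } else "none"
  notes <- paste0(
    ifelse(is.na(look(sp, genes, "note")), "",
           paste0("sperm: ", look(sp, genes, "note"))),
    ifelse(is.na(look(em, genes, "note")), "",
           paste0("; embryo: ", look(em, genes, "note"))))
  rows$region_notes <- sub("^; ", "", notes)
  is_mixed <- rows$sperm_meth == "mixed" | rows$embryo_meth == "mixed"
  structure(list(rows = rows[!is_mixed, , drop = FALSE],
                 mixed = rows[is_mixed, , drop = FALSE]),
            class = "concordance")
}

or_none <- function(x) ifelse(is.na(x), "none", x)

#' @export
print.concordance <- function(x, ...) {
  cat("concordance table:", nrow(x$rows), "gene(s)",
      if (nrow(x$mixed)) paste0("(+", nrow(x$mixed), " direction-mixed)")
      else "", "\n")
  print(x$rows, row.names = FALSE)
  invisible(x)
}
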