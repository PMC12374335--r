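# Per-site and global methylation arithmetic.

#' Construct a methylome sample
#'
#' A `MethylomeSample` bundles a site table (one row per covered reference
#' cytosine, counts kept per strand) with a sample identifier and a group
#' label (e.g. `fresh`, `stored`, `embryo_fresh`, `embryo_stored`).
#' Sites are sorted by (chrom, pos, strand) on construction.
#'
#' @param sites Site table with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_total`.
#' @param sample_id Unique sample identifier.
#' @param group Condition/generation label.
#' @return An object of class `MethylomeSample`.
#' @export
methylome_sample <- function(sites, sample_id, group = sample_id) {
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  if (!all(need %in% names(sites))) {
    stop("site table must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(sites$n_meth >= 0), all(sites$n_meth <= sites$n_total),
            all(sites$context %in% c("CpG", "CHG", "CHH")),
            all(sites$strand %in% c("+", "-")))
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sample_id = sample_id, group = group, sites = sites),
            class = "MethylomeSample")
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat("MethylomeSample", x$sample_id, "(group:", x$group, ")\n")
  cat("  ", nrow(x$sites), "sites on",
      length(unique(x$sites$chrom)), "sequences\n")
  tab <- table(x$sites$context)
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

as_site_table <- function(x) {
  if (inherits(x, "MethylomeSample")) x$sites else as.data.frame(x)
}

#' Classify the sequence context of a reference position
#'
#' Looks at the strand-oriented base at `pos` and the two following bases
#' (reverse-complemented for `-`): returns `"CpG"` if the next base is G,
#' `"CHG"` for C-H-G, `"CHH"` for C-H-H (H = A, C or T), and
#' `"not_cytosine"` if the oriented base is not a C.  Ambiguous reference
#' bases (N) in the lookahead give `NA`.
#'
#' @param reference Named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences.
#' @param chrom Chromosome name (recycled).
#' @param pos 0-based position(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @param end_policy What to do when the context is undeterminable because
#'   the oriented lookahead runs off the sequence end: `"error"` (default)
#'   or `"truncate_as_CHH"` which returns `"CHH"` for those positions.
#' @return Character vector of contexts.
#' @export
classify_context <- function(reference, chrom, pos, strand,
                             end_policy = c("error", "truncate_as_CHH")) {
  end_policy <- match.arg(end_policy)
  seqs <- reference_as_character(reference)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[[chrom[i]]]
    L <- nchar(s)
    p <- pos[i]
    if (p < 0 || p >= L) stop("position ", p, " outside ", chrom[i])
    base_at <- function(j) {
      if (j < 0 || j >= L) return(NA_character_)
      substr(s, j + 1L, j + 1L)
    }
    if (strand[i] == "+") {
      b0 <- base_at(p); b1 <- base_at(p + 1L); b2 <- base_at(p + 2L)
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      b0 <- unname(comp[base_at(p)])
      b1 <- unname(comp[base_at(p - 1L)])
      b2 <- unname(comp[base_at(p - 2L)])
    }
    out[i] <- classify_triplet(b0, b1, b2, end_policy)
  }
  out
}

classify_triplet <- function(b0, b1, b2, end_policy) {
  if (is.na(b0) || b0 != "C") {
    if (identical(b0, "N")) return(NA_character_)
    return("not_cytosine")
  }
  if (!is.na(b1) && b1 == "G") return("CpG")
  if (is.na(b1) || (!is.na(b1) && b1 == "N")) {
    if (end_policy == "truncate_as_CHH" && is.na(b1)) return("CHH")
    if (is.na(b1)) stop("context undeterminable at sequence end ",
                        "(set end_policy = \"truncate_as_CHH\" to coerce)")
    return(NA_character_)  # N lookahead: excluded
  }
  # b1 is H
  if (is.na(b2)) {
    if (end_policy == "truncate_as_CHH") return("CHH")
    stop("context undeterminable at sequence end ",
         "(set end_policy = \"truncate_as_CHH\" to coerce)")
  }
  if (b2 == "G") return("CHG")
  if (b2 == "N") return(NA_character_)
  "CHH"
}

reference_as_character <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    stopifnot(is.character(reference), !is.null(names(reference)))
    reference
  }
}

# Enumerate every determinable cytosine site of one sequence, both strands.
# Positions within 2 bp of the oriented end whose context cannot be decided
# are excluded, as are sites whose lookahead contains N.
site_contexts <- function(seq_string) {
  ch <- strsplit(seq_string, "")[[1]]
  L <- length(ch)
  pad <- c(ch, NA, NA)
  plus <- which(ch == "C")
  ctx_p <- triplet_context_vec(pad[plus + 1L], pad[plus + 2L])
  # minus strand: plus-strand G, lookahead leftwards, complemented
  pad2 <- c(NA, NA, ch)
  minus <- which(ch == "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  m1 <- unname(comp[pad2[minus + 1L]])  # base at pos-1, complemented
  m2 <- unname(comp[pad2[minus]])       # base at pos-2, complemented
  ctx_m <- triplet_context_vec(m1, m2)
  res <- rbind(
    data.frame(pos = plus - 1L, strand = "+", context = ctx_p,
               stringsAsFactors = FALSE),
    data.frame(pos = minus - 1L, strand = "-", context = ctx_m,
               stringsAsFactors = FALSE))
  res <- res[!is.na(res$context), , drop = FALSE]
  res[order(res$pos, res$strand), , drop = FALSE]
}

triplet_context_vec <- function(b1, b2) {
  ctx <- rep(NA_character_, length(b1))
  ctx[!is.na(b1) & b1 == "G"] <- "CpG"
  h1 <- !is.na(b1) & b1 %in% c("A", "C", "T")
  ctx[h1 & !is.na(b2) & b2 == "G"] <- "CHG"
  ctx[h1 & !is.na(b2) & b2 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

#' Merge complementary CpG strand counts
#'
#' Each CpG pair (`+` at position p, `-` at p+1) is collapsed to a single
#' `+` site at p with summed counts.  Unpaired CpG sites and all CHG/CHH
#' sites are left untouched.  Total methylated and total reads per
#' chromosome are conserved.
#'
#' @param sample A `MethylomeSample`.
#' @return A new `MethylomeSample` with merged CpG sites.
#' @export
merge_cpg_strands <- function(sample) {
  dt <- data.table::as.data.table(as_site_table(sample))
  cpg_p <- dt[context == "CpG" & strand == "+"]
  cpg_m <- dt[context == "CpG" & strand == "-"]
  rest <- dt[context != "CpG"]
  cpg_m[, mpos := pos - 1L]
  merged <- merge(cpg_p, cpg_m[, .(chrom, mpos, m_meth = n_meth,
                                   m_total = n_total)],
                  by.x = c("chrom", "pos"), by.y = c("chrom", "mpos"),
                  all.x = TRUE)
  merged[!is.na(m_meth), `:=`(n_meth = n_meth + m_meth,
                              n_total = n_total + m_total)]
  paired_mpos <- merged[!is.na(m_meth), paste(chrom, pos)]
  unpaired_m <- cpg_m[!paste(chrom, mpos) %in% paired_mpos]
  unpaired_m[, mpos := NULL]
  merged[, c("m_meth", "m_total") := NULL]
  out <- data.table::rbindlist(list(merged, unpaired_m, rest),
                               use.names = TRUE)
  methylome_sample(out, sample_id = sample$sample_id, group = sample$group)
}
utils::globalVariables(c("m_meth", "m_total", "trinucleotide"))

#' Per-context genome-wide methylation summaries
#'
#' For each of CpG, CHG and CHH reports the number of covered sites, the
#' pooled level (sum of methylated reads over sum of total reads) and the
#' mean of per-site levels.  A context with no covered sites gets
#' `n_sites_covered = 0` and `NA` levels.
#'
#' @param sample A `MethylomeSample` or site table.
#' @return `data.frame` with one row per context.
#' @export
context_summaries <- function(sample) {
  dt <- data.table::as.data.table(as_site_table(sample))
  dt <- dt[n_total > 0]
  sm <- dt[, .(n_sites_covered = .N,
               pooled_level = sum(n_meth) / sum(n_total),
               mean_site_level = mean(n_meth / n_total)),
           by = context]
  all_ctx <- data.table::data.table(context = c("CpG", "CHG", "CHH"))
  sm <- merge(all_ctx, sm, by = "context", all.x = TRUE, sort = FALSE)
  sm[is.na(n_sites_covered), n_sites_covered := 0L]
  as.data.frame(sm)
}
utils::globalVariables(c("n_sites_covered"))

#' Estimate the bisulphite conversion rate
#'
#' Uses sites on designated unmethylated control sequences (e.g. a lambda
#' spike-in or an unmethylated control contig): every methylated call there
#' is a conversion failure, so the rate is
#' `1 - sum(n_meth) / sum(n_total)` over all contexts on those sequences.
#'
#' @param sample A `MethylomeSample` or site table.
#' @param control_chroms Character vector of control sequence names.
#' @return Conversion rate in `[0, 1]`.
#' @export
conversion_rate <- function(sample, control_chroms) {
  sites <- as_site_table(sample)
  ctl <- sites[sites$chrom %in% control_chroms & sites$n_total > 0, ,
               drop = FALSE]
  if (nrow(ctl) == 0L || sum(ctl$n_total) == 0L) {
    stop("no covered sites on control sequences: ",
         paste(control_chroms, collapse = ", "))
  }
  1 - sum(ctl$n_meth) / sum(ctl$n_total)
}

#' Per-sample summary table
#'
#' Convenience wrapper combining [context_summaries()] and (optionally)
#' [conversion_rate()] into one exportable row set.
#'
#' @param sample A `MethylomeSample`.
#' @param control_chroms Optional control sequence names for the
#'   conversion-rate column.
#' @return `data.frame` with sample id, per-context summaries and the
#'   conversion rate (NA when no controls given).
#' @export
sample_summary <- function(sample, control_chroms = NULL) {
  sm <- context_summaries(sample)
  rate <- if (!is.null(control_chroms)) {
    conversion_rate(sample, control_chroms)
  } else NA_real_
  cbind(sample_id = sample$sample_id, group = sample$group, sm,
        conversion_rate = rate)
}
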