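# Window-based differential methylation calling.
#
# A DMR here is a genomic window that (i) contains at least `min_sites`
# covered sites of one context in EACH sample, (ii) changes its pooled
# methylation level at least `fc_threshold`-fold between the two samples,
# and (iii) has a two-sided Fisher exact P below `alpha` for the pooled
# 2x2 table [[meth_A, unmeth_A], [meth_B, unmeth_B]].  "hyper" means
# higher methylation in group B (the treated/stored sample).

FC_EPS <- 1e-6  # pseudo-level guarding fold changes against zero levels

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided P for the table `[[a, b], [c, d]]`, computed as the sum
#' of hypergeometric point probabilities (fixed margins) not exceeding that
#' of the observed table, with a relative tolerance of 1e-7 for ties.
#' Probabilities are evaluated in log space so large counts are safe.
#' Degenerate margins (a one-dimensional table) give P = 1.
#'
#' Vectorised over `a`, `b`, `c`, `d`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return P value(s) in `[0, 1]`.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- fisher_p_one(a[i], b[i], c[i], d[i])
  }
  out
}

fisher_p_one <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  N <- a + b + c + d
  if (N == 0) stop("empty 2x2 table")
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  lo <- max(0, r1 - (N - c1))
  hi <- min(r1, c1)
  k <- lo:hi
  lp <- stats::dhyper(k, c1, N - c1, r1, log = TRUE)
  lobs <- stats::dhyper(a, c1, N - c1, r1, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + log1p(1e-7)])))
}

# Map site positions to window indices.  Window k spans
# [k*step, k*step + window_size); with step < window_size a site belongs
# to several windows.
window_aggregate <- function(sites, window_size, step, context_sel) {
  dt <- data.table::as.data.table(sites)
  dt <- dt[context == context_sel & n_total > 0]
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), win = integer(),
                                  n_sites = integer(), meth = integer(),
                                  unmeth = integer()))
  }
  kmax <- dt$pos %/% step
  kmin <- pmax(0L, (dt$pos - window_size) %/% step + 1L)
  reps <- kmax - kmin + 1L
  idx <- rep(seq_len(nrow(dt)), reps)
  wins <- rep(kmin, reps) + (sequence(reps) - 1L)
  ex <- dt[idx]
  ex[, win := wins]
  ex[, .(n_sites = .N, meth = sum(n_meth), unmeth = sum(n_total - n_meth)),
     by = .(chrom, win)]
}

infer_chrom_lengths <- function(..., chrom_lengths = NULL) {
  tables <- lapply(list(...), as_site_table)
  sites <- data.table::rbindlist(lapply(tables, function(s)
    data.table::data.table(chrom = s$chrom, pos = s$pos)))
  inferred <- sites[, .(len = max(pos) + 1L), by = chrom]
  out <- stats::setNames(inferred$len, inferred$chrom)
  if (!is.null(chrom_lengths)) {
    out[names(chrom_lengths)] <- chrom_lengths
  }
  out
}

#' Tile covered windows over a sample
#'
#' Tiles each chromosome into `[k*step, k*step + window_size)` windows,
#' clipped at the chromosome end, and returns the windows that contain at
#' least one covered site of `context`.
#'
#' @param sample `MethylomeSample` or site table.
#' @param window_size Window width in bp (> 0).
#' @param step Tiling step (> 0, <= `window_size` gives overlapping or
#'   non-overlapping tiles).
#' @param context One of `"CpG"`, `"CHG"`, `"CHH"`.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clip the last window; defaults to `max(pos) + 1` per chromosome.
#' @return `data.frame` of window skeletons: `chrom`, `start`, `end`,
#'   `context`, `n_sites`.
#' @export
make_windows <- function(sample, window_size = 1000L, step = window_size,
                         context = c("CpG", "CHG", "CHH"),
                         chrom_lengths = NULL) {
  context <- match.arg(context)
  stopifnot(window_size > 0, step > 0, step <= window_size)
  sites <- as_site_table(sample)
  lens <- infer_chrom_lengths(sites, chrom_lengths = chrom_lengths)
  agg <- window_aggregate(sites, window_size, step, context)
  if (nrow(agg) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  agg[, start := win * step]
  agg[, end := pmin(start + window_size, lens[chrom])]
  ctx_label <- context
  out <- agg[, .(chrom, start, end, context = ctx_label, n_sites)]
  data.table::setorder(out, chrom, start)
  as.data.frame(out)
}

#' Test one window for differential methylation
#'
#' Pools counts of the window's context sites per sample and applies the
#' Fisher + fold-change rule.  Returns the string `"skipped"` when either
#' sample has fewer than `min_sites` covered sites in the window or when
#' both pooled totals are zero.
#'
#' @param window One-row window skeleton (list or data.frame row) with
#'   `chrom`, `start`, `end`, `context`.
#' @param A,B `MethylomeSample`s (A = control/fresh, B = treated/stored).
#' @param min_sites Minimum covered context sites per sample (default 5).
#' @param fc_threshold Fold-change threshold on pooled levels (default 2).
#' @param alpha Significance threshold on the Fisher P (default 0.05).
#' @return One-row `data.frame` (a tested window; `direction` is NA when
#'   the window is not a DMR) or `"skipped"`.
#' @export
test_window <- function(window, A, B, min_sites = 5L, fc_threshold = 2,
                        alpha = 0.05) {
  stopifnot(min_sites >= 1L, fc_threshold > 1, alpha > 0, alpha < 1)
  grab <- function(s) {
    st <- as_site_table(s)
    st[st$chrom == window$chrom & st$pos >= window$start &
         st$pos < window$end & st$context == window$context &
         st$n_total > 0, , drop = FALSE]
  }
  sa <- grab(A); sb <- grab(B)
  if (nrow(sa) < min_sites || nrow(sb) < min_sites) return("skipped")
  ma <- sum(sa$n_meth); ua <- sum(sa$n_total) - ma
  mb <- sum(sb$n_meth); ub <- sum(sb$n_total) - mb
  if (ma + ua == 0 && mb + ub == 0) return("skipped")
  la <- ma / (ma + ua)
  lb <- mb / (mb + ub)
  fc <- (lb + FC_EPS) / (la + FC_EPS)
  p <- fisher_exact_two_sided(ma, ua, mb, ub)
  dir <- dmr_direction(p, fc, fc_threshold, alpha)
  data.frame(chrom = window$chrom, start = window$start, end = window$end,
             context = window$context, n_sites_A = nrow(sa),
             n_sites_B = nrow(sb), meth_A = ma, unmeth_A = ua,
             meth_B = mb, unmeth_B = ub, level_A = la, level_B = lb,
             fold_change = fc, p_value = p, q_value = p, direction = dir,
             stringsAsFactors = FALSE)
}

dmr_direction <- function(p, fc, fc_threshold, alpha) {
  data.table::fifelse(
    p < alpha & fc >= fc_threshold, "hyper",
    data.table::fifelse(p < alpha & fc <= 1 / fc_threshold, "hypo",
                        NA_character_))
}

#' Call differentially methylated regions between two methylomes
#'
#' For each requested context the genome is tiled into windows
#' ([make_windows()] geometry), windows with at least `min_sites` covered
#' context sites in each sample are tested (pooled counts, two-sided
#' Fisher exact test), and windows meeting both the significance and the
#' fold-change criterion are reported as DMRs.  `direction = "hyper"`
#' means higher methylation in `B`.
#'
#' @param A,B `MethylomeSample`s covering the same reference
#'   (A = control/fresh, B = treated/stored).
#' @param window_size,step Window geometry in bp; default non-overlapping
#'   1000-bp tiles.
#' @param min_sites Minimum covered context sites per sample per window.
#' @param fc_threshold Fold-change threshold on pooled window levels.
#' @param alpha Significance threshold (applied to `q_value`, which equals
#'   the raw P under `padjust = "none"`).
#' @param contexts Contexts to scan.
#' @param padjust `"none"` (default; the criterion is the raw Fisher P) or
#'   `"bh"` for Benjamini-Hochberg within context.
#' @param chrom_lengths Optional named chromosome lengths for end clipping.
#' @return A list of class `dmr_result`: `dmrs` (the called DMRs, sorted),
#'   `tests` (every tested window), `summary` (per-context tested/hyper/
#'   hypo counts) and `params`.
#' @export
call_dmrs <- function(A, B, window_size = 1000L, step = window_size,
                      min_sites = 5L, fc_threshold = 2, alpha = 0.05,
                      contexts = c("CpG", "CHG", "CHH"),
                      padjust = c("none", "bh"), chrom_lengths = NULL) {
  padjust <- match.arg(padjust)
  stopifnot(window_size > 0, step > 0, step <= window_size,
            min_sites >= 1L, fc_threshold > 1, alpha > 0, alpha < 1)
  sa <- as_site_table(A)
  sb <- as_site_table(B)
  lens <- infer_chrom_lengths(sa, sb, chrom_lengths = chrom_lengths)

  tests <- list()
  for (ctx in contexts) {
    wa <- window_aggregate(sa, window_size, step, ctx)
    wb <- window_aggregate(sb, window_size, step, ctx)
    j <- merge(wa, wb, by = c("chrom", "win"), suffixes = c("_A", "_B"))
    j <- j[n_sites_A >= min_sites & n_sites_B >= min_sites]
    if (nrow(j) == 0L) next
    j <- j[meth_A + unmeth_A + meth_B + unmeth_B > 0]
    j[, `:=`(start = win * step, context = ctx)]
    j[, end := pmin(start + window_size, lens[chrom])]
    j[, `:=`(level_A = meth_A / (meth_A + unmeth_A),
             level_B = meth_B / (meth_B + unmeth_B))]
    j[, fold_change := (level_B + FC_EPS) / (level_A + FC_EPS)]
    j[, p_value := fisher_exact_two_sided(meth_A, unmeth_A, meth_B, unmeth_B)]
    tests[[ctx]] <- j[, .(chrom, start, end, context, n_sites_A, n_sites_B,
                          meth_A, unmeth_A, meth_B, unmeth_B, level_A,
                          level_B, fold_change, p_value)]
  }
  tests <- if (length(tests)) {
    data.table::rbindlist(tests)
  } else {
    data.table::as.data.table(
      test_window_empty())
  }
  tests <- adjust_pvalues(tests, method = padjust)
  data.table::setDT(tests)
  tests[, direction := dmr_direction(q_value, fold_change, fc_threshold,
                                     alpha)]
  data.table::setorder(tests, chrom, start, context)
  dmrs <- tests[!is.na(direction)]
  summary <- tests[, .(tested = .N,
                       hyper = sum(direction == "hyper", na.rm = TRUE),
                       hypo = sum(direction == "hypo", na.rm = TRUE)),
                   by = context]
  structure(list(dmrs = as.data.frame(dmrs), tests = as.data.frame(tests),
                 summary = as.data.frame(summary),
                 params = list(window_size = window_size, step = step,
                               min_sites = min_sites,
                               fc_threshold = fc_threshold, alpha = alpha,
                               contexts = contexts, padjust = padjust)),
            class = "dmr_result")
}

test_window_empty <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             context = character(), n_sites_A = integer(),
             n_sites_B = integer(), meth_A = integer(), unmeth_A = integer(),
             meth_B = integer(), unmeth_B = integer(), level_A = numeric(),
             level_B = numeric(), fold_change = numeric(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", nrow(x$dmrs), "DMRs from", nrow(x$tests),
      "tested windows\n")
  print(x$summary)
  invisible(x)
}

#' Multiple-testing adjustment for window tests
#'
#' Adds/overwrites a `q_value` column.  `"none"` sets `q = p` (the default
#' DMR criterion is the raw Fisher P); `"bh"` applies the
#' Benjamini-Hochberg step-up procedure within each context.
#'
#' @param tests Tested-window table with `p_value` and `context` columns.
#' @param method `"none"` or `"bh"`.
#' @return The table with a `q_value` column.
#' @export
adjust_pvalues <- function(tests, method = c("none", "bh")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(tests)
  if (nrow(dt) == 0L) {
    dt[, q_value := numeric(0)]
    return(as.data.frame(dt))
  }
  if (method == "none") {
    dt[, q_value := p_value]
  } else {
    dt[, q_value := stats::p.adjust(p_value, method = "BH"), by = context]
  }
  as.data.frame(dt)
}

#' Merge adjacent same-direction DMRs (optional post-process)
#'
#' Concatenates runs of DMRs on the same chromosome with the same context
#' and direction whose gap is at most `max_gap` bp.  Counts are pooled and
#' levels/fold change recomputed; the reported P is the minimum of the
#' member windows (a summary, not a re-test).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param max_gap Maximum gap in bp between members (default 0 = abutting).
#' @return Merged DMR table.
#' @export
merge_adjacent_dmrs <- function(dmrs, max_gap = 0L) {
  dt <- data.table::as.data.table(dmrs)
  if (nrow(dt) == 0L) return(as.data.frame(dt))
  data.table::setorder(dt, chrom, context, direction, start)
  grp <- cumsum(c(1L, (dt$chrom[-1] != dt$chrom[-nrow(dt)]) |
                    (dt$context[-1] != dt$context[-nrow(dt)]) |
                    (dt$direction[-1] != dt$direction[-nrow(dt)]) |
                    (dt$start[-1] - dt$end[-nrow(dt)] > max_gap)))
  dt[, grp := grp]
  out <- dt[, {
    ma <- sum(meth_A); ua <- sum(unmeth_A)
    mb <- sum(meth_B); ub <- sum(unmeth_B)
    la <- ma / (ma + ua); lb <- mb / (mb + ub)
    list(chrom = chrom[1], start = min(start), end = max(end),
         context = context[1], n_sites_A = sum(n_sites_A),
         n_sites_B = sum(n_sites_B), meth_A = ma, unmeth_A = ua,
         meth_B = mb, unmeth_B = ub, level_A = la, level_B = lb,
         fold_change = (lb + FC_EPS) / (la + FC_EPS),
         p_value = min(p_value), q_value = min(q_value),
         direction = direction[1], n_windows = .N)
  }, by = grp][, grp := NULL]
  data.table::setorder(out, chrom, start)
  as.data.frame(out)
}
utils::globalVariables(c("grp", "..context", "n_windows"))
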