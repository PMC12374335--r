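test_that("DEG filter applies both thresholds with the reciprocal rule", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    fold_change = c(2.5, 2.5, 0.4, 1.5),
    q_value = c(5e-4, 0.01, 1e-5, 1e-6), stringsAsFactors = FALSE)
  out <- filter_degs(tab)
  expect_equal(out$gene_id, c("a", "c"))
  expect_equal(out$direction, c("up", "down"))

  # idempotent and order-independent
  expect_equal(filter_degs(out), out)
  perm <- filter_degs(tab[c(3, 1, 4, 2), ])
  expect_setequal(paste(perm$gene_id, perm$direction),
                  paste(out$gene_id, out$direction))

  expect_error(filter_degs(tab[, 1:2]), "missing column")
  bad <- tab; bad$fold_change[1] <- -1
  expect_error(filter_degs(bad), "non-positive")

  # log2 input support
  l2 <- data.frame(gene_id = "x", fold_change = 1.5, q_value = 1e-5)
  expect_equal(filter_degs(l2, log2_fc = TRUE)$fold_change, 2^1.5)
})

test_that("DEP filter uses |fold change| and reports unmapped proteins", {
  tab <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    fold_change = c(1.4, 1.2, 1 / 1.5),
    adj_p = c(0.01, 0.001, 0.04), stringsAsFactors = FALSE)
  out <- suppressMessages(filter_deps(tab))
  expect_equal(out$protein_id, c("p1", "p3"))
  expect_equal(out$direction, c("up", "down"))
  expect_equal(attr(out, "unmapped"), c("p1", "p3"))

  gm <- data.frame(protein_id = c("p1", "p3"), gene_id = c("g1", "g3"))
  mapped <- filter_deps(tab, gene_map = gm)
  expect_equal(mapped$gene_id, c("g1", "g3"))
  expect_length(attr(mapped, "unmapped"), 0)

  # the stricter Methods-style 1.5-fold variant
  strict <- suppressMessages(filter_deps(tab, fc_threshold = 1.5))
  expect_equal(strict$protein_id, "p3")
})

test_that("shared_dmgs partitions sets with the Venn identity", {
  r <- shared_dmgs(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(r$shared, c("g2", "g3"))
  expect_equal(r$sizes, c(only_a = 1L, shared = 2L, only_b = 1L))

  expect_equal(shared_dmgs(c("a", "b"), c("c"))$shared, character(0))

  set.seed(77)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    r <- shared_dmgs(a, b)
    expect_equal(length(r$shared) + length(r$only_a), length(unique(a)))
    expect_equal(length(r$shared) + length(r$only_b), length(unique(b)))
  }
})

dmg_rec <- function(gene_id, region_class = "gene_body",
                    direction = "hyper") {
  data.frame(gene_id = gene_id, region_class = region_class,
             direction = direction, n_supporting_dmrs = 1L, dmr_ids = "x",
             stringsAsFactors = FALSE)
}

test_that("concordance rows are the strict triple intersection", {
  sperm <- rbind(dmg_rec("geneX"), dmg_rec("geneY", direction = "hypo"),
                 dmg_rec("geneZ"))
  embryo <- rbind(dmg_rec("geneX"), dmg_rec("geneY", direction = "hypo"),
                  dmg_rec("geneQ"))
  degs <- data.frame(gene_id = c("geneX", "geneY", "geneQ"),
                     fold_change = c(3, 0.3, 4),
                     q_value = 1e-5,
                     direction = c("up", "down", "up"),
                     stringsAsFactors = FALSE)
  conc <- concordance_table(sperm, embryo, degs)
  # fully concordant up row and down row
  x <- conc$rows[conc$rows$gene_id == "geneX", ]
  expect_equal(unlist(x[c("sperm_meth", "embryo_meth", "mrna")],
                      use.names = FALSE), c("up", "up", "up"))
  y <- conc$rows[conc$rows$gene_id == "geneY", ]
  expect_equal(unlist(y[c("sperm_meth", "embryo_meth", "mrna")],
                      use.names = FALSE), c("down", "down", "down"))
  # strict mode excludes genes missing from any layer
  expect_false("geneZ" %in% conc$rows$gene_id)  # not in embryo/degs
  expect_false("geneQ" %in% conc$rows$gene_id)  # not in sperm

  # loose mode brings in two-layer genes: geneQ (embryo + degs) joins,
  # geneZ (sperm only) still does not
  loose <- concordance_table(sperm, embryo, degs, loose = TRUE)
  expect_true("geneQ" %in% loose$rows$gene_id)
  expect_false("geneZ" %in% loose$rows$gene_id)
  expect_equal(loose$rows$sperm_meth[loose$rows$gene_id == "geneQ"],
               "none")

  # promoter-only support falls back with a region note
  spermP <- dmg_rec("geneX", region_class = "promoter")
  concP <- concordance_table(spermP, embryo, degs)
  expect_match(concP$rows$region_notes, "sperm: promoter hyper")

  # direction-mixed genes are listed separately
  mixed <- rbind(dmg_rec("geneX"), dmg_rec("geneX", direction = "hypo"))
  concM <- concordance_table(mixed, embryo, degs)
  expect_equal(concM$mixed$gene_id, "geneX")
  expect_false("geneX" %in% concM$rows$gene_id)
})

test_that("strict concordance equals a brute-force three-way join", {
  for (seed in c(101, 202, 303)) {
    sperm <- random_dmg_records(30, 40, seed)
    embryo <- random_dmg_records(30, 40, seed + 1)
    set.seed(seed + 2)
    deg_ids <- sprintf("g%03d", sample(30, 15))
    degs <- data.frame(gene_id = deg_ids, fold_change = 3, q_value = 1e-5,
                       direction = sample(c("up", "down"), 15, TRUE),
                       stringsAsFactors = FALSE)
    conc <- concordance_table(sperm, embryo, degs)
    got <- sort(c(conc$rows$gene_id, conc$mixed$gene_id))
    want <- sort(Reduce(intersect, list(unique(sperm$gene_id),
                                        unique(embryo$gene_id),
                                        unique(degs$gene_id))))
    expect_equal(got, want)
  }
})

test_that("venn_summary sizes recompute from raw records", {
  a <- random_dmg_records(40, 60, 7)
  b <- random_dmg_records(40, 60, 8)
  v <- venn_summary(a, b)
  for (i in seq_len(nrow(v))) {
    sa <- dmg_sets(a, v$region_class[i], v$direction[i])
    sb <- dmg_sets(b, v$region_class[i], v$direction[i])
    expect_equal(v$shared[i] + v$only_a[i], length(sa))
    expect_equal(v$shared[i] + v$only_b[i], length(sb))
    expect_equal(v$shared[i], length(intersect(sa, sb)))
  }
})
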