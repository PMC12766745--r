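mk_expr <- function(values, genomes = NULL, tissues = NULL,
                    timepoints = NULL) {
  n <- ncol(values)
  meta <- data.frame(
    sample_id = colnames(values),
    genome_id = genomes %||% rep("A1", n),
    tissue = tissues %||% rep(c("ovule", "root"), length.out = n),
    timepoint = timepoints %||% seq_len(n),
    stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

grid_expr <- function(gene_values, n_genomes = 9) {
  # gene_values: named list gene -> function(tissue) returning one RPKM draw
  genomes <- sprintf("G%d", seq_len(n_genomes))
  grid <- rbind(data.frame(tissue = "root", timepoint = c(-4, -2)),
                data.frame(tissue = "ovule", timepoint = c(0, 4, 8)))
  meta <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(sample_id = paste(g, grid$tissue, grid$timepoint, sep = "_"),
               genome_id = g, tissue = grid$tissue,
               timepoint = grid$timepoint, stringsAsFactors = FALSE)
  }))
  vals <- t(vapply(gene_values, function(f) {
    vapply(seq_len(nrow(meta)), function(j) f(meta$tissue[j]), 0)
  }, numeric(nrow(meta))))
  colnames(vals) <- meta$sample_id
  expression_matrix(vals, meta)
}

test_that("log2p1 transforms values once and guards re-application", {
  e <- mk_expr(matrix(c(0, 1, 3, 7), 2, 2,
                      dimnames = list(c("a", "b"), c("s1", "s2"))))
  lg <- log2p1(e)
  expect_equal(unname(lg$values), matrix(c(0, 1, 2, 3), 2, 2))
  expect_equal(lg$transform, "log2p1")
  expect_error(log2p1(lg), "already")
})

test_that("sv_association implements the joint |r|/p rule with exclusions", {
  set.seed(41)
  carriers <- data.frame(family = rep(c("gS", "gFlat"), each = 4),
                         genome_id = sprintf("G%d", 1:4))
  e <- grid_expr(list(
    gS = function(t) rlnorm(1, 3, 0.5),
    gFlat = function(t) 5,
    gNull = function(t) rlnorm(1, 3, 0.5)))
  # plant a strong shift in carrier genomes of gS
  shift_cols <- e$meta$genome_id %in% carriers$genome_id
  e$values["gS", shift_cols] <- 2^(log2(e$values["gS", shift_cols] + 1) + 3) - 1
  res <- sv_association(log2p1(e), carriers)
  expect_true(res$significant[res$gene_id == "gS"])
  expect_gt(res$pearson_r[res$gene_id == "gS"], 0.3)
  # constant expression: r undefined, never significant
  flat <- res[res$gene_id == "gFlat", ]
  expect_true(is.na(flat$pearson_r))
  expect_false(flat$significant)
  # no carriers at all -> zero carrier samples -> excluded
  expect_false("gNull" %in% res$gene_id)
})

test_that("a single carrier sample is excluded by the two-sample rule", {
  e <- mk_expr(matrix(runif(12, 1, 5), 3, 4,
                      dimnames = list(c("g1", "g2", "g3"),
                                      sprintf("s%d", 1:4))),
               genomes = c("A1", "A2", "A3", "A4"))
  res <- sv_association(log2p1(e),
                        data.frame(family = "g1", genome_id = "A1"))
  expect_false("g1" %in% res$gene_id)     # 1 carrier sample < 2
  res2 <- sv_association(log2p1(e),
                         data.frame(family = c("g1", "g1"),
                                    genome_id = c("A1", "A2")))
  expect_true("g1" %in% res2$gene_id)
})

test_that("negating the carrier set negates r and preserves p", {
  set.seed(13)
  e <- grid_expr(list(g1 = function(t) rlnorm(1, 2, 1)), n_genomes = 6)
  genomes <- unique(e$meta$genome_id)
  half <- genomes[1:3]
  a <- sv_association(log2p1(e), data.frame(family = "g1", genome_id = half))
  b <- sv_association(log2p1(e),
                      data.frame(family = "g1",
                                 genome_id = setdiff(genomes, half)))
  expect_equal(a$pearson_r, -b$pearson_r)
  expect_equal(a$pearson_p, b$pearson_p)
})

test_that("pattern classification covers all four categories", {
  e <- grid_expr(list(
    ov = function(t) if (t == "ovule") 5 else 0,
    rt = function(t) if (t == "root") 2 else 0.2,
    dual = function(t) 3,
    off = function(t) 0.4,
    edge = function(t) if (t == "ovule") 1 else 0))   # exactly at threshold
  calls <- classify_patterns(e)
  got <- setNames(calls$category, calls$gene_id)
  expect_equal(unname(got[c("ov", "rt", "dual", "off", "edge")]),
               c("ovule_only", "root_only", "both", "none", "ovule_only"))
  # partition: every gene exactly one category
  expect_equal(nrow(calls), 5L)
  expect_false(any(is.na(calls$category)))
  # missing tissue is a configuration error
  bad <- mk_expr(matrix(1, 1, 2, dimnames = list("g", c("s1", "s2"))),
                 tissues = c("ovule", "ovule"))
  expect_error(classify_patterns(bad), "both ovule and root")
})

test_that("crosstab reproduces the 15/8/4 -> 55.6/29.6/14.8 split", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    category = c(rep("ovule_only", 15), rep("root_only", 8),
                 rep("both", 4), rep("none", 3)),
    stringsAsFactors = FALSE)
  pav <- data.frame(gene = calls$gene_id, class = "core",
                    stringsAsFactors = FALSE)
  x <- crosstab_patterns(calls, pav)
  core <- x[x$class == "core", ]
  expect_equal(core$n_expressed, 27L)
  expect_equal(c(core$pct_ovule_only, core$pct_root_only, core$pct_both),
               c(55.6, 29.6, 14.8))
  # empty class row: no division-by-zero
  expect_equal(x$n_expressed[x$class == "variable"], 0L)
  expect_equal(x$pct_ovule_only[x$class == "variable"], 0)
  # single gene -> 100 / 0 / 0
  one <- crosstab_patterns(
    data.frame(gene_id = "g1", category = "ovule_only"),
    data.frame(gene = "g1", class = "variable"))
  expect_equal(one$pct_ovule_only[one$class == "variable"], 100)
})

test_that("co-expression edges follow the |r| >= r_min & p < p_max rule", {
  vals <- rbind(tf1 = c(1, 2, 3, 4, 5),
                tgtPos = c(2, 4, 6, 8, 10),
                tgtNeg = c(6, 5, 4, 3, 2),
                tgtFlat = c(1, 1, 1, 1, 1))
  colnames(vals) <- sprintf("s%d", 1:5)
  e <- mk_expr(vals)
  e$transform <- "log2p1"   # values already on log scale for this test
  net <- coexpression_network(e, "tf1", c("tgtPos", "tgtNeg", "tgtFlat"))
  byt <- setNames(net$kept, net$target)
  expect_true(byt[["tgtPos"]])            # r = 1
  expect_true(byt[["tgtNeg"]])            # r = -1, |r| rule
  expect_false(byt[["tgtFlat"]])          # undefined r
  expect_equal(net$r[net$target == "tgtNeg"], -1)
  expect_error(coexpression_network(e, "tf1", "tf1"), "disjoint")
  tiny <- mk_expr(vals[, 1:2])
  tiny$transform <- "log2p1"
  expect_error(coexpression_network(tiny, "tf1", "tgtPos"), "3 samples")
})

test_that("null co-expression kept-edge rate stays near the nominal level", {
  set.seed(77)
  kept <- logical(0)
  for (rep in 1:60) {
    vals <- matrix(rnorm(6 * 10), 6, 10,
                   dimnames = list(c(sprintf("tf%d", 1:2),
                                     sprintf("tg%d", 1:4)),
                                   sprintf("s%d", 1:10)))
    e <- mk_expr(abs(vals))
    e$transform <- "log2p1"
    net <- coexpression_network(e, sprintf("tf%d", 1:2),
                                sprintf("tg%d", 1:4))
    kept <- c(kept, net$kept)
  }
  # |r| >= 0.8 with n = 10 implies p << 0.05; the binding constraint is
  # P(|r| >= 0.8) under independence, which is tiny
  expect_lt(mean(kept), 0.05)
})
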