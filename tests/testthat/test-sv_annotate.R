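simple_gene <- function(strand = "+", start = 5000, end = 6000,
                        gene_id = "g1") {
  gene_model(gene_id, "chr1", strand, start, end,
             exons = iv(start, end), cds = iv(start, end))
}

sv_row <- function(start, end, svtype = "DEL", sv_id = "sv1",
                   genome_id = "sim") {
  data.frame(genome_id = genome_id, chrom = "chr1", start = start,
             end = end, svtype = svtype, sv_id = sv_id,
             stringsAsFactors = FALSE)
}

test_that("gene_territory orients flanks by strand and truncates at 0", {
  plus <- gene_territory(simple_gene("+"))
  up <- plus[plus$region == "upstream", ]
  down <- plus[plus$region == "downstream", ]
  expect_equal(c(up$start, up$end), c(3000, 5000))
  expect_equal(c(down$start, down$end), c(6000, 8000))
  minus <- gene_territory(simple_gene("-"))
  up2 <- minus[minus$region == "upstream", ]
  expect_equal(c(up2$start, up2$end), c(6000, 8000))
  edge <- gene_territory(simple_gene("+", start = 500, end = 900))
  upe <- edge[edge$region == "upstream", ]
  expect_equal(c(upe$start, upe$end), c(0, 500))
})

test_that("territory splits exons, introns, UTRs and splice zones", {
  m <- gene_model("gx", "chr1", "+", 1000, 2000,
                  exons = iv(c(1000, 1500), c(1200, 2000)),
                  cds = iv(c(1050, 1500), c(1200, 1900)),
                  utr5 = iv(1000, 1050), utr3 = iv(1900, 2000))
  t <- gene_territory(m)
  expect_equal(t$start[t$region == "intron"], 1200)
  expect_equal(t$end[t$region == "intron"], 1500)
  sp <- t[t$region == "splice", ]
  expect_equal(sp$start, c(1200, 1498))   # 2 nt into each junction
  expect_equal(sp$end, c(1202, 1500))
  expect_equal(nrow(t[t$region == "exon", ]), 2L)  # coding parts only
})

test_that("assign_region applies precedence and anchor semantics", {
  m <- gene_model("gx", "chr1", "+", 1000, 2000,
                  exons = iv(c(1000, 1500), c(1200, 2000)),
                  cds = iv(c(1050, 1500), c(1200, 1900)),
                  utr5 = iv(1000, 1050), utr3 = iv(1900, 2000))
  t <- gene_territory(m)
  expect_equal(assign_region(sv_row(200, 400), t), "upstream")
  expect_equal(assign_region(sv_row(2500, 2600), t), "downstream")
  # spanning the exon-intron junction: splice beats exon and intron
  expect_equal(assign_region(sv_row(1150, 1250), t), "splice")
  # inside the intron away from junctions
  expect_equal(assign_region(sv_row(1250, 1300), t), "intron")
  # UTR beats exon
  expect_equal(assign_region(sv_row(1020, 1100), t), "utr5")
  # no reach
  expect_true(is.na(assign_region(sv_row(9000, 9100), t)))
  # zero-length anchor: inside vs boundary (half-open on the right)
  expect_equal(assign_region(sv_row(1000, 1000, "INS"), t), "utr5")
  expect_equal(assign_region(sv_row(999, 999, "INS"), t), "upstream")
})

test_that("TRA uses its first-by-coordinate touching breakpoint", {
  t <- gene_territory(simple_gene("+"))
  # first anchor (100) misses, second (3500, upstream) hits
  expect_equal(assign_region(sv_row(100, 3500, "TRA"), t), "upstream")
  # both anchors hit different regions: the earlier coordinate wins
  expect_equal(assign_region(sv_row(4000, 6500, "TRA"), t), "upstream")
})

test_that("overlap census counts per (SV, gene) pair and warns on chroms", {
  g1 <- simple_gene("+", 5000, 6000, "g1")
  g2 <- simple_gene("+", 9000, 10000, "g2")
  models <- list(sim = list(g1, g2))
  # one DEL in the gap lands downstream of g1 AND upstream of g2
  svs <- rbind(sv_row(7100, 7200, sv_id = "svA"),
               sv_row(100, 150, sv_id = "svB"))
  res <- overlap_census(svs, models)
  expect_equal(res$total, 2L)
  expect_equal(res$n_genes, 2L)
  expect_equal(sort(res$overlaps$region), c("downstream", "upstream"))
  # partition: region sums equal the record count
  expect_equal(sum(res$census), res$total)
  # empty SV table -> all-zero census
  empty <- overlap_census(svs[0, ], models)
  expect_equal(sum(empty$census), 0L)
  expect_equal(dim(empty$census), c(7L, 5L))
  # chrom mismatch warning
  bad <- sv_row(10, 20); bad$chrom <- "chrZ"
  expect_warning(overlap_census(bad, models), "chrZ")
})

test_that("annotation matches the position-set oracle on random instances", {
  for (seed in 1:12) {
    inst <- random_sv_instance(n_genes = sample(3:12, 1),
                               n_svs = sample(10:40, 1), seed = seed)
    got <- overlap_census(inst$svs, inst$models)
    want <- oracle_overlaps(inst$svs, inst$models)
    got_df <- got$overlaps[order(got$overlaps$sv_id, got$overlaps$gene_id),
                           c("sv_id", "gene_id", "region")]
    rownames(got_df) <- rownames(want) <- NULL
    expect_equal(got_df, want, info = paste("seed", seed))
    expect_equal(sum(got$census), nrow(got$overlaps))
  }
})

test_that("mirroring coordinates with strand flips preserves every region count", {
  inst <- random_sv_instance(n_genes = 8, n_svs = 40, seed = 7)
  M <- 10^6
  mirror_models <- lapply(inst$models$sim, function(m) {
    refl <- function(x) if (nrow(x) == 0) x else
      iv_sort(iv(M - x[, "end"], M - x[, "start"]))
    gene_model(m$gene_id, m$chrom, if (m$strand == "+") "-" else "+",
               M - m$end, M - m$start,
               exons = refl(m$exons), cds = refl(m$cds),
               utr5 = refl(m$utr5), utr3 = refl(m$utr3),
               genome_id = m$genome_id)
  })
  mirror_svs <- inst$svs
  mirror_svs$start <- M - inst$svs$end
  mirror_svs$end <- M - inst$svs$start
  a <- overlap_census(inst$svs, inst$models)
  b <- overlap_census(mirror_svs, list(sim = mirror_models))
  ra <- rowSums(a$census); rb <- rowSums(b$census)
  expect_equal(unname(ra[c("upstream", "downstream")]),
               unname(rb[c("upstream", "downstream")]))
  expect_equal(unname(ra[c("exon", "intron", "splice")]),
               unname(rb[c("exon", "intron", "splice")]))
  expect_equal(unname(ra[c("utr5", "utr3")]), unname(rb[c("utr5", "utr3")]))
})
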