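tiny_catalog <- function(patterns, policy = "both") {
  data.frame(element_name = names(patterns),
             iupac_pattern = unname(patterns),
             category = rep_len(c("light", "stress"), length(patterns)),
             strand_policy = policy, stringsAsFactors = FALSE)
}

test_that("extract_promoter is strand-aware and truncates at edges", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "")
  assembly <- c(chr1 = chrom)
  plus <- gene_model("gp", "chr1", "+", 5000, 6000,
                     exons = iv(5000, 6000), cds = iv(5000, 6000))
  p <- extract_promoter(plus, assembly)
  expect_equal(as.character(p), substr(chrom, 3001, 5000))
  expect_false(attr(p, "truncated"))
  minus <- gene_model("gm", "chr1", "-", 3000, 5000,
                      exons = iv(3000, 5000), cds = iv(3000, 5000))
  m <- extract_promoter(minus, assembly)
  expect_equal(as.character(m), revcomp(substr(chrom, 5001, 7000)))
  near0 <- gene_model("g0", "chr1", "+", 800, 1200,
                      exons = iv(800, 1200), cds = iv(800, 1200))
  tr <- extract_promoter(near0, assembly)
  expect_equal(attr(tr, "length"), 800L)
  expect_true(attr(tr, "truncated"))
  expect_error(extract_promoter(plus, c(chr2 = "ACGT")), "chr1")
})

test_that("palindromic pattern is reported on both strands at offset 1", {
  hits <- scan_promoter("AACGTA", tiny_catalog(c(el = "ACGT")))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$position, c(1L, 1L))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("IUPAC degeneracy matches and N in the sequence never does", {
  cat1 <- tiny_catalog(c(r = "RCGT"), policy = "given")
  expect_equal(scan_promoter("ACGTTTGCGT", cat1)$position, c(0L, 6L))
  expect_equal(nrow(scan_promoter("ANGT", tiny_catalog(c(x = "ANGT"),
                                                       policy = "given"))),
               0L)
  # overlapping matches are all reported
  ov <- scan_promoter("AAAA", tiny_catalog(c(a2 = "AA"), policy = "given"))
  expect_equal(ov$position, 0:2)
})

test_that("scanner agrees with the sliding-window oracle on random DNA", {
  set.seed(19)
  pats <- c(p1 = "CACGTG", p2 = "TTGACC", p3 = "ACGTGKC", p4 = "MACGYA",
            p5 = "NTCGAN")
  for (rep in 1:6) {
    seq <- random_dna(4000, alphabet = c("A", "C", "G", "T", "T", "A"))
    hits <- scan_promoter(seq, tiny_catalog(pats))
    rc <- revcomp(seq)
    for (el in names(pats)) {
      fwd <- hits$position[hits$element_name == el & hits$strand == "+"]
      rev <- hits$position[hits$element_name == el & hits$strand == "-"]
      expect_equal(fwd, oracle_scan(seq, pats[[el]]), info = el)
      expect_equal(rev, oracle_scan(rc, pats[[el]]), info = el)
    }
  }
})

test_that("reverse-complement invariance: strand roles swap exactly", {
  set.seed(29)
  seq <- random_dna(2000)
  cat2 <- tiny_catalog(c(e1 = "CAAT", e2 = "ACGTG"))
  h1 <- scan_promoter(seq, cat2)
  h2 <- scan_promoter(revcomp(seq), cat2)
  swap <- function(h) {
    h$strand <- ifelse(h$strand == "+", "-", "+")
    h[order(h$element_name, h$strand, h$position), ]
  }
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(swap(h2)[, c("element_name", "position")],
               h1[, c("element_name", "position")], ignore_attr = TRUE)
})

test_that("extending a promoter never removes hits", {
  set.seed(37)
  seq <- random_dna(3000)
  cat3 <- tiny_catalog(c(e = "GTCAT"))
  short_hits <- scan_promoter(substr(seq, 1001, 3000), cat3)
  long_hits <- scan_promoter(seq, cat3)
  fwd_short <- short_hits$position[short_hits$strand == "+"] + 1000L
  expect_true(all(fwd_short %in%
                    long_hits$position[long_hits$strand == "+"]))
})

test_that("element comparison counts, categories, top-k and tie-breaks", {
  cat4 <- data.frame(
    element_name = c("elA", "elB", "elC", "elD"),
    iupac_pattern = c("AAAA", "CCCC", "GGGG", "TTTT"),
    category = c("light", "light", "stress", "hormone"),
    strand_policy = "given", stringsAsFactors = FALSE)
  hits_a <- data.frame(element_name = c("elA", "elA", "elB", "elC"),
                       position = 0L, strand = "+")
  hits_b <- data.frame(element_name = c("elB", "elC"),
                       position = 0L, strand = "+")
  cmp <- compare_element_counts(hits_a, hits_b, cat4, labels = c("A2", "A1"))
  expect_equal(cmp$categories$A2[cmp$categories$category == "light"], 2L)
  expect_equal(cmp$categories$A1[cmp$categories$category == "light"], 1L)
  expect_equal(cmp$elements$A2[cmp$elements$element_name == "elA"], 2L)
  # identical hit sets -> zero differences
  same <- compare_element_counts(hits_a, hits_a, cat4)
  expect_true(all(same$elements$a == same$elements$b))
  # top_k = 1 with a three-way pooled tie (elA, elB, elC all at 2):
  # the lexicographically first element is kept
  top1 <- compare_element_counts(hits_a, hits_b, cat4, top_k = 1)
  expect_equal(nrow(top1$elements), 1L)
  expect_equal(top1$elements$element_name, "elA")
  # disjoint element universes are an error
  alien <- data.frame(element_name = "zz", position = 0L, strand = "+")
  expect_error(compare_element_counts(alien, alien, cat4), "disjoint")
})

test_that("planted fixture motifs are all recovered at their positions", {
  cfg <- sim_config(seed = 101, n_genomes = 2, n_families = 6,
                    sv_count = 0, n_tfs = 0)
  pan <- simulate_pan_genome(cfg)
  catalog <- read_motif_catalog()
  mot <- simulate_promoter_motifs(pan$bundles, cfg, catalog)
  for (g in names(mot$bundles)) {
    b <- mot$bundles[[g]]
    for (gid in names(b$models)) {
      prom <- extract_promoter(b$models[[gid]], b$assembly)
      hits <- scan_promoter(prom, catalog)
      planted <- mot$truth[mot$truth$gene_id == gid, ]
      found <- paste(hits$element_name[hits$strand == "+"],
                     hits$position[hits$strand == "+"])
      expect_true(all(paste(planted$element_name, planted$position) %in%
                        found), info = gid)
    }
  }
})
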