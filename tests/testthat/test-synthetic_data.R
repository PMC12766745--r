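test_that("sim_config validates seed, fractions and weights", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, class_fractions = c(core = 0.6,
                                                        variable = 0.5,
                                                        specific = 0.1)),
               "sum to 1")
  expect_error(sim_config(seed = 1, pattern_fractions = c(ovule_only = 1.2,
                                                          root_only = -0.2,
                                                          both = 0,
                                                          none = 0)),
               "sum to 1")
  expect_error(sim_config(seed = 2^31), "2\\^30")
  expect_s3_class(sim_config(seed = 3), "sim_config")
})

test_that("PAV classes drive presence exactly at boundary fractions", {
  all_core <- sim_config(seed = 5, n_families = 10, n_genomes = 4,
                         class_fractions = c(core = 1, variable = 0,
                                             specific = 0),
                         sv_count = 0, n_tfs = 0)
  pan <- simulate_pan_genome(all_core)
  for (b in pan$bundles) expect_length(b$models, 10L)

  all_spec <- sim_config(seed = 5, n_families = 9, n_genomes = 4,
                         class_fractions = c(core = 0, variable = 0,
                                             specific = 1),
                         sv_count = 0, n_tfs = 0)
  pan2 <- simulate_pan_genome(all_spec)
  total_presence <- sum(vapply(pan2$bundles, function(b) length(b$models), 0L))
  expect_equal(total_presence, 9L)       # each family in exactly one genome

  mixed <- simulate_pan_genome(sim_config(seed = 8, n_families = 30,
                                          sv_count = 0, n_tfs = 0))
  occ <- table(unlist(lapply(mixed$bundles, function(b) {
    sub("^[^_]+_", "", names(b$models))
  })))
  cls <- mixed$truth$pav_class
  expect_true(all(occ[names(cls)[cls == "core"]] == 9))
  expect_true(all(occ[names(cls)[cls == "specific"]] == 1))
  v <- occ[names(cls)[cls == "variable"]]
  expect_true(all(v >= 2 & v <= 8))
})

test_that("the fixture is deterministic: same seed, identical bytes", {
  cfg <- sim_config(seed = 42, n_genomes = 3, n_families = 6, sv_count = 15,
                    n_tfs = 2)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("fixture is self-consistent: every gene id resolves to one genome", {
  cfg <- sim_config(seed = 9, n_genomes = 3, n_families = 8, sv_count = 30,
                    n_tfs = 2)
  fx <- simulate_fixture(cfg, file.path(tempdir(), "fxc"))
  all_genes <- unlist(lapply(fx$bundles, function(b) names(b$models)))
  expect_equal(anyDuplicated(all_genes), 0L)
  # SV truth gene ids exist
  tg <- fx$sv_truth$gene_id[!is.na(fx$sv_truth$gene_id)]
  expect_true(all(tg %in% all_genes))
  # every protein/CDS id has a model; CDS translates to the protein
  for (b in fx$bundles) {
    expect_setequal(names(b$proteins), names(b$models))
    expect_setequal(names(b$cds), names(b$models))
    expect_true(all(nchar(b$cds) %% 3 == 0))
    # CDS embedded in the assembly at the model's coding parts
    mdl <- b$models[[1L]]
    chrom <- b$assembly[["chr1"]]
    got <- paste(vapply(seq_len(nrow(mdl$cds)), function(k) {
      substr(chrom, mdl$cds[k, "start"] + 1, mdl$cds[k, "end"])
    }, ""), collapse = "")
    if (mdl$strand == "-") got <- revcomp(got)
    expect_equal(got, unname(b$cds[[mdl$gene_id]]))
  }
})

test_that("evolve_cds_pair limits: omega -> 0 and zero divergence", {
  anc <- paste(random_codons(400), collapse = "")
  same <- evolve_cds_pair(anc, 1, 0, seed = 4)
  expect_equal(same$cds_a, anc)
  expect_equal(same$cds_b, anc)
  purifying <- evolve_cds_pair(anc, 1e-6, 0.05, seed = 4)
  expect_equal(unname(purifying$realized[["nonsyn_a"]] +
                        purifying$realized[["nonsyn_b"]]), 0L)
  kk <- ng86(substring(purifying$cds_a, seq(1, nchar(anc), 3),
                       seq(3, nchar(anc), 3)),
             substring(purifying$cds_b, seq(1, nchar(anc), 3),
                       seq(3, nchar(anc), 3)))
  # pathway averaging over multiply-hit codons can contribute tiny Nd even
  # when every accepted substitution was synonymous; Ka stays near 0
  expect_lt(kk$Ka, 0.005)
  expect_gt(kk$Ks, 10 * kk$Ka)
  expect_error(evolve_cds_pair("ATGTAA", 1, 0.05), "stop")
  expect_error(evolve_cds_pair(anc, 0, 0.05), "omega")
  expect_error(evolve_cds_pair(anc, 1, 0.5), "divergence")
})

test_that("simulated SV catalog recovers intended regions", {
  cfg <- sim_config(seed = 21, n_genomes = 3, n_families = 12,
                    sv_count = 120, n_tfs = 0)
  pan <- simulate_pan_genome(cfg)
  svres <- simulate_sv_catalog(pan$bundles, cfg)
  models <- lapply(pan$bundles, `[[`, "models")
  res <- overlap_census(svres$svs, models)
  tr <- svres$truth[svres$truth$region != "none", ]
  got <- res$overlaps$region[match(paste(tr$sv_id, tr$gene_id),
                                   paste(res$overlaps$sv_id,
                                         res$overlaps$gene_id))]
  expect_gte(mean(got == tr$region, na.rm = TRUE), 0.95)
  # far-intergenic SVs produce no overlap at all
  far <- svres$truth$sv_id[svres$truth$region == "none"]
  expect_false(any(far %in% res$overlaps$sv_id))
  # single-region weight concentrates all placements there
  up_only <- cfg
  up_only$region_weights[] <- 0
  up_only$region_weights["upstream"] <- 1
  sv_up <- simulate_sv_catalog(pan$bundles, up_only)
  res_up <- overlap_census(sv_up$svs, models)
  expect_true(all(res_up$overlaps$region[
    match(sv_up$truth$sv_id, res_up$overlaps$sv_id)] == "upstream"))
})

test_that("planted expression patterns and TF correlations materialise", {
  cfg <- sim_config(seed = 33, n_genomes = 4, n_families = 20, sv_count = 0,
                    n_tfs = 4, rho = 1)
  pan <- simulate_pan_genome(cfg)
  ex <- simulate_expression(pan$bundles, cfg)
  fam_rows <- setdiff(rownames(ex$expr$values), ex$tf_ids)
  fam_expr <- expression_matrix(ex$expr$values[fam_rows, , drop = FALSE],
                                ex$expr$meta)
  calls <- classify_patterns(fam_expr)
  got <- setNames(calls$category, calls$gene_id)
  tr <- setNames(ex$truth$patterns$category, ex$truth$patterns$family)
  expect_gte(mean(got[names(tr)] == tr), 0.98)
  # rho = 1 gives sample correlation exactly 1 on the log scale
  lg <- log2p1(ex$expr)
  for (k in seq_len(nrow(ex$truth$tf_targets))) {
    tf <- ex$truth$tf_targets$tf_id[k]
    tg <- ex$truth$tf_targets$target[k]
    expect_equal(cor(lg$values[tf, ], lg$values[tg, ]), 1)
  }
  # null model: delta = 0 keeps expression independent of carriers
  expect_equal(cfg$sv_effect_delta, 0)
})

test_that("degenerate grids are rejected", {
  cfg <- sim_config(seed = 2, n_genomes = 2, n_families = 4, sv_count = 0,
                    n_tfs = 0, root_timepoints = numeric(0))
  pan <- simulate_pan_genome(sim_config(seed = 2, n_genomes = 2,
                                        n_families = 4, sv_count = 0,
                                        n_tfs = 0))
  expect_error(simulate_expression(pan$bundles, cfg), "root")
})
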