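#' Simulation configuration for the synthetic pan-genome fixture
#'
#' Defaults describe the emulated study system: nine diploid genomes
#' sharing 107 gene families split 45/43/19 into core/variable/specific,
#' ortholog CDS pairs at ~5% divergence with about 20% of families under
#' positive selection, a root (-4, -2 DPA) / ovule (0, 4, 8 DPA)
#' expression grid, and 2000-bp promoters with planted cis-elements.
#'
#' @param seed Mandatory integer seed (< 2^30; small offsets are added for
#'   the independent simulation stages).
#' @param n_genomes,n_families Pan-genome size.
#' @param class_fractions Named fractions (core/variable/specific) summing
#'   to 1; realised counts use largest-remainder rounding.
#' @param divergence Total pairwise CDS divergence (substitutions/site).
#' @param omega_values Optional named vector family -> true omega;
#'   otherwise each family draws omega ~ U(1.5, 2.6) with probability
#'   `omega_positive_rate` and U(0.1, 0.6) otherwise.
#' @param omega_positive_rate Share of families under positive selection.
#' @param short_family_rate Share of families whose protein is short enough
#'   to trigger the atypical length rule in every genome.
#' @param atypical_rate Per-gene probability of an atypical-coverage domain
#'   hit among normal-length families.
#' @param n_codons_normal,n_codons_short Codon-count ranges for normal and
#'   short families.
#' @param sv_count Number of simulated structural variants.
#' @param region_weights Placement weights over the seven gene regions plus
#'   `intergenic_far` (defaults proportional to the published region
#'   breakdown).
#' @param svtype_weights Weights over DEL/INS/DUP/INV/TRA.
#' @param pattern_fractions Named fractions over
#'   ovule_only/root_only/both/none summing to 1.
#' @param n_tfs,rho Number of planted transcription factors and the target
#'   Pearson correlation of each TF-target pair.
#' @param sv_effect_delta Expression shift (log2 units) applied to SV
#'   carrier genomes; 0 = null model.
#' @param root_timepoints,ovule_timepoints Timepoint grids in DPA.
#' @param expr_meanlog,expr_sdlog LogNormal parameters of expressed RPKM.
#' @param off_max Upper bound of the uniform "not expressed" RPKM.
#' @param promoter_len,motifs_per_promoter Promoter length and planted
#'   motifs per promoter.
#' @param flank Gene-territory flank width for SV placement.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genomes = 9, n_families = 107,
                       class_fractions = c(core = 45, variable = 43,
                                           specific = 19) / 107,
                       divergence = 0.05,
                       omega_values = NULL, omega_positive_rate = 0.2,
                       short_family_rate = 0.1, atypical_rate = 0.2,
                       n_codons_normal = c(110, 130),
                       n_codons_short = c(60, 85),
                       sv_count = 300,
                       region_weights = c(upstream = 1004, downstream = 669,
                                          intron = 731, exon = 260,
                                          utr3 = 51, utr5 = 21, splice = 4,
                                          intergenic_far = 75),
                       svtype_weights = c(DEL = 0.35, INS = 0.30, DUP = 0.15,
                                          INV = 0.12, TRA = 0.08),
                       pattern_fractions = c(ovule_only = 0.35,
                                             root_only = 0.25,
                                             both = 0.20, none = 0.20),
                       n_tfs = 10, rho = 0.95, sv_effect_delta = 0,
                       root_timepoints = c(-4, -2),
                       ovule_timepoints = c(0, 4, 8),
                       expr_meanlog = 3, expr_sdlog = 0.6, off_max = 0.3,
                       promoter_len = 2000, motifs_per_promoter = 3,
                       flank = 2000) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config: seed is mandatory", call. = FALSE)
  }
  if (seed >= 2^30) stop("seed must be below 2^30", call. = FALSE)
  chk_frac <- function(x, what) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  chk_frac(class_fractions, "class_fractions")
  chk_frac(pattern_fractions, "pattern_fractions")
  stopifnot(n_genomes >= 2, n_families >= 1, sv_count >= 0, n_tfs >= 0,
            all(region_weights >= 0), all(svtype_weights >= 0),
            divergence >= 0, divergence <= 0.3)
  if (!setequal(names(region_weights), c(sv_regions, "intergenic_far"))) {
    stop("region_weights must cover the seven regions plus intergenic_far",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# largest-remainder integer allocation of n across fractions
alloc_counts <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

default_genome_ids <- function(n) {
  labels <- c("A1", "A2", "B1", "C1", "D5", "E1", "F1", "G1", "K2")
  if (n <= length(labels)) labels[seq_len(n)] else sprintf("g%02d", seq_len(n))
}

random_cds <- function(n_codons) {
  gc <- genetic_code()
  pool <- names(gc)[gc != "*" & names(gc) != "ATG"]
  paste(c("ATG", sample(pool, n_codons - 1L, replace = TRUE)), collapse = "")
}

#' Evolve an ancestral CDS into a diverged ortholog pair
#'
#' Proposes random single-nucleotide substitutions (uniform over positions
#' and alternative bases) on each of the two branches and thins them by
#' acceptance probability: synonymous proposals are accepted with
#' probability `min(1, 1/omega)` and nonsynonymous ones with
#' `min(1, omega)`, so the realised Nd/Sd ratio scales with omega.
#' Proposals creating a stop codon are rejected and redrawn. Each branch
#' receives half of `round(target_divergence * length)` accepted
#' substitutions.
#'
#' @param ancestor_cds CDS string, length a multiple of 3, no internal
#'   stop codons.
#' @param omega True nonsynonymous/synonymous rate ratio (> 0).
#' @param target_divergence Total pairwise divergence in [0, 0.3].
#' @param seed Optional seed applied before evolving.
#' @return List `cds_a`, `cds_b`, and `realized` (accepted synonymous /
#'   nonsynonymous counts per branch).
#' @export
evolve_cds_pair <- function(ancestor_cds, omega, target_divergence,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(ancestor_cds) %% 3 != 0) {
    stop("ancestor CDS length is not a multiple of 3", call. = FALSE)
  }
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (target_divergence < 0 || target_divergence > 0.3) {
    stop("target_divergence must be in [0, 0.3]", call. = FALSE)
  }
  codons <- substring(ancestor_cds, seq(1, nchar(ancestor_cds), 3),
                      seq(3, nchar(ancestor_cds), 3))
  if (any(genetic_code()[codons] == "*")) {
    stop("ancestor CDS contains a stop codon", call. = FALSE)
  }
  n_total <- round(target_divergence * nchar(ancestor_cds))
  n_a <- floor(n_total / 2); n_b <- n_total - n_a
  a <- evolve_branch(codons, omega, n_a)
  b <- evolve_branch(codons, omega, n_b)
  list(cds_a = paste(a$codons, collapse = ""),
       cds_b = paste(b$codons, collapse = ""),
       realized = c(syn_a = a$syn, nonsyn_a = a$nonsyn,
                    syn_b = b$syn, nonsyn_b = b$nonsyn))
}

evolve_branch <- function(codons, omega, n_sub) {
  gc <- genetic_code()
  p_syn <- min(1, 1 / omega); p_non <- min(1, omega)
  syn <- 0L; non <- 0L
  accepted <- 0L
  while (accepted < n_sub) {
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old <- codons[ci]
    cur_base <- substr(old, pos, pos)
    new_base <- sample(setdiff(bases, cur_base), 1L)
    new <- old
    substr(new, pos, pos) <- new_base
    if (gc[[new]] == "*") next            # never introduce a stop codon
    is_syn <- gc[[new]] == gc[[old]]
    p <- if (is_syn) p_syn else p_non
    if (stats::runif(1) <= p) {
      codons[ci] <- new
      accepted <- accepted + 1L
      if (is_syn) syn <- syn + 1L else non <- non + 1L
    }
  }
  list(codons = codons, syn = syn, nonsyn = non)
}

#' Simulate a pan-genome of gene-family carriers
#'
#' Generates `n_genomes` genome bundles: each family is assigned a PAV
#' class and appears in the genome subset that class dictates (core: all;
#' specific: exactly one; variable: a uniform subset of 2..n-1 genomes).
#' Each carried gene gets a 1-3 exon model with UTRs on a random strand,
#' its CDS evolved from the family ancestor at half the configured pairwise
#' divergence under the family's true omega, an embedded assembly sequence
#' and a simulated profile-domain hit whose coverage band encodes the
#' intended typical/atypical status.
#'
#' @param config A [sim_config()].
#' @return List with `bundles` (per genome: `genome_id`, `models`,
#'   `proteins`, `cds`, `assembly`, `domain_hits`) and `truth`
#'   (`pav_class`, `omega`, `members`, `family_codons`).
#' @export
simulate_pan_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  genomes <- default_genome_ids(n)
  fams <- sprintf("FAM%03d", seq_len(config$n_families))

  counts <- alloc_counts(config$n_families, config$class_fractions)
  pav_class <- rep(names(counts), counts)[seq_len(config$n_families)]
  names(pav_class) <- fams

  omega <- config$omega_values
  if (is.null(omega)) {
    pos <- stats::runif(length(fams)) < config$omega_positive_rate
    omega <- ifelse(pos, stats::runif(length(fams), 1.5, 2.6),
                    stats::runif(length(fams), 0.1, 0.6))
    names(omega) <- fams
  }

  short <- stats::runif(length(fams)) < config$short_family_rate
  n_codons <- ifelse(
    short,
    sample(seq(config$n_codons_short[1L], config$n_codons_short[2L]),
           length(fams), replace = TRUE),
    sample(seq(config$n_codons_normal[1L], config$n_codons_normal[2L]),
           length(fams), replace = TRUE))
  names(short) <- names(n_codons) <- fams

  ancestors <- stats::setNames(
    vapply(n_codons, random_cds, ""), fams)

  presence <- lapply(fams, function(f) {
    switch(pav_class[[f]],
           core = genomes,
           specific = sample(genomes, 1L),
           variable = sort(sample(genomes,
                                  sample(seq(2L, max(2L, n - 1L)), 1L))))
  })
  names(presence) <- fams

  bundles <- stats::setNames(vector("list", n), genomes)
  member_rows <- list()
  for (g in genomes) {
    carried <- fams[vapply(presence, function(p) g %in% p, TRUE)]
    models <- list(); cds_v <- character(0); pos_cursor <- 3000
    chrom <- "chr1"
    hit_rows <- list()
    for (f in carried) {
      cds_len <- 3 * n_codons[[f]]
      cds <- evolve_branch(
        substring(ancestors[[f]], seq(1, cds_len, 3), seq(3, cds_len, 3)),
        omega[[f]],
        round(config$divergence / 2 * cds_len))
      cds <- paste(cds$codons, collapse = "")
      gid <- paste(g, f, sep = "_")
      strand <- sample(c("+", "-"), 1L)
      mdl <- build_gene_structure(gid, chrom, strand, pos_cursor, cds_len, g)
      models[[gid]] <- mdl
      cds_v[gid] <- cds
      pos_cursor <- mdl$end + sample(5000:8000, 1L)

      # domain hit: coverage band encodes intended status
      atyp_cov <- !short[[f]] && stats::runif(1) < config$atypical_rate
      dom <- sample(c("PF00234", "PF14368"), 1L, prob = c(0.7, 0.3))
      mlen <- if (dom == "PF00234") 100L else 50L
      width <- if (atyp_cov) sample(seq(ceiling(0.805 * mlen), floor(0.90 * mlen)), 1L)
               else sample(seq(ceiling(0.905 * mlen), mlen), 1L)
      from <- sample.int(mlen - width + 1L, 1L)
      hit_rows[[gid]] <- data.frame(
        gene_id = gid, genome_id = g, family_id = f, domain_acc = dom,
        e_value = 10^-stats::runif(1, 6, 30),
        hmm_from = from, hmm_to = from + width - 1L,
        model_len = mlen, target_len = n_codons[[f]],
        stringsAsFactors = FALSE)
      member_rows[[gid]] <- data.frame(
        genome_id = g, gene_id = gid, family_id = f,
        cov_typical = !atyp_cov, protein_len = n_codons[[f]],
        stringsAsFactors = FALSE)
    }
    assembly <- build_assembly(models, cds_v, pos_cursor + config$flank + 1500)
    proteins <- vapply(cds_v, function(x) sub("\\*$", "", codon_aa_string(x)), "")
    bundles[[g]] <- list(genome_id = g, models = models,
                         proteins = proteins, cds = cds_v,
                         assembly = assembly,
                         domain_hits = do.call(rbind, hit_rows))
  }
  members <- do.call(rbind, member_rows)
  rownames(members) <- NULL
  # intended status by definition: coverage band, then the length rule
  # anchored on the per-genome median provisionally-typical protein length
  pan_med <- stats::median(members$protein_len[members$cov_typical])
  status <- ifelse(members$cov_typical, "typical", "atypical")
  for (g in genomes) {
    in_g <- members$genome_id == g
    prov <- in_g & members$cov_typical
    ref <- if (any(prov)) stats::median(members$protein_len[prov]) else pan_med
    status[prov & members$protein_len < 0.9 * ref] <- "atypical"
  }
  members$status <- status
  members <- members[, c("genome_id", "gene_id", "family_id", "status")]
  truth <- list(
    pav_class = pav_class,
    presence = presence,
    omega = omega,
    members = members,
    short_family = short)
  list(bundles = bundles, truth = truth)
}

# random 1-3 exon gene with UTRs; returns a gene_model at genomic offset
build_gene_structure <- function(gene_id, chrom, strand, g_start, cds_len,
                                 genome_id) {
  u5 <- sample(60:150, 1L); u3 <- sample(80:200, 1L)
  n_exons <- sample(1:3, 1L)
  chunks <- if (n_exons == 1L) cds_len else {
    cuts <- sort(sample(seq(30L, cds_len - 30L), n_exons - 1L))
    diff(c(0L, cuts, cds_len))
  }
  introns <- if (n_exons > 1L) sample(100:300, n_exons - 1L, replace = TRUE)
             else integer(0)
  # transcript-forward layout from local offset 0
  exon_s <- numeric(n_exons); exon_e <- numeric(n_exons)
  cds_s <- numeric(n_exons); cds_e <- numeric(n_exons)
  cur <- 0
  for (k in seq_len(n_exons)) {
    ex_start <- cur
    if (k == 1L) cur <- cur + u5
    cds_s[k] <- cur; cur <- cur + chunks[k]; cds_e[k] <- cur
    if (k == n_exons) cur <- cur + u3
    exon_s[k] <- ex_start; exon_e[k] <- cur
    if (k < n_exons) cur <- cur + introns[k]
  }
  L <- exon_e[n_exons]
  exons <- iv(exon_s, exon_e); cds <- iv(cds_s, cds_e)
  utr5 <- iv(0, u5); utr3 <- iv(cds_e[n_exons], L)
  if (strand == "-") {
    refl <- function(m) if (nrow(m) == 0L) m else
      iv_sort(iv(L - m[, "end"], L - m[, "start"]))
    exons <- refl(exons); cds <- refl(cds)
    utr5 <- refl(utr5); utr3 <- refl(utr3)
  }
  shift <- function(m) { m[, "start"] <- m[, "start"] + g_start
                         m[, "end"] <- m[, "end"] + g_start; m }
  gene_model(gene_id, chrom, strand, g_start, g_start + L,
             exons = shift(exons), cds = shift(cds),
             utr5 = shift(utr5), utr3 = shift(utr3), genome_id = genome_id)
}

# random chromosome with each gene's CDS embedded at its coding parts
build_assembly <- function(models, cds_v, chrom_len) {
  seq_chr <- sample(bases, chrom_len, replace = TRUE)
  for (mdl in models) {
    cds <- cds_v[[mdl$gene_id]]
    genomic <- if (mdl$strand == "+") cds else revcomp(cds)
    chars <- strsplit(genomic, "")[[1L]]
    off <- 0L
    for (k in seq_len(nrow(mdl$cds))) {
      w <- mdl$cds[k, "end"] - mdl$cds[k, "start"]
      seq_chr[seq(mdl$cds[k, "start"] + 1L, mdl$cds[k, "end"])] <-
        chars[seq(off + 1L, off + w)]
      off <- off + w
    }
  }
  c(chr1 = paste(seq_chr, collapse = ""))
}

#' Simulate a structural-variant catalog with known region labels
#'
#' Places `sv_count` SVs so that each hits a configured gene-region
#' category (or lies in intergenic space beyond any territory), drawing SV
#' types from DEL/INS/DUP/INV/TRA with configured weights. Placement stays
#' strictly inside a single labelled interval (introns are shrunk by the
#' splice-zone width) so the intended label is recoverable. A TRA receives
#' a second breakpoint in far-intergenic space.
#'
#' @param bundles Genome bundles from [simulate_pan_genome()].
#' @param config A [sim_config()].
#' @return List `svs` (SV table data.frame) and `truth` (per-SV intended
#'   `gene_id`, `family_id`, `region`).
#' @export
simulate_sv_catalog <- function(bundles, config) {
  set.seed(config$seed + 1L)
  rw <- config$region_weights
  active <- names(rw)[rw > 0]
  # candidate (genome, gene) pools per region
  pools <- list()
  for (r in setdiff(active, "intergenic_far")) pools[[r]] <- list()
  far_zone <- list()
  for (g in names(bundles)) {
    b <- bundles[[g]]
    chrom_len <- nchar(b$assembly[["chr1"]])
    last_end <- max(vapply(b$models, `[[`, 0, "end"))
    far_zone[[g]] <- c(last_end + config$flank + 100,
                       min(chrom_len, last_end + config$flank + 1200))
    for (gid in names(b$models)) {
      terr <- gene_territory(b$models[[gid]], flank = config$flank)
      for (r in setdiff(active, "intergenic_far")) {
        sub <- terr[terr$region == r, , drop = FALSE]
        if (r == "intron" && nrow(sub) > 0L) {
          m <- iv_clip(iv(sub$start + 2, sub$end - 2), lo = 0)
          sub <- if (nrow(m) == 0L) sub[0L, ] else
            data.frame(region = r, start = m[, "start"], end = m[, "end"])
        }
        if (nrow(sub) > 0L) {
          pools[[r]][[length(pools[[r]]) + 1L]] <-
            list(genome = g, gene = gid, iv = iv(sub$start, sub$end))
        }
      }
    }
  }
  for (r in setdiff(active, "intergenic_far")) {
    if (length(pools[[r]]) == 0L) {
      stop("region '", r, "' requested but absent from all gene models",
           call. = FALSE)
    }
  }
  rows <- list(); truth <- list()
  regions_drawn <- sample(active, config$sv_count, replace = TRUE,
                          prob = rw[active] / sum(rw[active]))
  types_drawn <- sample(names(config$svtype_weights), config$sv_count,
                        replace = TRUE, prob = config$svtype_weights)
  for (i in seq_len(config$sv_count)) {
    r <- regions_drawn[i]; ty <- types_drawn[i]
    sv_id <- sprintf("sv%04d", i)
    if (r == "intergenic_far") {
      g <- sample(names(bundles), 1L)
      zone <- far_zone[[g]]
      if (ty %in% c("INS", "TRA")) {
        p <- sample(seq(zone[1L], zone[2L] - 1), 1L)
        s <- p; e <- if (ty == "TRA") min(p + 50, zone[2L]) else p
      } else {
        len <- sample(20:100, 1L)
        s <- sample(seq(zone[1L], zone[2L] - len), 1L); e <- s + len
      }
      rows[[i]] <- data.frame(genome_id = g, chrom = "chr1", start = s,
                              end = e, svtype = ty, sv_id = sv_id,
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(sv_id = sv_id, genome_id = g,
                               gene_id = NA_character_, region = "none",
                               stringsAsFactors = FALSE)
      next
    }
    slot <- pools[[r]][[sample.int(length(pools[[r]]), 1L)]]
    widths <- slot$iv[, "end"] - slot$iv[, "start"]
    k <- sample.int(nrow(slot$iv), 1L, prob = widths)
    s0 <- slot$iv[k, "start"]; e0 <- slot$iv[k, "end"]
    if (ty %in% c("INS", "TRA")) {
      p <- if (e0 - s0 <= 1) s0 else sample(seq(s0, e0 - 1), 1L)
      s <- p; e <- p
      if (ty == "TRA") e <- far_zone[[slot$genome]][1L] + 10  # 2nd breakpoint
    } else {
      len <- min(sample(20:150, 1L), e0 - s0)
      s <- if (e0 - len <= s0) s0 else sample(seq(s0, e0 - len), 1L)
      e <- s + len
    }
    rows[[i]] <- data.frame(genome_id = slot$genome, chrom = "chr1",
                            start = min(s, e), end = max(s, e),
                            svtype = ty, sv_id = sv_id,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(sv_id = sv_id, genome_id = slot$genome,
                             gene_id = slot$gene, region = r,
                             stringsAsFactors = FALSE)
  }
  svs <- do.call(rbind, rows); tr <- do.call(rbind, truth)
  rownames(svs) <- rownames(tr) <- NULL
  list(svs = svs, truth = tr)
}

#' Simulate the ovule/root expression matrix with planted patterns
#'
#' Each family is assigned a spatiotemporal category; "on" samples draw
#' RPKM from LogNormal(`expr_meanlog`, `expr_sdlog`) and "off" samples
#' from U(0, `off_max`), below the default detection threshold of 1 RPKM.
#' Families absent from a genome are NA in its samples. Planted
#' transcription factors are built from their target's realised
#' log2(RPKM+1) profile so the pairwise Pearson correlation is ~`rho`
#' (exactly 1 when `rho = 1`). When `sv_carriers` is given and
#' `sv_effect_delta != 0`, carrier genomes' samples are shifted by delta
#' log2 units.
#'
#' @param bundles Genome bundles from [simulate_pan_genome()].
#' @param config A [sim_config()].
#' @param sv_carriers Optional data.frame (`family`, `genome_id`) of SV
#'   carrier genomes per family.
#' @return List `expr` (`expression_matrix`, raw scale, TF rows included),
#'   `tf_ids`, and `truth` (`patterns`, `tf_targets`).
#' @export
simulate_expression <- function(bundles, config, sv_carriers = NULL) {
  set.seed(config$seed + 2L)
  genomes <- names(bundles)
  grid <- rbind(
    expand.grid(tissue = "root", timepoint = config$root_timepoints,
                stringsAsFactors = FALSE),
    expand.grid(tissue = "ovule", timepoint = config$ovule_timepoints,
                stringsAsFactors = FALSE))
  for (t in expr_tissues) {
    if (length(genomes) * sum(grid$tissue == t) < 2L) {
      stop("expression grid has fewer than 2 ", t, " samples", call. = FALSE)
    }
  }
  meta <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(sample_id = paste(g, grid$tissue, grid$timepoint, sep = "_"),
               genome_id = g, tissue = grid$tissue,
               timepoint = grid$timepoint, stringsAsFactors = FALSE)
  }))
  fams <- sort(unique(unlist(lapply(bundles, function(b) {
    sub("^[^_]+_", "", names(b$models))
  }))))
  category <- sample(names(config$pattern_fractions), length(fams),
                     replace = TRUE, prob = config$pattern_fractions)
  names(category) <- fams
  present <- vapply(genomes, function(g) {
    fams %in% sub("^[^_]+_", "", names(bundles[[g]]$models))
  }, logical(length(fams)))
  rownames(present) <- fams

  vals <- matrix(NA_real_, length(fams), nrow(meta),
                 dimnames = list(fams, meta$sample_id))
  on_in <- function(cat, tissue) {
    switch(cat, both = TRUE, none = FALSE,
           ovule_only = tissue == "ovule", root_only = tissue == "root")
  }
  for (f in fams) {
    for (j in seq_len(nrow(meta))) {
      g <- meta$genome_id[j]
      if (!present[f, g]) next
      vals[f, j] <- if (on_in(category[[f]], meta$tissue[j])) {
        stats::rlnorm(1, config$expr_meanlog, config$expr_sdlog)
      } else {
        stats::runif(1, 0, config$off_max)
      }
    }
  }
  if (!is.null(sv_carriers) && config$sv_effect_delta != 0) {
    for (f in intersect(unique(sv_carriers$family), fams)) {
      gs <- sv_carriers$genome_id[sv_carriers$family == f]
      cols <- meta$genome_id %in% gs
      vals[f, cols] <- 2^(log2(vals[f, cols] + 1) +
                            config$sv_effect_delta) - 1
    }
  }

  tf_rows <- NULL; tf_truth <- NULL
  n_tfs <- config$n_tfs
  if (n_tfs > 0L) {
    eligible <- fams[category[fams] != "none" &
                       rowSums(!present) == 0]      # core, expressed
    n_tfs <- min(n_tfs, length(eligible))
    targets <- sample(eligible, n_tfs)
    tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
    tf_rows <- matrix(NA_real_, n_tfs, nrow(meta),
                      dimnames = list(tf_ids, meta$sample_id))
    for (k in seq_len(n_tfs)) {
      t_log <- log2(vals[targets[k], ] + 1)
      zx <- (t_log - mean(t_log)) / stats::sd(t_log)
      z <- stats::rnorm(length(zx))
      l <- 5 + (config$rho * zx + sqrt(max(0, 1 - config$rho^2)) * z)
      if (min(l) < 0) l <- l - min(l)     # affine shift keeps r exact
      tf_rows[k, ] <- 2^l - 1
    }
    tf_truth <- data.frame(tf_id = tf_ids, target = targets,
                           rho = config$rho, stringsAsFactors = FALSE)
  }
  expr <- expression_matrix(rbind(vals, tf_rows), meta)
  list(expr = expr,
       tf_ids = if (is.null(tf_rows)) character(0) else rownames(tf_rows),
       truth = list(patterns = data.frame(family = fams,
                                          category = unname(category[fams]),
                                          stringsAsFactors = FALSE),
                    tf_targets = tf_truth))
}

#' Plant cis-element motifs in every promoter
#'
#' Inserts `motifs_per_promoter` concrete instances of catalog elements at
#' non-overlapping random positions of each gene's promoter (the
#' `promoter_len` bases 5' of the gene, strand-aware), modifying the
#' bundle assemblies in place and recording the planted positions in
#' promoter coordinates.
#'
#' @param bundles Genome bundles from [simulate_pan_genome()].
#' @param config A [sim_config()].
#' @param catalog Motif catalog (default: bundled).
#' @return List `bundles` (assemblies updated) and `truth` (data.frame
#'   `genome_id`, `gene_id`, `element_name`, `position`, `strand`).
#' @export
simulate_promoter_motifs <- function(bundles, config,
                                     catalog = read_motif_catalog()) {
  set.seed(config$seed + 3L)
  plen <- config$promoter_len
  rows <- list()
  for (g in names(bundles)) {
    chars <- strsplit(bundles[[g]]$assembly[["chr1"]], "")[[1L]]
    for (gid in names(bundles[[g]]$models)) {
      mdl <- bundles[[g]]$models[[gid]]
      taken <- iv_empty()
      for (k in seq_len(config$motifs_per_promoter)) {
        ei <- sample.int(nrow(catalog), 1L)
        pat <- catalog$iupac_pattern[ei]
        inst <- vapply(strsplit(pat, "")[[1L]], function(s) {
          set <- strsplit(iupac_map[[s]], "")[[1L]]
          if (length(set) == 1L) set else sample(set, 1L)
        }, "")
        w <- length(inst)
        pos <- NA
        for (try in 1:20) {
          cand <- sample.int(plen - w + 1L, 1L) - 1L   # promoter offset
          if (!iv_hits(cand, cand + w, taken)) { pos <- cand; break }
        }
        if (is.na(pos)) next
        taken <- rbind(taken, iv(pos, pos + w))
        if (mdl$strand == "+") {
          gpos <- mdl$start - plen + pos                # genomic, 0-based
          chars[seq(gpos + 1L, gpos + w)] <- inst
        } else {
          gpos <- mdl$end + plen - pos - w
          chars[seq(gpos + 1L, gpos + w)] <-
            strsplit(revcomp(paste(inst, collapse = "")), "")[[1L]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g, gene_id = gid,
          element_name = catalog$element_name[ei],
          position = pos, strand = "+", stringsAsFactors = FALSE)
      }
    }
    bundles[[g]]$assembly <- c(chr1 = paste(chars, collapse = ""))
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(bundles = bundles, truth = truth)
}

#' Generate and write the complete synthetic fixture
#'
#' Runs [simulate_pan_genome()], [simulate_promoter_motifs()],
#' [simulate_sv_catalog()] and [simulate_expression()] and writes every
#' format the readers consume (per-genome GFF3, protein/CDS/assembly
#' FASTA, domtblout; SV table; expression matrix + metadata; TF list;
#' motif catalog) plus `ground_truth.json`. Byte-identical for identical
#' configs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `bundles`, `svs`, `expr`,
#'   `tf_ids` and `truth`.
#' @export
simulate_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pan <- simulate_pan_genome(config)
  mot <- simulate_promoter_motifs(pan$bundles, config)
  bundles <- mot$bundles
  svres <- simulate_sv_catalog(bundles, config)
  carriers <- unique(data.frame(
    family = sub("^[^_]+_", "", svres$truth$gene_id[
      !is.na(svres$truth$gene_id)]),
    genome_id = svres$truth$genome_id[!is.na(svres$truth$gene_id)],
    stringsAsFactors = FALSE))
  exprres <- simulate_expression(bundles, config, sv_carriers = carriers)

  for (g in names(bundles)) {
    b <- bundles[[g]]
    write_gff3(b$models, file.path(out_dir, paste0(g, ".gff3")))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(b$proteins),
      file.path(out_dir, paste0(g, ".proteins.faa")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(b$cds),
      file.path(out_dir, paste0(g, ".cds.fna")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(b$assembly),
      file.path(out_dir, paste0(g, ".assembly.fna")))
    write_domtblout(b$domain_hits,
                    file.path(out_dir, paste0(g, ".domtblout")))
  }
  write_sv_table(svres$svs, file.path(out_dir, "sv_table.tsv"))
  write_expression(exprres$expr, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "metadata.tsv"))
  writeLines(exprres$tf_ids, file.path(out_dir, "tf_list.txt"))
  file.copy(system.file("extdata", "motif_catalog.tsv", package = "panfam"),
            file.path(out_dir, "motif_catalog.tsv"), overwrite = TRUE)

  truth <- list(pav_class = as.list(pan$truth$pav_class),
                omega = as.list(pan$truth$omega),
                members = pan$truth$members,
                sv = svres$truth,
                patterns = exprres$truth$patterns,
                tf_targets = exprres$truth$tf_targets,
                motifs = mot$truth)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(bundles = bundles, svs = svres$svs, sv_truth = svres$truth,
                 expr = exprres$expr, tf_ids = exprres$tf_ids,
                 truth = truth))
}
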