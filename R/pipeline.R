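pipeline_stages <- c("simulate", "family", "pav", "kaks", "sv", "expr",
                     "promoter")

#' Run the full pan-genome family analysis pipeline
#'
#' Executes the requested stages in order
#' `family -> pav -> kaks -> sv -> expr -> promoter` on either a simulated
#' fixture (`config$simulate = TRUE`, generated under `config$seed` into
#' `out_dir/fixture`) or on user-supplied inputs in `config$input_dir`
#' following the fixture's file layout. Each stage writes one TSV and one
#' JSON summary into `out_dir`; every JSON echoes the stage parameters for
#' provenance. Runs are deterministic given (inputs, config, seed).
#'
#' Missing required inputs for a requested stage raise a configuration
#' error before any computation starts.
#'
#' @param config Named list: `out_dir` (required); either
#'   `simulate = TRUE` (with optional `sim` overrides for [sim_config()]
#'   and a `seed`) or `input_dir`; `stages` (subset of
#'   `c("family","pav","kaks","sv","expr","promoter")` or `"all"`,
#'   default all); optional threshold overrides `e_max`, `cov_typical`,
#'   `cov_atypical`, `len_frac`, `flank`, `splice_width`, `expressed_min`,
#'   `r_threshold`, `p_threshold`, `r_min`, `p_max`, `top_k`.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  stages <- config$stages
  if (is.null(stages) || identical(stages, "all")) {
    stages <- setdiff(pipeline_stages, "simulate")
  }
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0L) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  opt <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(config$simulate) || "simulate" %in% stages) {
    seed <- opt("seed", 1L)
    sim_args <- c(list(seed = seed), opt("sim", list()))
    sim_args <- sim_args[!duplicated(names(sim_args))]
    cfg <- do.call(sim_config, sim_args)
    input_dir <- file.path(config$out_dir, "fixture")
    simulate_fixture(cfg, input_dir)
  } else {
    input_dir <- config$input_dir
    if (is.null(input_dir)) {
      stop("config needs either simulate = TRUE or input_dir", call. = FALSE)
    }
  }
  stages <- setdiff(stages, "simulate")
  if (length(stages) == 0L) return(invisible(list(input_dir = input_dir)))

  p <- function(...) file.path(input_dir, ...)
  genomes <- sub("\\.gff3$", "", basename(Sys.glob(p("*.gff3"))))

  # configuration errors before any computation
  need <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  if (any(c("family", "pav", "kaks", "sv", "expr", "promoter") %in% stages)) {
    need(length(genomes) > 0L, "no per-genome GFF3 inputs found")
  }
  if (any(c("family", "pav", "expr") %in% stages)) {
    need(all(file.exists(p(paste0(genomes, ".domtblout")))),
         "family/pav/expr stages need per-genome domtblout inputs")
  }
  if ("sv" %in% stages) {
    need(file.exists(p("sv_table.tsv")), "sv stage needs sv_table.tsv")
  }
  if ("expr" %in% stages) {
    need(file.exists(p("expression.tsv")) && file.exists(p("metadata.tsv")),
         "expr stage needs expression.tsv and metadata.tsv")
    need(file.exists(p("sv_table.tsv")),
         "expr stage needs sv_table.tsv for the association test")
  }
  if ("kaks" %in% stages) {
    need(all(file.exists(p(paste0(genomes, ".cds.fna")))),
         "kaks stage needs per-genome CDS FASTA inputs")
  }
  if ("promoter" %in% stages) {
    need(all(file.exists(p(paste0(genomes, ".assembly.fna")))),
         "promoter stage needs per-genome assembly FASTA inputs")
    need(file.exists(p("motif_catalog.tsv")),
         "promoter stage needs motif_catalog.tsv")
  }

  models <- stats::setNames(lapply(genomes, function(g) {
    read_gff3(p(paste0(g, ".gff3")), genome_id = g)
  }), genomes)
  results <- list()
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_json_report <- function(x, name) {
    jsonlite::write_json(
      rapply(x, function(v) if (is.numeric(v)) signif(v, 6) else v,
             how = "replace"),
      file.path(config$out_dir, name),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  members <- NULL
  if (any(c("family", "pav", "expr") %in% stages)) {
    hits <- do.call(rbind, lapply(genomes, function(g) {
      h <- read_domtblout(p(paste0(g, ".domtblout")), genome_id = g)
      h$family_id <- sub("^[^_]+_", "", h$gene_id)
      h
    }))
    pars <- list(e_max = opt("e_max", 1e-5),
                 cov_typical = opt("cov_typical", 0.90),
                 cov_atypical = opt("cov_atypical", 0.80),
                 len_frac = opt("len_frac", 0.90))
    members <- do.call(classify_members, c(list(hits), pars))
    if ("family" %in% stages) {
      summ <- summarize_family(members)
      write_tsv(members, "members.tsv")
      write_json_report(list(parameters = pars, counts = summ$counts,
                             family_flags = summ$family_flags),
                        "family_summary.json")
      results$family <- list(members = members, summary = summ)
    }
  }

  pav <- NULL
  if (any(c("pav", "expr") %in% stages)) {
    m <- pav_matrix(members, genomes = genomes)
    pav <- classify_pav(m)
    if ("pav" %in% stages) {
      occ <- occupancy_table(m, pav)
      write_tsv(pav, "pav_classes.tsv")
      write_tsv(cbind(gene = rownames(pav_heat_table(m)),
                      as.data.frame(pav_heat_table(m))), "heat_table.tsv")
      write_json_report(
        list(class_counts = as.list(attr(pav, "class_counts")),
             pooled_pct = as.list(occ$pooled_pct),
             gene_share_pct = as.list(occ$gene_share_pct)),
        "pav_summary.json")
      results$pav <- list(classification = pav, occupancy = occ)
    }
  }

  if ("kaks" %in% stages) {
    cds_by_genome <- stats::setNames(lapply(genomes, function(g) {
      x <- Biostrings::readDNAStringSet(p(paste0(g, ".cds.fna")))
      stats::setNames(as.character(x), sub("^[^_]+_", "", names(x)))
    }), genomes)
    kk <- kaks_all_pairs(cds_by_genome)
    sel <- selection_summary(kk)
    write_tsv(kk, "kaks.tsv")
    write_tsv(sel$per_gene, "selection_summary.tsv")
    write_json_report(list(n_families = nrow(sel$per_gene),
                           share_peak_gt1 = sel$share_peak_gt1),
                      "kaks_summary.json")
    results$kaks <- list(kaks = kk, selection = sel)
  }

  overlaps <- NULL
  if (any(c("sv", "expr") %in% stages)) {
    svs <- read_sv_table(p("sv_table.tsv"))
    census <- overlap_census(svs, models, flank = opt("flank", 2000),
                             splice_width = opt("splice_width", 2))
    overlaps <- census$overlaps
    if ("sv" %in% stages) {
      write_tsv(overlaps, "sv_overlaps.tsv")
      write_tsv(cbind(region = rownames(census$census),
                      as.data.frame(census$census)), "census.tsv")
      write_json_report(
        list(parameters = list(flank = opt("flank", 2000),
                               splice_width = opt("splice_width", 2)),
             total = census$total, n_genes = census$n_genes,
             by_region = as.list(rowSums(census$census)),
             by_svtype = as.list(colSums(census$census))),
        "census.json")
      results$sv <- census
    }
  }

  if ("expr" %in% stages) {
    expr <- read_expression(p("expression.tsv"), p("metadata.tsv"))
    tf_ids <- if (file.exists(p("tf_list.txt"))) readLines(p("tf_list.txt"))
              else character(0)
    fams <- setdiff(rownames(expr$values), tf_ids)
    fam_expr <- expression_matrix(expr$values[fams, , drop = FALSE],
                                  expr$meta)
    calls <- classify_patterns(fam_expr,
                               expressed_min = opt("expressed_min", 1))
    carriers <- unique(data.frame(
      family = sub("^[^_]+_", "", overlaps$gene_id),
      genome_id = overlaps$genome_id, stringsAsFactors = FALSE))
    assoc <- sv_association(log2p1(fam_expr), carriers,
                            r_threshold = opt("r_threshold", 0.3),
                            p_threshold = opt("p_threshold", 0.05))
    xtab <- crosstab_patterns(calls, pav)
    write_tsv(calls, "patterns.tsv")
    write_tsv(assoc, "association.tsv")
    write_tsv(xtab, "crosstab.tsv")
    edges <- NULL
    if (length(tf_ids) > 0L) {
      de_targets <- calls$gene_id[calls$category != "none"]
      edges <- coexpression_network(log2p1(expr), tf_ids, de_targets,
                                    r_min = opt("r_min", 0.8),
                                    p_max = opt("p_max", 0.05))
      write_tsv(edges, "edges.tsv")
    }
    lg <- log2p1(fam_expr)
    ord <- order(match(calls$category, pattern_categories))
    heat <- lg$values[ord, order(lg$meta$tissue, lg$meta$timepoint),
                      drop = FALSE]
    write_tsv(cbind(gene_id = rownames(heat),
                    as.data.frame(signif(heat, 6))), "expr_heat_table.tsv")
    write_json_report(
      list(parameters = list(expressed_min = opt("expressed_min", 1),
                             r_threshold = opt("r_threshold", 0.3),
                             p_threshold = opt("p_threshold", 0.05),
                             r_min = opt("r_min", 0.8),
                             p_max = opt("p_max", 0.05)),
           category_counts = as.list(table(calls$category)),
           n_significant = sum(assoc$significant),
           n_edges_kept = if (is.null(edges)) 0L else sum(edges$kept)),
      "expr_summary.json")
    results$expr <- list(patterns = calls, association = assoc,
                         crosstab = xtab, edges = edges)
  }

  if ("promoter" %in% stages) {
    catalog <- read_motif_catalog(p("motif_catalog.tsv"))
    hits_by_genome <- stats::setNames(lapply(genomes, function(g) {
      assembly <- Biostrings::readDNAStringSet(p(paste0(g, ".assembly.fna")))
      hits <- lapply(models[[g]], function(mdl) {
        prom <- extract_promoter(mdl, assembly,
                                 length = opt("promoter_len", 2000))
        h <- scan_promoter(prom, catalog)
        if (nrow(h) > 0L) h$gene_id <- mdl$gene_id
        h
      })
      do.call(rbind, hits)
    }), genomes)
    all_hits <- do.call(rbind, lapply(genomes, function(g) {
      h <- hits_by_genome[[g]]
      if (!is.null(h) && nrow(h) > 0L) h$genome_id <- g
      h
    }))
    write_tsv(all_hits, "cis_hits.tsv")
    cmp <- NULL
    if (length(genomes) >= 2L) {
      cmp <- compare_element_counts(hits_by_genome[[1L]],
                                    hits_by_genome[[2L]], catalog,
                                    top_k = opt("top_k", 20),
                                    labels = genomes[1:2])
      write_tsv(cmp$elements, "element_comparison.tsv")
      write_json_report(list(parameters = list(top_k = opt("top_k", 20)),
                             categories = cmp$categories),
                        "promoter_summary.json")
    }
    results$promoter <- list(hits = all_hits, comparison = cmp)
  }
  invisible(results)
}
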