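sv_regions <- c("splice", "utr5", "utr3", "exon", "intron",
                "upstream", "downstream")

#' Labelled region territory of a gene
#'
#' Strand-aware labelled intervals covering a gene's 2-kb-extended
#' territory: `upstream`/`downstream` flanks of width `flank`, `exon`
#' (coding parts only; UTRs are separate categories), `intron` (gene body
#' minus exons), `splice` (intronic positions within `splice_width`
#' nucleotides of each exon-intron junction) and the two UTRs. Flanks are
#' truncated at position 0.
#'
#' @param model A [gene_model].
#' @param flank Flank width in bp (default 2000).
#' @param splice_width Intronic splice-zone width per junction (default 2).
#' @return Data.frame `region`, `start`, `end` with attributes `chrom`,
#'   `strand`, `gene_id`.
#' @export
gene_territory <- function(model, flank = 2000, splice_width = 2) {
  introns <- model_introns(model)
  splice <- iv_empty()
  if (nrow(introns) > 0L && splice_width > 0) {
    for (k in seq_len(nrow(introns))) {
      s <- introns[k, "start"]; e <- introns[k, "end"]
      if (e - s <= 2 * splice_width) {
        splice <- rbind(splice, iv(s, e))
      } else {
        splice <- rbind(splice, iv(s, s + splice_width),
                        iv(e - splice_width, e))
      }
    }
    splice <- iv_sort(splice)
  }
  up <- if (model$strand == "+") iv(model$start - flank, model$start)
        else iv(model$end, model$end + flank)
  down <- if (model$strand == "+") iv(model$end, model$end + flank)
          else iv(model$start - flank, model$start)
  parts <- list(splice = splice, utr5 = model$utr5, utr3 = model$utr3,
                exon = model$cds, intron = introns,
                upstream = iv_clip(up, lo = 0),
                downstream = iv_clip(down, lo = 0))
  rows <- lapply(names(parts), function(r) {
    m <- parts[[r]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(region = r, start = m[, "start"], end = m[, "end"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "chrom") <- model$chrom
  attr(out, "strand") <- model$strand
  attr(out, "gene_id") <- model$gene_id
  out
}

# anchor intervals an SV is tested with: TRA contributes its two
# breakpoints (coordinate order), everything else its own interval
sv_query_intervals <- function(sv) {
  if (sv$svtype == "TRA") {
    pts <- sort(unique(c(sv$start, sv$end)))
    lapply(pts, function(p) c(start = p, end = p))
  } else {
    list(c(start = sv$start, end = sv$end))
  }
}

#' Assign one structural variant to a gene's region category
#'
#' Returns the single highest-precedence region the SV intersects
#' (`splice > utr5 > utr3 > exon > intron > upstream > downstream`), or NA
#' when no labelled interval is touched. Zero-length anchors (INS, TRA
#' breakpoints) intersect an interval iff the anchor point lies inside it;
#' for TRA the first breakpoint (by coordinate) that touches the territory
#' wins.
#'
#' @param sv One-row data.frame (or list) with `start`, `end`, `svtype`.
#' @param territory Result of [gene_territory()].
#' @return Region name or `NA_character_`.
#' @export
assign_region <- function(sv, territory) {
  for (q in sv_query_intervals(sv)) {
    for (r in sv_regions) {
      sub <- territory[territory$region == r, , drop = FALSE]
      if (nrow(sub) == 0L) next
      if (iv_hits(q[["start"]], q[["end"]], iv(sub$start, sub$end))) return(r)
    }
    # this anchor hit nothing only if no region matched; for non-TRA there
    # is a single query so fall through; for TRA try the next breakpoint
  }
  NA_character_
}

#' Overlap census of structural variants against gene territories
#'
#' Tests every SV against the 2-kb-extended territory of every gene of the
#' same genome and chromosome, assigning at most one region per (SV, gene)
#' pair ([assign_region()]). An SV overlapping k genes yields k records.
#' SVs on chromosomes absent from the gene models are skipped with a
#' warning.
#'
#' @param svs Data.frame from [read_sv_table()].
#' @param models Named list genome_id -> list of [gene_model]s (or a plain
#'   list of models carrying `genome_id`).
#' @param flank,splice_width Passed to [gene_territory()].
#' @return List: `overlaps` (sv_id, gene_id, genome_id, region, svtype),
#'   `census` (region x svtype count matrix over all seven regions and five
#'   SV types), `n_genes` (distinct genes with >= 1 overlap),
#'   `total` (number of overlap records).
#' @export
overlap_census <- function(svs, models, flank = 2000, splice_width = 2) {
  models <- group_models(models)
  recs <- list()
  for (g in unique(svs$genome_id)) {
    gmods <- models[[g]]
    gsvs <- svs[svs$genome_id == g, , drop = FALSE]
    if (is.null(gmods)) {
      warning("genome ", g, " has no gene models; its SVs are skipped",
              call. = FALSE)
      next
    }
    terr <- lapply(gmods, gene_territory, flank = flank,
                   splice_width = splice_width)
    chroms <- vapply(gmods, `[[`, "", "chrom")
    missing_chrom <- setdiff(unique(gsvs$chrom), unique(chroms))
    if (length(missing_chrom) > 0L) {
      warning("chromosome(s) ", paste(missing_chrom, collapse = ", "),
              " in SV table but not in gene models of genome ", g,
              "; SVs skipped", call. = FALSE)
    }
    for (i in seq_len(nrow(gsvs))) {
      sv <- gsvs[i, ]
      for (k in which(chroms == sv$chrom)) {
        region <- assign_region(sv, terr[[k]])
        if (!is.na(region)) {
          recs[[length(recs) + 1L]] <- data.frame(
            sv_id = sv$sv_id, gene_id = gmods[[k]]$gene_id,
            genome_id = g, region = region, svtype = sv$svtype,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  overlaps <- if (length(recs) > 0L) do.call(rbind, recs)
              else data.frame(sv_id = character(0), gene_id = character(0),
                              genome_id = character(0), region = character(0),
                              svtype = character(0), stringsAsFactors = FALSE)
  rownames(overlaps) <- NULL
  census <- table(factor(overlaps$region, levels = sv_regions),
                  factor(overlaps$svtype, levels = sv_types))
  census <- unclass(census)
  names(dimnames(census)) <- NULL
  list(overlaps = overlaps, census = census,
       n_genes = length(unique(overlaps$gene_id)),
       total = nrow(overlaps))
}

group_models <- function(models) {
  if (length(models) > 0L && inherits(models[[1L]], "gene_model")) {
    gids <- vapply(models, `[[`, "", "genome_id")
    return(split(models, gids))
  }
  models
}
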