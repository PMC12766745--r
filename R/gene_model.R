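#' Construct a gene model
#'
#' A `gene_model` describes one gene's genomic architecture: its span,
#' exons, coding parts and UTRs on one strand of one chromosome. All
#' coordinates are 0-based half-open; conversion to the 1-based inclusive
#' GFF3 convention happens only in [read_gff3()] / [write_gff3()].
#'
#' @param gene_id Unique gene identifier within its genome.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 0-based half-open.
#' @param exons,cds,utr5,utr3 Two-column `start`/`end` matrices (see [iv()]);
#'   `cds` holds the coding parts, `utr5`/`utr3` the untranslated regions.
#' @param genome_id Optional genome label (e.g. `"A1"`).
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exons, cds = iv_empty(),
                       utr5 = iv_empty(), utr3 = iv_empty(),
                       genome_id = NA_character_) {
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for gene ", gene_id, call. = FALSE)
  }
  exons <- iv_sort(exons); cds <- iv_sort(cds)
  utr5 <- iv_sort(utr5); utr3 <- iv_sort(utr3)
  if (!iv_is_disjoint_sorted(exons)) {
    stop("exons of gene ", gene_id, " overlap or are unsorted", call. = FALSE)
  }
  if (!iv_contained(cds, exons)) {
    stop("CDS of gene ", gene_id, " extends outside its exons", call. = FALSE)
  }
  feats <- rbind(exons, cds, utr5, utr3)
  if (nrow(feats) > 0L &&
      (min(feats[, "start"]) < start || max(feats[, "end"]) > end)) {
    stop("gene span of ", gene_id, " does not cover all features", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = as.numeric(start), end = as.numeric(end),
         exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
         genome_id = genome_id),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s)  %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, as.integer(x$start), as.integer(x$end),
              x$strand, nrow(x$exons), as.integer(iv_width(x$cds))))
  invisible(x)
}

# introns = gene body minus exons
model_introns <- function(model) {
  iv_subtract(iv(model$start, model$end), model$exons)
}

# derive UTR intervals from exon minus CDS, oriented by strand
derive_utrs <- function(exons, cds, strand) {
  non_cds <- iv_subtract(exons, cds)
  if (nrow(cds) == 0L || nrow(non_cds) == 0L) {
    return(list(utr5 = iv_empty(), utr3 = iv_empty()))
  }
  cds_min <- min(cds[, "start"]); cds_max <- max(cds[, "end"])
  left <- non_cds[non_cds[, "end"] <= cds_min, , drop = FALSE]
  right <- non_cds[non_cds[, "start"] >= cds_max, , drop = FALSE]
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}
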