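#' log2(RPKM + 1) transform
#'
#' @param expr An `expression_matrix` on the raw RPKM scale.
#' @return The matrix with `log2(x + 1)` values and `transform = "log2p1"`.
#'   Re-applying to an already transformed matrix is an error.
#' @export
log2p1 <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform == "log2p1") {
    stop("matrix is already on the log2(RPKM+1) scale", call. = FALSE)
  }
  if (any(expr$values < 0, na.rm = TRUE)) {
    stop("negative RPKM value", call. = FALSE)
  }
  expr$values <- log2(expr$values + 1)
  expr$transform <- "log2p1"
  expr
}

#' SV-expression association tests
#'
#' For each gene, samples are split by whether their genome carries an SV
#' overlapping the gene. Genes with fewer than `min_samples` samples in
#' either group are excluded. Reported per gene: the Pearson correlation
#' between the binary carrier indicator and log2(RPKM+1) expression with
#' its two-sided p-value, plus Welch t-test and Wilcoxon rank-sum p-values
#' between groups. The significance flag follows the published rule
#' `|r| > r_threshold & p < p_threshold`; a Benjamini-Hochberg adjusted
#' p-value column is added for convenience but does not drive the flag.
#'
#' @param expr `expression_matrix` on the log2p1 scale.
#' @param carriers Data.frame with columns `family` (matching rownames of
#'   the matrix) and `genome_id`: the genomes whose copy of that gene
#'   overlaps an SV.
#' @param min_samples Minimum samples per group (default 2).
#' @param r_threshold,p_threshold Significance rule (defaults 0.3, 0.05).
#' @return Data.frame with one row per tested gene.
#' @export
sv_association <- function(expr, carriers, min_samples = 2,
                           r_threshold = 0.3, p_threshold = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "log2p1") {
    stop("sv_association expects log2(RPKM+1) values; call log2p1() first",
         call. = FALSE)
  }
  rows <- list()
  for (gene in rownames(expr$values)) {
    y <- expr$values[gene, ]
    ok <- !is.na(y)
    carrier_genomes <- carriers$genome_id[carriers$family == gene]
    x <- as.numeric(expr$meta$genome_id %in% carrier_genomes)
    n1 <- sum(ok & x == 1); n0 <- sum(ok & x == 0)
    if (n1 < min_samples || n0 < min_samples) next
    yy <- y[ok]; xx <- x[ok]
    if (stats::sd(yy) == 0) {
      r <- NA_real_; r_p <- NA_real_; t_p <- NA_real_; w_p <- NA_real_
    } else {
      ct <- stats::cor.test(xx, yy)
      r <- unname(ct$estimate); r_p <- ct$p.value
      t_p <- tryCatch(stats::t.test(yy[xx == 1], yy[xx == 0])$p.value,
                      error = function(e) NA_real_)
      w_p <- suppressWarnings(
        stats::wilcox.test(yy[xx == 1], yy[xx == 0])$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene, n_sv_samples = n1, n_nonsv_samples = n0,
      pearson_r = r, pearson_p = r_p, t_p = t_p, wilcoxon_p = w_p,
      significant = !is.na(r) && abs(r) > r_threshold && r_p < p_threshold,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows)
         else data.frame(gene_id = character(0), n_sv_samples = integer(0),
                         n_nonsv_samples = integer(0), pearson_r = numeric(0),
                         pearson_p = numeric(0), t_p = numeric(0),
                         wilcoxon_p = numeric(0), significant = logical(0),
                         stringsAsFactors = FALSE)
  out$pearson_p_bh <- stats::p.adjust(out$pearson_p, method = "BH")
  rownames(out) <- NULL
  out
}

pattern_categories <- c("ovule_only", "root_only", "both", "none")

#' Spatiotemporal expression-pattern classification
#'
#' A gene counts as expressed in a tissue when its raw RPKM reaches
#' `expressed_min` in at least one sample of that tissue; the four
#' categories are ovule_only, root_only, both and none. Per-(tissue,
#' timepoint) expressed masks are kept for heat-table output.
#'
#' @param expr `expression_matrix` on the raw scale (threshold is in RPKM
#'   units).
#' @param expressed_min Detection threshold in RPKM, default 1.
#' @return Data.frame `gene_id`, `category`; the per-timepoint logical mask
#'   matrix is in `attr(, "mask")`.
#' @export
classify_patterns <- function(expr, expressed_min = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "raw") {
    stop("classify_patterns expects raw RPKM values", call. = FALSE)
  }
  present <- unique(expr$meta$tissue)
  if (!all(expr_tissues %in% present)) {
    stop("metadata must contain both ovule and root samples",
         call. = FALSE)
  }
  grp <- paste(expr$meta$tissue, expr$meta$timepoint, sep = "_")
  grps <- unique(grp[order(expr$meta$tissue, expr$meta$timepoint)])
  mask <- vapply(grps, function(g) {
    apply(expr$values[, grp == g, drop = FALSE] >= expressed_min, 1,
          any, na.rm = TRUE)
  }, logical(nrow(expr$values)))
  in_tissue <- function(tissue) {
    apply(expr$values[, expr$meta$tissue == tissue, drop = FALSE] >=
            expressed_min, 1, any, na.rm = TRUE)
  }
  ov <- in_tissue("ovule"); rt <- in_tissue("root")
  category <- ifelse(ov & rt, "both",
                     ifelse(ov, "ovule_only",
                            ifelse(rt, "root_only", "none")))
  out <- data.frame(gene_id = rownames(expr$values), category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mask") <- mask
  out
}

#' Cross-tabulate expression categories by PAV class
#'
#' For the core and variable PAV classes: counts and percentage shares of
#' ovule_only / root_only / both among the genes of that class that are
#' expressed at all (category != none). Percentages are rounded to one
#' decimal.
#'
#' @param calls Data.frame from [classify_patterns()].
#' @param pav Data.frame from [classify_pav()] (columns `gene`, `class`).
#' @return Data.frame with one row per PAV class.
#' @export
crosstab_patterns <- function(calls, pav) {
  cls <- pav$class[match(calls$gene_id, pav$gene)]
  rows <- lapply(c("core", "variable"), function(k) {
    sub <- calls$category[!is.na(cls) & cls == k & calls$category != "none"]
    n <- length(sub)
    cnt <- vapply(c("ovule_only", "root_only", "both"),
                  function(cat) sum(sub == cat), 0L)
    pct <- if (n == 0L) c(0, 0, 0) else round(100 * cnt / n, 1)
    data.frame(class = k, n_expressed = n,
               ovule_only = cnt[[1L]], root_only = cnt[[2L]], both = cnt[[3L]],
               pct_ovule_only = pct[[1L]], pct_root_only = pct[[2L]],
               pct_both = pct[[3L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcription-factor co-expression network
#'
#' Scores every TF x target pair by Pearson correlation of log2(RPKM+1)
#' profiles; an edge is kept when `|r| >= r_min` and `p < p_max`.
#'
#' @param expr `expression_matrix` on the log2p1 scale containing both TF
#'   and target rows.
#' @param tf_ids,targets Disjoint subsets of the matrix rownames.
#' @param r_min,p_max Edge thresholds (defaults 0.8, 0.05).
#' @return Data.frame of edges (`tf_id`, `target`, `r`, `p`, `kept`); the
#'   kept-edge node degree table is in `attr(, "degrees")`.
#' @export
coexpression_network <- function(expr, tf_ids, targets,
                                 r_min = 0.8, p_max = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$transform != "log2p1") {
    stop("coexpression_network expects log2(RPKM+1) values", call. = FALSE)
  }
  if (length(intersect(tf_ids, targets)) > 0L) {
    stop("tf_ids and targets must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(tf_ids, targets), rownames(expr$values))
  if (length(missing) > 0L) {
    stop("gene(s) not in the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(expr$values) < 3L) {
    stop("co-expression needs >= 3 samples", call. = FALSE)
  }
  rows <- list()
  for (tf in tf_ids) {
    for (tg in targets) {
      x <- expr$values[tf, ]; y <- expr$values[tg, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, target = tg, r = r, p = p,
        kept = !is.na(r) && abs(r) >= r_min &&
          # a perfect correlation has p = 0 numerically; guard NA
          (!is.na(p) && p < p_max),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows)
         else data.frame(tf_id = character(0), target = character(0),
                         r = numeric(0), p = numeric(0), kept = logical(0))
  rownames(out) <- NULL
  kept <- out[out$kept, , drop = FALSE]
  attr(out, "degrees") <- sort(table(c(kept$tf_id, kept$target)),
                               decreasing = TRUE)
  out
}
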