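#' Build a presence/absence (PAV) matrix
#'
#' @param members Data.frame from [classify_members()] with `family_id` and
#'   `genome_id`, or any data.frame with those two columns.
#' @param genomes Optional full genome set (columns); defaults to the
#'   genomes observed. Supplying it matters when some genome carries no
#'   member at all.
#' @param typical_only Count only typical members as present (default
#'   FALSE: typical or atypical both count).
#' @return Logical families x genomes matrix.
#' @export
pav_matrix <- function(members, genomes = NULL, typical_only = FALSE) {
  if (typical_only) members <- members[members$status == "typical", , drop = FALSE]
  fams <- sort(unique(members$family_id))
  if (is.null(genomes)) genomes <- sort(unique(members$genome_id))
  m <- matrix(FALSE, length(fams), length(genomes),
              dimnames = list(fams, genomes))
  m[cbind(match(members$family_id, fams),
          match(members$genome_id, genomes))] <- TRUE
  m
}

pav_classes <- c("core", "variable", "specific")

#' Classify genes into core / variable / specific PAV classes
#'
#' Occupancy rule over an n-genome pan-genome: present in all n genomes =
#' core; in exactly one = specific; in a proper subset of 2..n-1 = variable.
#'
#' @param matrix Logical genes x genomes matrix (n genomes >= 2).
#' @return Data.frame with `gene`, `occupancy`, `class`; class counts in
#'   `attr(, "class_counts")`.
#' @export
classify_pav <- function(matrix) {
  if (ncol(matrix) < 2L) stop("PAV matrix needs >= 2 genomes", call. = FALSE)
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("PAV matrix labels must be unique", call. = FALSE)
  }
  occ <- rowSums(matrix)
  if (any(occ == 0)) {
    stop("gene '", rownames(matrix)[which(occ == 0)[1L]],
         "' is present in no genome", call. = FALSE)
  }
  cls <- ifelse(occ == ncol(matrix), "core",
                ifelse(occ == 1, "specific", "variable"))
  out <- data.frame(gene = rownames(matrix), occupancy = as.integer(occ),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "class_counts") <-
    vapply(pav_classes, function(k) sum(cls == k), 0L)
  out
}

#' Per-genome and pooled occupancy summary
#'
#' For each genome, counts of core/variable/specific genes *present in it*
#' with per-genome percentage shares. Two pooled summaries are returned:
#' `pooled_pct`, the occurrence-weighted share (sum of per-genome class
#' counts over the sum of per-genome totals), and `gene_share_pct`, the
#' plain share of genes per class.
#'
#' @param matrix Logical genes x genomes PAV matrix.
#' @param classification Result of [classify_pav()] on `matrix`.
#' @return List with `per_genome`, `pooled_pct`, `gene_share_pct`.
#' @export
occupancy_table <- function(matrix, classification) {
  cls <- classification$class[match(rownames(matrix), classification$gene)]
  per <- t(vapply(colnames(matrix), function(g) {
    present <- matrix[, g]
    vapply(pav_classes, function(k) sum(present & cls == k), 0L)
  }, integer(3)))
  per_df <- data.frame(genome = colnames(matrix), per,
                       total = rowSums(per), stringsAsFactors = FALSE,
                       row.names = NULL)
  pct <- 100 * per / pmax(rowSums(per), 1L)
  colnames(pct) <- paste0("pct_", pav_classes)
  per_df <- cbind(per_df, round(pct, 1))
  pooled <- 100 * colSums(per) / sum(per)
  gene_share <- 100 * attr(classification, "class_counts") /
    nrow(classification)
  list(per_genome = per_df,
       pooled_pct = round(pooled, 1),
       gene_share_pct = round(gene_share, 1))
}

#' Presence/absence heat table
#'
#' The 0/1 genes x genomes grid underlying a PAV heatmap, optionally
#' excluding core and/or specific genes (the usual display keeps only the
#' variable genes, i.e. those with at least one deletion but more than one
#' carrier). Rows are ordered by ascending occupancy, then label.
#'
#' @param matrix Logical PAV matrix.
#' @param exclude_core,exclude_specific Drop those classes (default TRUE).
#' @return Integer 0/1 matrix (possibly 0 rows).
#' @export
pav_heat_table <- function(matrix, exclude_core = TRUE,
                           exclude_specific = TRUE) {
  classification <- classify_pav(matrix)
  drop <- character(0)
  if (exclude_core) drop <- c(drop, "core")
  if (exclude_specific) drop <- c(drop, "specific")
  keep <- classification$gene[!classification$class %in% drop]
  sub <- matrix[rownames(matrix) %in% keep, , drop = FALSE]
  if (nrow(sub) > 0L) {
    sub <- sub[order(rowSums(sub), rownames(sub)), , drop = FALSE]
  }
  storage.mode(sub) <- "integer"
  sub
}
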