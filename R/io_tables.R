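#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited `--domtblout` format of `hmmsearch`,
#' keeping one row per domain hit: the target gene, the query domain model
#' accession (version suffix stripped), the independent (i-)E-value, the
#' hit's coordinates on the HMM, the model length and the target protein
#' length.
#'
#' @param path Path to a domtblout file.
#' @param genome_id Optional genome label added as a column.
#' @return A data.frame with columns `gene_id`, `genome_id`, `domain_acc`,
#'   `e_value`, `hmm_from`, `hmm_to`, `model_len`, `target_len`.
#' @export
read_domtblout <- function(path, genome_id = NA_character_) {
  lines <- readLines(path)
  idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  empty <- data.frame(gene_id = character(0), genome_id = character(0),
                      domain_acc = character(0), e_value = numeric(0),
                      hmm_from = integer(0), hmm_to = integer(0),
                      model_len = integer(0), target_len = integer(0),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L)) {
    bad <- which(nf < 23L)[1L]
    stop(sprintf("malformed domtblout row at line %d: %d columns (need >= 23)",
                 idx[bad], nf[bad]), call. = FALSE)
  }
  col <- function(k) vapply(fields, `[`, "", k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric %s ('%s') in domtblout at line %d",
                   what, col(k)[bad], idx[bad]), call. = FALSE)
    }
    v
  }
  acc <- col(5L)
  acc <- ifelse(acc %in% c("-", ""), col(4L), acc)
  acc <- sub("\\.\\d+$", "", acc)
  out <- data.frame(
    gene_id = col(1L), genome_id = genome_id, domain_acc = acc,
    e_value = num(13L, "E-value"),
    hmm_from = as.integer(num(16L, "hmm_from")),
    hmm_to = as.integer(num(17L, "hmm_to")),
    model_len = as.integer(num(6L, "model length")),
    target_len = as.integer(num(3L, "target length")),
    stringsAsFactors = FALSE)
  if (any(out$e_value < 0)) stop("negative E-value in domtblout", call. = FALSE)
  bad <- out$hmm_from < 1L | out$hmm_to < out$hmm_from |
    out$hmm_to > out$model_len
  if (any(bad)) {
    stop(sprintf("inconsistent hmm coordinates in domtblout at line %d",
                 idx[which(bad)[1L]]), call. = FALSE)
  }
  out
}

# minimal domtblout writer used by the fixture simulator
write_domtblout <- function(hits, path) {
  header <- "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  rows <- sprintf(
    "%s - %d %s %s %d %.2g 100.0 0.1 1 1 %.2g %.2g 99.0 0.1 %d %d 1 %d 1 %d 0.95 -",
    hits$gene_id, hits$target_len, hits$domain_acc, hits$domain_acc,
    hits$model_len, hits$e_value, hits$e_value, hits$e_value,
    hits$hmm_from, hits$hmm_to, hits$target_len, hits$target_len)
  writeLines(c(header, rows), path)
  invisible(path)
}

sv_types <- c("DEL", "INS", "DUP", "INV", "TRA")

#' Read a structural-variant table
#'
#' Expects a header line and tab-separated columns `genome_id`, `chrom`,
#' `start`, `end`, `svtype`, `sv_id` with BED-like 0-based half-open
#' coordinates. `svtype` must be one of DEL, INS, DUP, INV, TRA. INS
#' breakpoints must be zero-or-one-length anchors; a TRA row's start and end
#' are interpreted as its two breakpoint anchors.
#'
#' @param path Path to the TSV.
#' @return A data.frame of validated SV records.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "chrom", "start", "end", "svtype", "sv_id")
  if (!all(need %in% names(df))) {
    stop("SV table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-numeric SV coordinates", call. = FALSE)
  }
  if (any(df$end < df$start)) {
    bad <- df$sv_id[which(df$end < df$start)[1L]]
    stop("SV '", bad, "' has end < start", call. = FALSE)
  }
  bad_type <- setdiff(unique(df$svtype), sv_types)
  if (length(bad_type) > 0L) {
    stop("unknown svtype '", bad_type[1L], "' (allowed: ",
         paste(sv_types, collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(df$sv_id)) {
    stop("duplicate sv_id: ", df$sv_id[duplicated(df$sv_id)][1L],
         call. = FALSE)
  }
  long_ins <- df$svtype == "INS" & (df$end - df$start) > 1
  if (any(long_ins)) {
    stop("INS '", df$sv_id[which(long_ins)[1L]],
         "' is not a zero-or-one-length anchor", call. = FALSE)
  }
  df
}

write_sv_table <- function(svs, path) {
  utils::write.table(
    svs[, c("genome_id", "chrom", "start", "end", "svtype", "sv_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

expr_tissues <- c("ovule", "root")

#' Read an expression matrix with sample metadata
#'
#' The matrix file is a genes x samples TSV of RPKM values (first column
#' `gene_id`); the metadata file maps each sample to `genome_id`,
#' `tissue` (ovule or root) and `timepoint` in days post anthesis (DPA).
#' Values are stored raw; apply [log2p1()] before statistics that expect
#' the log scale.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An `expression_matrix` object.
#' @export
read_expression <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "gene_id") {
    stop("expression matrix must have 'gene_id' as its first column",
         call. = FALSE)
  }
  if (anyDuplicated(raw$gene_id)) {
    stop("duplicate gene id in expression matrix: ",
         raw$gene_id[duplicated(raw$gene_id)][1L], call. = FALSE)
  }
  samples <- names(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in expression matrix: ",
         samples[duplicated(samples)][1L], call. = FALSE)
  }
  values <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(values) <- raw$gene_id
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genome_id", "tissue", "timepoint")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L], call. = FALSE)
  }
  expression_matrix(values, meta)
}

#' Construct an expression matrix object
#'
#' @param values Numeric genes x samples matrix of RPKM (all values >= 0;
#'   NA marks genes absent from a genome).
#' @param meta Data.frame with columns `sample_id`, `genome_id`, `tissue`,
#'   `timepoint` covering every column of `values`.
#' @param transform `"raw"` or `"log2p1"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, meta, transform = "raw") {
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta) > 0L) {
    stop("sample '", missing_meta[1L], "' has no metadata", call. = FALSE)
  }
  bad_tissue <- setdiff(unique(meta$tissue), expr_tissues)
  if (length(bad_tissue) > 0L) {
    stop("unknown tissue '", bad_tissue[1L], "' (allowed: ",
         paste(expr_tissues, collapse = ", "), ")", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative expression value: RPKM must be >= 0", call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, transform = transform),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

write_expression <- function(expr, path, metadata_path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

motif_categories <- c("light", "stress", "hormone", "development", "other")

#' Read a cis-element motif catalog
#'
#' Tab-separated columns `element_name`, `iupac_pattern`, `category`,
#' `strand_policy`. Patterns are over the IUPAC nucleotide alphabet;
#' categories are light/stress/hormone/development/other; `strand_policy`
#' is `both` (scan forward and reverse-complement) or `given`.
#'
#' @param path Path to the catalog TSV, or `NULL` for the bundled default
#'   catalog of common plant promoter elements.
#' @return A validated data.frame.
#' @export
read_motif_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_catalog.tsv", package = "panfam",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element_name", "iupac_pattern", "category", "strand_policy")
  if (!all(need %in% names(df))) {
    stop("motif catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$element_name)) {
    stop("duplicate element name in catalog", call. = FALSE)
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", df$iupac_pattern)
  if (any(bad)) {
    stop("non-IUPAC pattern for element ", df$element_name[which(bad)[1L]],
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(df$category), motif_categories)
  if (length(bad_cat) > 0L) {
    stop("unknown element category '", bad_cat[1L], "'", call. = FALSE)
  }
  if (!all(df$strand_policy %in% c("both", "given"))) {
    stop("strand_policy must be 'both' or 'given'", call. = FALSE)
  }
  df
}
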