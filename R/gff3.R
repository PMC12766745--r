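#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `exon`, `CDS` and (optionally)
#' `five_prime_UTR`/`three_prime_UTR` features into [gene_model] objects.
#' When a gene carries several mRNAs the transcript with the longest total
#' CDS wins (ties broken by lexicographic mRNA id). When UTR features are
#' absent they are derived as exon minus CDS, oriented by strand. On-disk
#' 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Optional genome label stored on each model.
#' @return A list of [gene_model] objects ordered by (chrom, start, gene_id).
#' @export
read_gff3 <- function(path, genome_id = NA_character_) {
  lines <- readLines(path)
  idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(idx) == 0L) return(list())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GFF3 record at line %d: expected 9 tab-separated columns, found %d",
                 idx[bad], nf[bad]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 4L]))
  end <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("non-numeric coordinate in GFF3 at line %d", idx[bad]),
         call. = FALSE)
  }
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    val <- rep(NA_character_, length(attr_field))
    pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
    hit <- regmatches(attr_field, regexec(pat, attr_field))
    has <- lengths(hit) == 2L
    val[has] <- vapply(hit[has], `[`, "", 2L)
    val
  }
  feat <- data.frame(
    chrom = m[, 1L], type = m[, 3L],
    start = start - 1, end = end,      # -> 0-based half-open
    strand = m[, 7L],
    id = get_attr("ID"), parent = get_attr("Parent"),
    line = idx, stringsAsFactors = FALSE)
  feat <- feat[feat$type %in% c("gene", "mRNA", "exon", "CDS",
                                "five_prime_UTR", "three_prime_UTR"), ,
               drop = FALSE]
  if (nrow(feat) == 0L) return(list())

  genes <- feat[feat$type == "gene", , drop = FALSE]
  if (anyNA(genes$id)) {
    stop(sprintf("gene feature without ID at line %d",
                 genes$line[which(is.na(genes$id))[1L]]), call. = FALSE)
  }
  mrnas <- feat[feat$type == "mRNA", , drop = FALSE]
  kids <- feat[!feat$type %in% c("gene", "mRNA"), , drop = FALSE]

  known <- c(genes$id, mrnas$id)
  orphan <- c(mrnas$parent[!mrnas$parent %in% genes$id],
              kids$parent[!kids$parent %in% known])
  if (length(stats::na.omit(orphan)) > 0L ||
      anyNA(mrnas$parent) || anyNA(kids$parent)) {
    bad <- rbind(mrnas[is.na(mrnas$parent) | !mrnas$parent %in% genes$id, ],
                 kids[is.na(kids$parent) | !kids$parent %in% known, ])
    stop(sprintf("orphan feature (unknown or missing Parent) at line %d",
                 min(bad$line)), call. = FALSE)
  }

  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrnas[mrnas$parent == g$id, , drop = FALSE]
    # transcripts: real mRNAs, or the gene itself when children attach directly
    tx_ids <- if (nrow(gm) > 0L) gm$id else g$id
    cds_sum <- vapply(tx_ids, function(tid) {
      iv_width(as_iv(kids[kids$parent == tid & kids$type == "CDS", ]))
    }, 0)
    best <- tx_ids[order(-cds_sum, tx_ids)][1L]
    sub <- kids[kids$parent == best, , drop = FALSE]
    exons <- as_iv(sub[sub$type == "exon", ])
    cds <- as_iv(sub[sub$type == "CDS", ])
    if (nrow(exons) == 0L) exons <- if (nrow(cds) > 0L) cds else iv(g$start, g$end)
    utr5 <- as_iv(sub[sub$type == "five_prime_UTR", ])
    utr3 <- as_iv(sub[sub$type == "three_prime_UTR", ])
    if (nrow(utr5) == 0L && nrow(utr3) == 0L) {
      d <- derive_utrs(exons, cds, g$strand)
      utr5 <- d$utr5; utr3 <- d$utr3
    }
    models[[i]] <- gene_model(g$id, g$chrom, g$strand, g$start, g$end,
                              exons = exons, cds = cds,
                              utr5 = utr5, utr3 = utr3,
                              genome_id = genome_id)
  }
  ids <- vapply(models, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID in GFF3: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  sort_models(models)
}

as_iv <- function(df) {
  if (nrow(df) == 0L) return(iv_empty())
  iv_sort(iv(df$start, df$end))
}

sort_models <- function(models) {
  if (length(models) == 0L) return(models)
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0, "start"),
               vapply(models, `[[`, "", "gene_id"))
  models[ord]
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene`/`mRNA` pair plus `exon`, `CDS` and UTR rows per model in
#' canonical (chrom, start, gene_id) order, converting back to 1-based
#' inclusive coordinates. `read_gff3(write_gff3(x))` reproduces the models.
#'
#' @param models List of [gene_model] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  models <- sort_models(models)
  out <- c("##gff-version 3")
  row <- function(chrom, type, s, e, strand, attrs, phase = ".") {
    sprintf("%s\tpanfam\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, as.integer(s) + 1L, as.integer(e), strand, phase, attrs)
  }
  for (mdl in models) {
    tid <- paste0(mdl$gene_id, ".t1")
    out <- c(out,
             row(mdl$chrom, "gene", mdl$start, mdl$end, mdl$strand,
                 paste0("ID=", mdl$gene_id)),
             row(mdl$chrom, "mRNA", mdl$start, mdl$end, mdl$strand,
                 paste0("ID=", tid, ";Parent=", mdl$gene_id)))
    emit <- function(type, m, phases = NULL) {
      for (k in seq_len(nrow(m))) {
        out <<- c(out, row(mdl$chrom, type, m[k, "start"], m[k, "end"],
                           mdl$strand, paste0("Parent=", tid),
                           if (is.null(phases)) "." else phases[k]))
      }
    }
    emit("exon", mdl$exons)
    emit("CDS", mdl$cds, cds_phases(mdl$cds, mdl$strand))
    emit("five_prime_UTR", mdl$utr5)
    emit("three_prime_UTR", mdl$utr3)
  }
  writeLines(out, path)
  invisible(path)
}

# GFF3 phase per CDS part, following transcript order (descending for -)
cds_phases <- function(cds, strand) {
  if (nrow(cds) == 0L) return(character(0))
  ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  widths <- cds[, "end"] - cds[, "start"]
  ph <- integer(nrow(cds))
  acc <- 0
  for (k in ord) {
    ph[k] <- (3 - acc %% 3) %% 3
    acc <- acc + widths[k]
  }
  as.character(ph)
}
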