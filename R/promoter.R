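iupac_map <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# IUPAC pattern -> regex over ACGT (an N in the *sequence* never matches)
iupac_regex <- function(pattern) {
  ch <- strsplit(pattern, "")[[1L]]
  bad <- setdiff(ch, names(iupac_map))
  if (length(bad) > 0L) {
    stop("invalid IUPAC symbol '", bad[1L], "' in pattern ", pattern,
         call. = FALSE)
  }
  paste0(vapply(ch, function(s) {
    set <- iupac_map[[s]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, ""), collapse = "")
}

revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

#' Extract a gene's promoter from the assembly
#'
#' The `length` bases immediately 5' of the gene start, strand-aware: for a
#' minus-strand gene the region 3' of its genomic end is taken and
#' reverse-complemented. The promoter is truncated at contig edges; the
#' actual extracted length and a truncation flag are attached as
#' attributes.
#'
#' @param model A [gene_model].
#' @param assembly Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param length Promoter length in bp, default 2000.
#' @return Character promoter sequence (5'->3' of the gene) with
#'   attributes `gene_id`, `truncated`, `length`.
#' @export
extract_promoter <- function(model, assembly, length = 2000) {
  seqs <- if (methods::is(assembly, "DNAStringSet")) {
    stats::setNames(as.character(assembly), names(assembly))
  } else assembly
  if (!model$chrom %in% names(seqs)) {
    stop("chromosome '", model$chrom, "' not in assembly", call. = FALSE)
  }
  chrom_seq <- seqs[[model$chrom]]
  L <- nchar(chrom_seq)
  if (model$strand == "+") {
    s <- max(0, model$start - length); e <- model$start
    out <- substr(chrom_seq, s + 1, e)            # 0-based -> substr
  } else {
    s <- model$end; e <- min(L, model$end + length)
    out <- revcomp(substr(chrom_seq, s + 1, e))
  }
  structure(out, gene_id = model$gene_id,
            truncated = nchar(out) < length, length = nchar(out))
}

#' Scan a promoter for cis-element motif matches
#'
#' Reports every IUPAC match of every catalog element on the forward
#' strand and, for elements with `strand_policy = "both"`, on the reverse
#' complement. Overlapping matches are all reported; `N` in the sequence
#' never matches. Reverse-strand hit positions are offsets in the
#' reverse-complemented sequence.
#'
#' @param seq Promoter sequence (character over ACGTN).
#' @param catalog Motif catalog data.frame ([read_motif_catalog()]).
#' @return Data.frame `element_name`, `position` (0-based), `strand`.
#' @export
scan_promoter <- function(seq, catalog) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) {
    stop("promoter sequence must be over ACGTN", call. = FALSE)
  }
  rc <- if (any(catalog$strand_policy == "both")) revcomp(seq) else NULL
  rows <- list()
  scan_one <- function(subject, pattern) {
    # lookahead regex reports overlapping matches
    m <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), subject,
                  perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  for (i in seq_len(nrow(catalog))) {
    el <- catalog$element_name[i]; pat <- catalog$iupac_pattern[i]
    fwd <- scan_one(seq, pat)
    if (length(fwd) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        element_name = el, position = fwd, strand = "+",
        stringsAsFactors = FALSE)
    }
    if (catalog$strand_policy[i] == "both") {
      rev <- scan_one(rc, pat)
      if (length(rev) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_name = el, position = rev, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows)
         else data.frame(element_name = character(0), position = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$element_name, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare cis-element counts between two genomes
#'
#' Per element: total hit counts in each genome, restricted to the `top_k`
#' elements by pooled count (ties broken by element name). Per category:
#' the number of distinct elements observed in each genome.
#'
#' @param hits_a,hits_b Concatenated [scan_promoter()] hits for each
#'   genome (all promoters pooled).
#' @param catalog The shared motif catalog.
#' @param top_k Number of elements retained, default 20.
#' @param labels Genome labels, default `c("a", "b")`.
#' @return List with `elements` (top-k per-element counts) and
#'   `categories` (distinct-element counts per functional category).
#' @export
compare_element_counts <- function(hits_a, hits_b, catalog, top_k = 20,
                                   labels = c("a", "b")) {
  known <- catalog$element_name
  seen <- union(unique(hits_a$element_name), unique(hits_b$element_name))
  if (length(seen) > 0L && length(intersect(seen, known)) == 0L) {
    stop("hit sets share no element with the catalog: disjoint catalogs?",
         call. = FALSE)
  }
  cnt <- function(hits) {
    v <- table(factor(hits$element_name, levels = known))
    as.integer(v)
  }
  ca <- cnt(hits_a); cb <- cnt(hits_b)
  el <- data.frame(element_name = known, category = catalog$category,
                   a = ca, b = cb, pooled = ca + cb,
                   stringsAsFactors = FALSE)
  names(el)[names(el) == "a"] <- labels[1L]
  names(el)[names(el) == "b"] <- labels[2L]
  el <- el[order(-el$pooled, el$element_name), , drop = FALSE]
  el <- utils::head(el, top_k)
  rownames(el) <- NULL
  cats <- data.frame(
    category = motif_categories,
    a = vapply(motif_categories, function(k) {
      length(unique(hits_a$element_name[hits_a$element_name %in%
        known[catalog$category == k]]))
    }, 0L),
    b = vapply(motif_categories, function(k) {
      length(unique(hits_b$element_name[hits_b$element_name %in%
        known[catalog$category == k]]))
    }, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  names(cats)[2:3] <- labels
  list(elements = el, categories = cats)
}
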