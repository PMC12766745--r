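#' Coverage of a domain hit on its HMM model
#'
#' The fraction of the profile model covered by the hit,
#' `(hmm_to - hmm_from + 1) / model_len`. Domain completeness on the model
#' side is the quantity the typical/atypical tiering is about; query-side
#' coverage can be requested via `side = "target"`.
#'
#' @param hits Data.frame as returned by [read_domtblout()] (or one row).
#' @param side `"model"` (default) or `"target"`.
#' @return Numeric vector of coverages in (0, 1].
#' @export
domain_coverage <- function(hits, side = c("model", "target")) {
  side <- match.arg(side)
  len <- if (side == "model") hits$model_len else hits$target_len
  if (any(len == 0)) stop("zero model length in domain hit", call. = FALSE)
  (hits$hmm_to - hits$hmm_from + 1) / len
}

#' Classify candidate genes into typical / atypical family members
#'
#' Two-tier rule: hits with independent E-value strictly below `e_max` are
#' retained; per gene the best hit is the one with maximal model coverage
#' (ties: smaller E-value, then lexicographic domain accession). A gene is
#' *typical* when its best coverage strictly exceeds `cov_typical`;
#' *atypical* when coverage is in (`cov_atypical`, `cov_typical`], or when
#' coverage passes the typical bar but the protein is shorter than
#' `len_frac` times the median typical protein length of the family in that
#' genome (falling back to the cross-genome median when a genome has no
#' typical member). Genes at or below `cov_atypical` are dropped.
#'
#' @param hits Data.frame of domain hits (columns of [read_domtblout()];
#'   a `genome_id` column groups genomes, a `family_id` column, if present,
#'   is carried through for cross-genome summaries).
#' @param e_max E-value gate (strict `<`), default 1e-5.
#' @param cov_typical Coverage bar for typical members (strict `>`), 0.90.
#' @param cov_atypical Lower coverage bar for atypical members (strict `>`), 0.80.
#' @param len_frac Short-protein fraction for the length rule, 0.90.
#' @param coverage_side Passed to [domain_coverage()].
#' @param validated Optional character vector of externally validated gene
#'   ids; when given, output is intersected with it.
#' @return Data.frame with one row per retained gene: `gene_id`,
#'   `genome_id`, `family_id` (NA when not supplied), `status`,
#'   `best_domain`, `best_coverage`, `e_value`, `protein_len`.
#' @export
classify_members <- function(hits, e_max = 1e-5, cov_typical = 0.90,
                             cov_atypical = 0.80, len_frac = 0.90,
                             coverage_side = "model", validated = NULL) {
  empty <- data.frame(gene_id = character(0), genome_id = character(0),
                      family_id = character(0), status = character(0),
                      best_domain = character(0), best_coverage = numeric(0),
                      e_value = numeric(0), protein_len = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  if (is.null(hits$genome_id)) hits$genome_id <- NA_character_
  if (is.null(hits$family_id)) hits$family_id <- NA_character_
  hits <- hits[hits$e_value < e_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits$coverage <- domain_coverage(hits, coverage_side)

  key <- paste(hits$genome_id, hits$gene_id, sep = "\r")
  ord <- order(key, -hits$coverage, hits$e_value, hits$domain_acc)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(key[ord]), , drop = FALSE]

  best <- best[best$coverage > cov_atypical, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  status <- ifelse(best$coverage > cov_typical, "typical", "atypical")

  # length rule: demote short proteins among the provisionally typical,
  # anchored on the per-genome median typical protein length
  prov <- status == "typical"
  if (any(prov)) {
    pan_median <- stats::median(best$target_len[prov])
    for (g in unique(best$genome_id)) {
      in_g <- best$genome_id %in% g
      ref <- if (any(prov & in_g)) stats::median(best$target_len[prov & in_g])
             else pan_median
      demote <- in_g & prov & best$target_len < len_frac * ref
      status[demote] <- "atypical"
    }
  }

  out <- data.frame(gene_id = best$gene_id, genome_id = best$genome_id,
                    family_id = best$family_id, status = status,
                    best_domain = best$domain_acc,
                    best_coverage = best$coverage, e_value = best$e_value,
                    protein_len = best$target_len, stringsAsFactors = FALSE)
  if (!is.null(validated)) out <- out[out$gene_id %in% validated, , drop = FALSE]
  out[order(out$genome_id, out$gene_id), , drop = FALSE]
}

#' Summarise classified family members per genome
#'
#' Counts typical, atypical and total members per genome and overall.
#' When members carry a `family_id`, each cross-genome family is flagged
#' `typical`, `atypical` or `both` depending on the statuses observed
#' across genomes ("both" marks families with conventional members in some
#' genomes and unconventional ones in others).
#'
#' @param members Data.frame from [classify_members()].
#' @return List with `counts` (per-genome table plus a `total` row) and
#'   `family_flags` (NULL when no family ids are available).
#' @export
summarize_family <- function(members) {
  genomes <- sort(unique(members$genome_id))
  tab <- function(sub) {
    c(typical = sum(sub$status == "typical"),
      atypical = sum(sub$status == "atypical"),
      total = nrow(sub))
  }
  rows <- lapply(genomes, function(g) tab(members[members$genome_id %in% g, ]))
  counts <- as.data.frame(do.call(rbind, c(rows, list(tab(members)))))
  counts <- cbind(genome_id = c(genomes, "total"), counts,
                  stringsAsFactors = FALSE)
  rownames(counts) <- NULL

  flags <- NULL
  fam <- members$family_id
  if (length(fam) > 0L && !all(is.na(fam))) {
    fams <- sort(unique(stats::na.omit(fam)))
    flag <- vapply(fams, function(f) {
      st <- unique(members$status[members$family_id %in% f])
      if (length(st) == 2L) "both" else st
    }, "")
    flags <- data.frame(family_id = fams, flag = flag,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  list(counts = counts, family_flags = flags)
}
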