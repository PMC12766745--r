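# Codon-level machinery for the Nei-Gojobori (1986) counting method.
# The standard genetic code comes from Biostrings; everything above it
# (site counting, pathway averaging) is authored here.

.pf_cache <- new.env(parent = emptyenv())

bases <- c("A", "C", "G", "T")

genetic_code <- function() {
  if (is.null(.pf_cache$gc)) .pf_cache$gc <- Biostrings::GENETIC_CODE
  .pf_cache$gc
}

codon_aa <- function(codon) unname(genetic_code()[codon])

is_stop <- function(codon) codon_aa(codon) == "*"

check_codon <- function(codon, allow_stop = FALSE) {
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("invalid or ambiguous codon '", codon, "'", call. = FALSE)
  }
  if (!allow_stop && is_stop(codon)) {
    stop("stop codon '", codon, "' not allowed here", call. = FALSE)
  }
  invisible(codon)
}

# all 9 single-nucleotide neighbours of a codon
codon_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(bases, ch[pos])) {
      mut <- ch; mut[pos] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' NG86 fractional site counts: each of the 9 single-nucleotide mutations
#' of the codon is classified as synonymous or nonsynonymous under the
#' standard genetic code (mutations *to* stop codons count as
#' nonsynonymous); `s` is the synonymous count divided by 3 and
#' `n = 3 - s`.
#'
#' @param codon A 3-letter string over ACGT, not a stop codon.
#' @return Named numeric vector `c(s = , n = )`.
#' @export
count_sites <- function(codon) {
  tab <- site_table()
  if (!codon %in% rownames(tab)) check_codon(codon)
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

site_table <- function() {
  if (!is.null(.pf_cache$sites)) return(.pf_cache$sites)
  gc <- genetic_code()
  codons <- names(gc)[gc != "*"]
  s <- vapply(codons, function(cd) {
    nb <- codon_neighbours(cd)
    sum(codon_aa(nb) == codon_aa(cd)) / 3
  }, 0)
  .pf_cache$sites <- cbind(s = s, n = 3 - s)
  .pf_cache$sites
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' NG86 pathway averaging: with one difference the substitution is
#' classified directly; with two or three, the counts are averaged over
#' all orderings of the differing positions, excluding pathways that pass
#' through a stop codon. When no stop-free pathway exists the stop-passing
#' pathways are used and the pair is flagged (`attr(, "stop_path")`).
#'
#' @param codon_a,codon_b Non-stop codons over ACGT.
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions whenever a legal pathway exists.
#' @export
count_differences <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  if (is.null(.pf_cache$diffs)) .pf_cache$diffs <- new.env(parent = emptyenv())
  hit <- .pf_cache$diffs[[key]]
  if (!is.null(hit)) return(hit)
  check_codon(codon_a); check_codon(codon_b)
  a <- strsplit(codon_a, "")[[1L]]; b <- strsplit(codon_b, "")[[1L]]
  dpos <- which(a != b)
  if (length(dpos) == 0L) {
    res <- c(sd = 0, nd = 0)
    attr(res, "stop_path") <- FALSE
    .pf_cache$diffs[[key]] <- res
    return(res)
  }
  orders <- perms(dpos)
  walk <- function(order) {
    cur <- a; sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_nxt <- codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*") through_stop <- TRUE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stop = through_stop)
  }
  paths <- lapply(orders, walk)
  legal <- !vapply(paths, `[[`, TRUE, "stop")
  used <- if (any(legal)) paths[legal] else paths
  res <- c(sd = mean(vapply(used, `[[`, 0, "sd")),
           nd = mean(vapply(used, `[[`, 0, "nd")))
  attr(res, "stop_path") <- !any(legal)
  .pf_cache$diffs[[key]] <- res
  res
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}
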