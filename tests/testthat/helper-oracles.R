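# Independent oracles used by the property/acceptance tests. These
# deliberately take different routes from the package implementation:
# position-set expansion instead of interval arithmetic, recursive DFS
# instead of permutation iteration, naive sliding windows instead of regex.

std_code <- Biostrings::GENETIC_CODE

# --- NG86 oracles -----------------------------------------------------------

# exhaustive 9-mutant enumeration of synonymous site fraction
oracle_site_counts <- function(codon) {
  ch <- strsplit(codon, "")[[1L]]
  syn <- 0L
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[pos]) next
      mut <- ch; mut[pos] <- b
      mut_aa <- std_code[[paste(mut, collapse = "")]]
      if (mut_aa != "*" && mut_aa == std_code[[codon]]) syn <- syn + 1L
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# recursive DFS over substitution orderings, averaging (sd, nd) over
# stop-free pathways (all pathways when none is stop-free)
oracle_count_diffs <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  paths <- list()
  dfs <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, stop = through_stop)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- bv[pos]
      aa1 <- std_code[[paste(cur, collapse = "")]]
      aa2 <- std_code[[paste(nxt, collapse = "")]]
      dfs(nxt, setdiff(remaining, pos),
          sd + (aa1 == aa2), nd + (aa1 != aa2),
          through_stop || aa2 == "*")
    }
  }
  dpos <- which(av != bv)
  if (length(dpos) == 0L) return(c(sd = 0, nd = 0))
  dfs(av, dpos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  use <- if (any(m[, "stop"] == 0)) m[m[, "stop"] == 0, , drop = FALSE] else m
  c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
}

random_codons <- function(n) {
  sample(names(std_code)[std_code != "*"], n, replace = TRUE)
}

# --- SV annotation oracle ---------------------------------------------------

# integer position sets for every region of a gene, built directly from the
# model's fields (no interval arithmetic shared with the implementation)
oracle_region_positions <- function(model, flank = 2000) {
  expand <- function(m) {
    if (nrow(m) == 0L) return(integer(0))
    unlist(lapply(seq_len(nrow(m)), function(k) {
      if (m[k, "end"] <= m[k, "start"]) integer(0)
      else seq(m[k, "start"], m[k, "end"] - 1)
    }))
  }
  exon_all <- expand(model$exons)
  body <- seq(model$start, model$end - 1)
  intron <- setdiff(body, exon_all)
  splice <- intron[(intron - 1) %in% exon_all | (intron - 2) %in% exon_all |
                     (intron + 1) %in% exon_all | (intron + 2) %in% exon_all]
  if (model$strand == "+") {
    up <- seq(max(0, model$start - flank), model$start - 1)
    down <- seq(model$end, model$end + flank - 1)
  } else {
    up <- seq(model$end, model$end + flank - 1)
    down <- seq(max(0, model$start - flank), model$start - 1)
  }
  list(splice = splice, utr5 = expand(model$utr5), utr3 = expand(model$utr3),
       exon = expand(model$cds), intron = intron,
       upstream = up[up >= 0], downstream = down[down >= 0])
}

# quadratic all-pairs checker with per-position membership and the
# splice > utr5 > utr3 > exon > intron > upstream > downstream precedence
oracle_overlaps <- function(svs, models_by_genome, flank = 2000) {
  prec <- c("splice", "utr5", "utr3", "exon", "intron",
            "upstream", "downstream")
  rows <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    for (mdl in models_by_genome[[sv$genome_id]]) {
      if (mdl$chrom != sv$chrom) next
      pos_sets <- oracle_region_positions(mdl, flank)
      anchors <- if (sv$svtype == "TRA") {
        lapply(sort(unique(c(sv$start, sv$end))), function(p) c(p, p))
      } else list(c(sv$start, sv$end))
      region <- NA_character_
      for (anc in anchors) {
        pts <- if (anc[2L] == anc[1L]) anc[1L] else seq(anc[1L], anc[2L] - 1)
        hit <- prec[vapply(prec, function(r) any(pts %in% pos_sets[[r]]),
                           TRUE)]
        if (length(hit) > 0L) { region <- hit[1L]; break }
      }
      if (!is.na(region)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sv_id = sv$sv_id, gene_id = mdl$gene_id, region = region,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sv_id = character(0), gene_id = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$sv_id, out$gene_id), , drop = FALSE]
}

# random SV-annotation instance generator for property tests
random_sv_instance <- function(n_genes, n_svs, seed) {
  set.seed(seed)
  models <- list()
  cursor <- sample(0:3000, 1)
  for (k in seq_len(n_genes)) {
    n_ex <- sample(1:3, 1)
    u5 <- sample(c(0, 30, 80), 1); u3 <- sample(c(0, 40, 120), 1)
    chunks <- sample(60:200, n_ex, replace = TRUE)
    introns <- if (n_ex > 1) sample(c(3, 4, 10, 150), n_ex - 1, replace = TRUE)
               else integer(0)
    s <- cursor; cur <- s
    ex_s <- ex_e <- cd_s <- cd_e <- numeric(n_ex)
    for (j in seq_len(n_ex)) {
      ex_s[j] <- cur
      if (j == 1) cur <- cur + u5
      cd_s[j] <- cur; cur <- cur + chunks[j]; cd_e[j] <- cur
      if (j == n_ex) cur <- cur + u3
      ex_e[j] <- cur
      if (j < n_ex) cur <- cur + introns[j]
    }
    L <- ex_e[n_ex] - s
    strand <- sample(c("+", "-"), 1)
    exons <- iv(ex_s, ex_e); cds <- iv(cd_s, cd_e)
    utr5 <- if (u5 > 0) iv(s, s + u5) else iv_empty()
    utr3 <- if (u3 > 0) iv(cd_e[n_ex], s + L) else iv_empty()
    if (strand == "-") { tmp <- utr5; utr5 <- utr3; utr3 <- tmp }
    models[[k]] <- gene_model(sprintf("g%03d", k), "chr1", strand, s, s + L,
                              exons = exons, cds = cds, utr5 = utr5,
                              utr3 = utr3, genome_id = "sim")
    cursor <- s + L + sample(200:6000, 1)
  }
  span_max <- cursor + 3000
  svs <- do.call(rbind, lapply(seq_len(n_svs), function(i) {
    ty <- sample(c("DEL", "INS", "DUP", "INV", "TRA"), 1)
    if (ty == "INS") {
      p <- sample(0:span_max, 1); s <- p; e <- p
    } else if (ty == "TRA") {
      s <- sample(0:span_max, 1); e <- sample(0:span_max, 1)
      if (e < s) { tmp <- s; s <- e; e <- tmp }
    } else {
      s <- sample(0:span_max, 1); e <- s + sample(1:400, 1)
    }
    data.frame(genome_id = "sim", chrom = "chr1", start = s, end = e,
               svtype = ty, sv_id = sprintf("sv%04d", i),
               stringsAsFactors = FALSE)
  }))
  list(models = list(sim = models), svs = svs)
}

# --- promoter scan oracle ---------------------------------------------------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_scan <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1L]]; pv <- strsplit(pattern, "")[[1L]]
  w <- length(pv); L <- length(sv)
  hits <- integer(0)
  if (L < w) return(hits)
  for (i in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!sv[i + j] %in% iupac_sets[[pv[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
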