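#' Back-translate a pair of aligned proteins onto their CDS
#'
#' Maps each aligned residue column to its source codon; columns with a gap
#' in either sequence are dropped and terminal stop codons are trimmed.
#' The ungapped proteins must match the translations of the CDS exactly.
#'
#' @param protein_aln_a,protein_aln_b Aligned amino-acid strings (may
#'   contain `-`), same length.
#' @param cds_a,cds_b Nucleotide CDS strings, multiples of 3.
#' @return List with `codons_a`, `codons_b` (character vectors of codons)
#'   and `n_codons`.
#' @export
backtranslate_alignment <- function(protein_aln_a, protein_aln_b,
                                    cds_a, cds_b) {
  if (nchar(protein_aln_a) != nchar(protein_aln_b)) {
    stop("aligned proteins differ in length", call. = FALSE)
  }
  prep <- function(paln, cds, label) {
    if (nchar(cds) %% 3 != 0) {
      stop("CDS ", label, " length is not a multiple of 3", call. = FALSE)
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- codon_aa_string(cds)
    if (endsWith(aa, "*")) {               # trim terminal stop
      aa <- substr(aa, 1, nchar(aa) - 1)
      codons <- codons[-length(codons)]
    }
    ungapped <- gsub("-", "", paln, fixed = TRUE)
    if (ungapped != aa) {
      mism <- which(strsplit(ungapped, "")[[1L]] != strsplit(aa, "")[[1L]])[1L]
      stop("protein ", label, " does not match its CDS translation (first ",
           "mismatch at residue ", mism, ")", call. = FALSE)
    }
    codons
  }
  ca <- prep(protein_aln_a, cds_a, "a")
  cb <- prep(protein_aln_b, cds_b, "b")
  cols_a <- strsplit(protein_aln_a, "")[[1L]] != "-"
  cols_b <- strsplit(protein_aln_b, "")[[1L]] != "-"
  keep <- cols_a & cols_b
  idx_a <- cumsum(cols_a); idx_b <- cumsum(cols_b)
  list(codons_a = ca[idx_a[keep]], codons_b = cb[idx_b[keep]],
       n_codons = sum(keep))
}

# fast translation via the standard code table (ambiguous codons -> X)
codon_aa_string <- function(cds) {
  n <- nchar(cds)
  aa <- genetic_code()[substring(cds, seq(1, n, 3), seq(3, n, 3))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Nei-Gojobori (1986) Ka/Ks estimate for one codon alignment
#'
#' Site counts S and N are the mean of the per-sequence sums; difference
#' counts Sd and Nd sum the pathway-averaged per-column counts
#' ([count_differences()]). Proportions pS = Sd/S and pN = Nd/N receive the
#' Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)` to give Ks and Ka;
#' `omega = Ka/Ks` is NA (undefined) when Ks = 0. Proportions at or above
#' 0.75 flag the pair as saturated (rates NA). Codon columns containing an
#' ambiguous base or a stop codon are dropped pairwise.
#'
#' @param codons_a,codons_b Equal-length character vectors of codons, or a
#'   list from [backtranslate_alignment()] passed as `codons_a`.
#' @return One-row data.frame: `n_codons`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ka`, `Ks`, `omega`, `flag` ("" | "saturated" | "stop_path").
#' @export
ng86 <- function(codons_a, codons_b = NULL) {
  if (is.list(codons_a) && is.null(codons_b)) {
    codons_b <- codons_a$codons_b; codons_a <- codons_a$codons_a
  }
  if (length(codons_a) != length(codons_b)) {
    stop("codon vectors differ in length", call. = FALSE)
  }
  ok <- grepl("^[ACGT]{3}$", codons_a) & grepl("^[ACGT]{3}$", codons_b)
  gc <- genetic_code()
  ok[ok] <- gc[codons_a[ok]] != "*" & gc[codons_b[ok]] != "*"
  a <- codons_a[ok]; b <- codons_b[ok]
  n_codons <- length(a)
  if (n_codons == 0L) stop("no usable codon columns", call. = FALSE)

  st <- site_table()
  S <- (sum(st[a, "s"]) + sum(st[b, "s"])) / 2
  N <- (sum(st[a, "n"]) + sum(st[b, "n"])) / 2

  Sd <- 0; Nd <- 0; stop_path <- FALSE
  diff <- a != b
  if (any(diff)) {
    pair_tab <- table(paste(a[diff], b[diff]))
    for (k in names(pair_tab)) {
      cd <- strsplit(k, " ", fixed = TRUE)[[1L]]
      d <- count_differences(cd[1L], cd[2L])
      Sd <- Sd + pair_tab[[k]] * d[["sd"]]
      Nd <- Nd + pair_tab[[k]] * d[["nd"]]
      if (isTRUE(attr(d, "stop_path"))) stop_path <- TRUE
    }
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  flag <- if (stop_path) "stop_path" else ""
  if (pS >= 0.75 || pN >= 0.75) {
    flag <- paste0(flag, if (nzchar(flag)) ";", "saturated")
    Ks <- NA_real_; Ka <- NA_real_; omega <- NA_real_
  } else {
    Ks <- jc(pS); Ka <- jc(pN)
    omega <- if (Ks == 0) NA_real_ else Ka / Ks
  }
  data.frame(n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ka = Ka, Ks = Ks, omega = omega,
             flag = flag, stringsAsFactors = FALSE)
}

#' Ka/Ks for every family across all genome pairs
#'
#' For each family present in at least two genomes, computes the NG86
#' estimate for every genome pair. Equal-length CDS pairs are compared
#' codon-by-codon; unequal pairs are aligned at the protein level with
#' [Biostrings::pairwiseAlignment()] and back-translated.
#'
#' @param cds_by_genome Named list (genome -> named character vector or
#'   `DNAStringSet` of family CDS, names = family ids).
#' @return Data.frame with one row per (family, genome pair): `family`,
#'   `genome_a`, `genome_b` plus the [ng86()] columns.
#' @export
kaks_all_pairs <- function(cds_by_genome) {
  genomes <- names(cds_by_genome)
  cds_by_genome <- lapply(cds_by_genome, function(x) {
    if (methods::is(x, "XStringSet")) {
      stats::setNames(as.character(x), names(x))
    } else x
  })
  fams <- sort(unique(unlist(lapply(cds_by_genome, names))))
  rows <- list()
  for (fam in fams) {
    carriers <- genomes[vapply(cds_by_genome,
                               function(x) fam %in% names(x), TRUE)]
    if (length(carriers) < 2L) next
    for (i in seq_len(length(carriers) - 1L)) {
      for (j in seq((i + 1L), length(carriers))) {
        ga <- carriers[i]; gb <- carriers[j]
        aln <- align_cds_pair(cds_by_genome[[ga]][[fam]],
                              cds_by_genome[[gb]][[fam]])
        res <- ng86(aln)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(family = fam, genome_a = ga, genome_b = gb,
                           stringsAsFactors = FALSE), res)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), genome_a = character(0),
                      genome_b = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

align_cds_pair <- function(cds_a, cds_b) {
  aa_a <- sub("\\*$", "", codon_aa_string(cds_a))
  aa_b <- sub("\\*$", "", codon_aa_string(cds_b))
  if (nchar(aa_a) == nchar(aa_b)) {
    return(backtranslate_alignment(aa_a, aa_b, cds_a, cds_b))
  }
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(aa_a),
                                      Biostrings::AAString(aa_b),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  backtranslate_alignment(as.character(Biostrings::pattern(pa)),
                          as.character(Biostrings::subject(pa)),
                          cds_a, cds_b)
}

#' Positive-selection summary across genome pairs
#'
#' Per family: the fraction of defined omegas exceeding 1 and the mode of
#' the omega distribution over a fixed-width histogram (bin width 0.1,
#' lowest bin wins ties). The headline `share_peak_gt1` is the share of
#' families whose distribution peak exceeds 1. Families with no defined
#' omega are excluded with a warning; undefined omegas never enter a
#' denominator.
#'
#' @param kaks Data.frame from [kaks_all_pairs()].
#' @param bin_width Histogram bin width for the mode, default 0.1.
#' @return List with `per_gene` (family, n_pairs, n_defined, frac_gt1,
#'   omega_mode, peak_gt1) and `share_peak_gt1`.
#' @export
selection_summary <- function(kaks, bin_width = 0.1) {
  fams <- sort(unique(kaks$family))
  rows <- lapply(fams, function(fam) {
    om <- kaks$omega[kaks$family == fam]
    def <- om[!is.na(om)]
    if (length(def) == 0L) {
      warning("family ", fam, " has no defined omega; excluded",
              call. = FALSE)
      return(NULL)
    }
    breaks <- seq(0, max(def) + bin_width, by = bin_width)
    counts <- graphics::hist(def, breaks = breaks, plot = FALSE)$counts
    mode_mid <- breaks[which.max(counts)] + bin_width / 2
    data.frame(family = fam, n_pairs = length(om), n_defined = length(def),
               frac_gt1 = mean(def > 1), omega_mode = mode_mid,
               peak_gt1 = mode_mid > 1, stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       share_peak_gt1 = if (is.null(per_gene)) NA_real_
                        else mean(per_gene$peak_gt1))
}
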