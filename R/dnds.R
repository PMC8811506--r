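## Pairwise dN/dS by synonymous/nonsynonymous counting.
##
## Counting estimator in the Nei-Gojobori tradition: synonymous and
## nonsynonymous *sites* are counted per codon from the fraction of
## single-base changes that preserve the amino acid; *differences* between two
## codons are classified by enumerating every mutational pathway (ordering of
## the differing positions) with equal weights, skipping pathways that pass
## through a stop codon; the resulting proportions are corrected for multiple
## hits with the Jukes-Cantor formula. Equal pathway weighting, the standard
## genetic code, and whole-codon exclusion of gaps/N are deliberate, simple
## conventions; no transition/transversion or codon-frequency weighting is
## applied.

GENETIC_CODE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
STOP_CODONS  <- names(GENETIC_CODE)[GENETIC_CODE == "*"]
BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) unname(GENETIC_CODE[codon])
is_stop <- function(codon) codon %in% STOP_CODONS

## single-base neighbors of `codon` at `pos`
codon_neighbors <- function(codon, pos) {
  b <- substr(codon, pos, pos)
  vapply(setdiff(BASES, b), function(nb) {
    s <- codon
    substr(s, pos, pos) <- nb
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous site fraction is the proportion of
#' admissible single-base changes (changes to stop codons are excluded from
#' the possibilities) that leave the amino acid unchanged; the nonsynonymous
#' fraction is its complement, so every codon contributes exactly 3 sites.
#'
#' @param codon 3-letter string over A/C/G/T; must not be a stop codon.
#' @return list with `s` and `n`, `s + n == 3`.
#' @examples
#' codon_site_counts("TTT")  # s = 1/3
#' codon_site_counts("TGG")  # s = 0
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% SENSE_CODONS)
    stop("not a sense codon: '", codon, "'", call. = FALSE)
  hit <- .site_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    nb <- nb[!is_stop(nb)]
    if (length(nb) == 0L) next  # cannot happen with the standard code
    s <- s + sum(translate_codon(nb) == aa) / length(nb)
  }
  out <- list(s = s, n = 3 - s)
  .site_cache[[codon]] <- out
  out
}

.site_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous differences between two codons
#'
#' Enumerates every ordering of the differing positions as a stepwise
#' mutational pathway, classifies each single-base step as synonymous or
#' nonsynonymous, and averages over the admissible pathways with equal
#' weights. Pathways passing through a stop codon are excluded; if every
#' pathway is inadmissible both counts are `NA` and the codon pair should be
#' excluded upstream.
#'
#' @param codon_a,codon_b sense codons.
#' @return list with `sd`, `nd` (`sd + nd` equals the number of differing
#'   positions when at least one pathway is admissible), and `n_pathways`,
#'   the number of admissible pathways.
#' @examples
#' codon_diff_counts("TTT", "TTC")  # sd = 1, nd = 0
#' codon_diff_counts("TTT", "GTA")  # sd = 0.5, nd = 1.5
#' @export
codon_diff_counts <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_a %in% SENSE_CODONS || !codon_b %in% SENSE_CODONS)
    stop("both codons must be sense codons", call. = FALSE)
  key <- paste0(codon_a, codon_b)
  hit <- .diff_cache[[key]]
  if (!is.null(hit)) return(hit)

  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    out <- list(sd = 0, nd = 0, n_pathways = 1L)
    .diff_cache[[key]] <- out
    return(out)
  }
  orders <- permutations(pos)
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
  for (ord in orders) {
    cur <- codon_a
    sd_i <- 0; nd_i <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (is_stop(nxt)) { ok <- FALSE; break }
      if (translate_codon(cur) == translate_codon(nxt)) sd_i <- sd_i + 1
      else nd_i <- nd_i + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd_i; nd_tot <- nd_tot + nd_i; n_ok <- n_ok + 1L }
  }
  out <- if (n_ok == 0L) list(sd = NA_real_, nd = NA_real_, n_pathways = 0L)
         else list(sd = sd_tot / n_ok, nd = nd_tot / n_ok, n_pathways = n_ok)
  .diff_cache[[key]] <- out
  out
}

.diff_cache <- new.env(parent = emptyenv())

## all orderings of a vector (k <= 3 here)
permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differences per site for multiple hits:
#' `d = -(3/4) * log(1 - 4p/3)`. Saturated inputs (`p >= 0.75`) return `NA`
#' rather than an error so a batch of estimates can proceed.
#'
#' @param p observed proportion in `[0, 0.75)`.
#' @return corrected distance `d >= p`, or `NA` at saturation.
#' @examples
#' jukes_cantor(0.3)  # ~0.3831
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p))
  ifelse(is.na(p) | p < 0 | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Estimate pairwise dN/dS from a codon alignment
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and pathway-averaged differences over all usable codon columns, converts
#' to proportions, applies the Jukes-Cantor correction, and reports
#' `omega = dN/dS`. Codon columns containing a gap, an ambiguous base, or a
#' stop codon in either sequence are excluded whole, as are the (rare) pairs
#' with no stop-free mutational pathway.
#'
#' @param seq_a,seq_b aligned, equal-length nucleotide strings over
#'   `A/C/G/T/-/N`, length a multiple of 3 with codon-respecting gaps.
#' @param ids length-2 character vector naming the sequences.
#' @param min_codons minimum usable codons (default 10, a small-input guard
#'   sized for short genes such as chemokines).
#' @return object of class `dnds_estimate`: `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega` (`NA` when undefined or saturated, `Inf`
#'   when `dS = 0 < dN`), `n_codons_used`, `n_codons_excluded`, `ids`.
#' @examples
#' est <- estimate_dnds(strrep("TTTGGG", 10), strrep("TTCGGG", 10))
#' est$omega  # 0: only synonymous change
#' @export
estimate_dnds <- function(seq_a, seq_b, ids = c("a", "b"), min_codons = 10L) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences must have equal aligned length", call. = FALSE)
  usable <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca_u <- ca[usable]; cb_u <- cb[usable]

  S <- 0; N <- 0; Sd <- 0; Nd <- 0; n_used <- 0L
  for (i in seq_along(ca_u)) {
    diff <- codon_diff_counts(ca_u[i], cb_u[i])
    if (is.na(diff$sd)) next  # no stop-free pathway; exclude the column
    sa <- codon_site_counts(ca_u[i]); sb <- codon_site_counts(cb_u[i])
    S <- S + (sa$s + sb$s) / 2
    N <- N + (sa$n + sb$n) / 2
    Sd <- Sd + diff$sd
    Nd <- Nd + diff$nd
    n_used <- n_used + 1L
  }
  if (n_used < min_codons)
    stop("alignment too short: ", n_used, " usable codons (need ",
         min_codons, ")", call. = FALSE)
  pS <- Sd / S
  pN <- Nd / N
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  omega <- if (is.na(dS) || is.na(dN)) NA_real_
           else if (dS == 0 && dN == 0) NA_real_
           else if (dS == 0) Inf
           else dN / dS
  out <- list(ids = ids, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
              pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
              n_codons_used = n_used,
              n_codons_excluded = length(ca) - n_used)
  class(out) <- "dnds_estimate"
  out
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN/dS estimate (%s vs %s), %d codons (%d excluded)\n",
              x$ids[1], x$ids[2], x$n_codons_used, x$n_codons_excluded))
  cat(sprintf("  sites  S = %.2f  N = %.2f\n", x$S_sites, x$N_sites))
  cat(sprintf("  diffs  Sd = %.2f  Nd = %.2f  (pS = %.4f, pN = %.4f)\n",
              x$Sd, x$Nd, x$pS, x$pN))
  cat(sprintf("  dS = %s  dN = %s  omega = %s\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              format(x$omega, digits = 4)))
  invisible(x)
}

#' Screen homeolog copies for dN/dS above a threshold
#'
#' For each gene, compares the diploid reference sequence against each
#' subgenome copy and flags copies whose estimated omega strictly exceeds the
#' threshold. An infinite omega (nonsynonymous change without any synonymous
#' change) flags; an undefined omega never flags. Per-gene failures (e.g.
#' alignments too short) are logged and do not abort the batch.
#'
#' @param genes named list; each element a list with an aligned nucleotide
#'   string per available sequence: `xtr` (diploid reference) and/or the
#'   subgenome copies `L`, `S` (all sequences of one gene mutually aligned).
#'   With a reference present each copy is compared against it; without one,
#'   the two copies are compared directly (`L_vs_S`).
#' @param threshold strict cutoff (default 1).
#' @param min_codons passed to [estimate_dnds()].
#' @return A `data.frame` with one row per comparison: `gene`, `comparison`
#'   (`"Xtr_vs_L"`, `"Xtr_vs_S"`, `"L_vs_S"`), `copy` (the tested copy, `NA`
#'   for a direct homeolog comparison), `omega`, `dN`, `dS`, `flagged`, and
#'   `error` (message or `NA`).
#' @export
dnds_screen <- function(genes, threshold = 1, min_codons = 10L) {
  stopifnot(length(genes) == 0L || !is.null(names(genes)))
  rows <- list()
  add_row <- function(gene, comparison, copy, seq1, seq2, ids) {
    est <- tryCatch(estimate_dnds(seq1, seq2, ids = ids, min_codons = min_codons),
                    error = function(e) e)
    row <- if (inherits(est, "error"))
      data.frame(gene = gene, comparison = comparison, copy = copy,
                 omega = NA_real_, dN = NA_real_, dS = NA_real_,
                 flagged = FALSE, error = conditionMessage(est),
                 stringsAsFactors = FALSE)
    else
      data.frame(gene = gene, comparison = comparison, copy = copy,
                 omega = est$omega, dN = est$dN, dS = est$dS,
                 flagged = !is.na(est$omega) && est$omega > threshold,
                 error = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- row
  }
  for (g in names(genes)) {
    entry <- genes[[g]]
    if (!is.null(entry$xtr)) {
      for (sub in intersect(c("L", "S"), names(entry)))
        add_row(g, paste0("Xtr_vs_", sub), paste0(g, ".", sub),
                entry$xtr, entry[[sub]],
                c(paste0(g, ".Xtr"), paste0(g, ".", sub)))
    } else if (!is.null(entry$L) && !is.null(entry$S)) {
      add_row(g, "L_vs_S", NA_character_, entry$L, entry$S,
              paste0(g, c(".L", ".S")))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, comparison = NA_character_, copy = NA_character_,
        omega = NA_real_, dN = NA_real_, dS = NA_real_, flagged = FALSE,
        error = "need a reference sequence or both homeolog copies",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), comparison = character(), copy = character(),
               omega = numeric(), dN = numeric(), dS = numeric(),
               flagged = logical(), error = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Read per-gene codon FASTA files
#'
#' Reads one FASTA of mutually aligned coding sequences per gene; sequence
#' ids carry the suffix `.Xtr`, `.L`, or `.S` (e.g. `cxcl12.L`).
#'
#' @param path FASTA file.
#' @return named list keyed by gene symbol, each element a list with any of
#'   `xtr`, `L`, `S` as character sequences, ready for [dnds_screen()].
#' @export
read_codon_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  m <- regmatches(ids, regexec("^(.*)\\.(Xtr|L|S)$", ids))
  genes <- list()
  for (i in seq_along(ids)) {
    if (length(m[[i]]) != 3L)
      stop("sequence id '", ids[i], "' lacks a .Xtr/.L/.S suffix", call. = FALSE)
    gene <- m[[i]][2]
    sub <- if (m[[i]][3] == "Xtr") "xtr" else m[[i]][3]
    genes[[gene]][[sub]] <- as.character(seqs[[i]])
  }
  genes
}

#' Write aligned codon sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
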