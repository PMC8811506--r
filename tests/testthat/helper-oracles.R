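# Independent oracles, written separately from the package implementation.
# They use seqinr's genetic-code translation (not Biostrings) and explicit
# hard-coded orderings (not the package's recursive permutation generator).

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

oracle_sense_codons <- local({
  b <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all[!vapply(all, oracle_is_stop, logical(1))]
})

# synonymous site fraction per codon: per position, synonymous changes over
# non-stop changes, summed over the three positions
oracle_site_counts <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; admissible <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_is_stop(mut)) next
      admissible <- admissible + 1
      if (oracle_translate(mut) == aa) syn <- syn + 1
    }
    if (admissible > 0) s <- s + syn / admissible
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged synonymous/nonsynonymous differences; orderings of the
# differing positions are hard-coded per k
oracle_diff_counts <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  orders <- switch(k,
    list(pos),
    list(pos[c(1, 2)], pos[c(2, 1)]),
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
  sd_sum <- 0; nd_sum <- 0; n_ok <- 0
  for (ord in orders) {
    cur <- a; sd_i <- 0; nd_i <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_is_stop(nxt)) { ok <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) sd_i <- sd_i + 1
      else nd_i <- nd_i + 1
      cur <- nxt
    }
    if (ok) { sd_sum <- sd_sum + sd_i; nd_sum <- nd_sum + nd_i; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_sum / n_ok, nd = nd_sum / n_ok)
}

# closed-form Pearson r and two-sided p via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# closed-form paired t and two-sided p
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# write a temporary catalog file from a data.frame of character columns
write_catalog_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

minimal_catalog_row <- function(gene_symbol = "genea", role = "ligand",
                                family = "CXC", present_xtr = "1",
                                present_L = "1", present_S = "1",
                                identity_pct = "80", dnds_L = "0.5",
                                dnds_S = "0.5", category_embryonic = "n/a",
                                category_tissue = "HCSE", notes = "") {
  data.frame(gene_symbol = gene_symbol, role = role, family = family,
             present_xtr = present_xtr, present_L = present_L,
             present_S = present_S, identity_pct = identity_pct,
             dnds_L = dnds_L, dnds_S = dnds_S,
             category_embryonic = category_embryonic,
             category_tissue = category_tissue, notes = notes,
             stringsAsFactors = FALSE)
}
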