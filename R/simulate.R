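## Seeded synthetic-data generators.
##
## simulate_expression() emulates the statistical structure the correlation
## analysis assumes: per homeolog pair a latent log2-scale L profile, an S
## profile with a target correlation and a mean log2 offset, independent
## clutch-level technical noise, and structural (biological) zeros shared
## across copies and clutches. simulate_codon_pair() evolves a stop-free
## ancestral coding sequence along two branches with an acceptance-ratio
## tuned toward a target dN/dS; the realized omega is ordered with, not
## numerically equal to, the target (documented in the vignette).

#' Simulate a two-clutch homeolog expression experiment
#'
#' Per pair, a latent log2(TPM+1)-scale L profile is drawn i.i.d. over
#' samples from `N(base_mean_log2, base_sd_log2^2)`; the latent S profile is
#' `base_mean_log2 - offset_log2 + rho * (L - base_mean_log2) +
#' sqrt(1 - rho^2) * e` with `e ~ N(0, base_sd_log2^2)`, giving target
#' correlation `rho` and mean L-S difference `offset_log2` with the same
#' marginal spread. Each clutch observes the latent profiles plus independent
#' `N(0, noise_sd_log2^2)` technical noise. Values are back-transformed to
#' TPM (`2^x - 1`, clipped at 0). Structural zeros are drawn once per pair
#' and sample and applied to both copies and both clutches (biological
#' absence, as opposed to clutch-level technical variation).
#'
#' @param n_pairs number of homeolog pairs.
#' @param sample_set `"tissue"` (14 samples) or `"developmental"` (11).
#' @param rho target correlation of the latent log-scale profiles, in
#'   `[-1, 1]`.
#' @param offset_log2 mean L minus S difference on the log2 scale (3 is an
#'   8-fold TPM ratio).
#' @param base_mean_log2,base_sd_log2 latent profile marginal parameters.
#' @param noise_sd_log2 clutch-level technical noise sd (log2 scale).
#' @param zero_fraction probability a pair/sample position is structurally 0.
#' @param seed integer seed; identical specs give bit-identical output.
#' @return list with `clutch_t`, `clutch_u` (TPM matrices, rows
#'   `g<i>.L`/`g<i>.S`, columns the sample set), and `truth`, a `data.frame`
#'   recording the generating `rho` and `offset_log2` per pair.
#' @examples
#' sim <- simulate_expression(3, rho = 1, offset_log2 = 0,
#'                            noise_sd_log2 = 0, seed = 1)
#' identical(sim$clutch_t, sim$clutch_u)
#' @export
simulate_expression <- function(n_pairs,
                                sample_set = c("tissue", "developmental"),
                                rho = 0.8,
                                offset_log2 = 0,
                                base_mean_log2 = 4,
                                base_sd_log2 = 2,
                                noise_sd_log2 = 0.25,
                                zero_fraction = 0.15,
                                seed = 1L) {
  sample_set <- match.arg(sample_set)
  stopifnot(n_pairs >= 0, abs(rho) <= 1, noise_sd_log2 >= 0,
            base_sd_log2 >= 0, zero_fraction >= 0, zero_fraction <= 1)
  samples <- if (sample_set == "tissue") TISSUE_SAMPLES else DEVELOPMENTAL_SAMPLES
  n_s <- length(samples)

  gene_ids <- if (n_pairs > 0) sprintf("g%03d", seq_len(n_pairs)) else character()
  row_ids <- as.vector(rbind(paste0(gene_ids, ".L"), paste0(gene_ids, ".S")))
  empty <- matrix(numeric(0), nrow = 0, ncol = n_s, dimnames = list(NULL, samples))
  if (n_pairs == 0L)
    return(list(clutch_t = empty, clutch_u = empty,
                truth = data.frame(gene_symbol = character(),
                                   rho = numeric(), offset_log2 = numeric())))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  clutch_t <- clutch_u <- matrix(0, nrow = 2L * n_pairs, ncol = n_s,
                                 dimnames = list(row_ids, samples))
  for (i in seq_len(n_pairs)) {
    zL <- stats::rnorm(n_s, base_mean_log2, base_sd_log2)
    zS <- base_mean_log2 - offset_log2 + rho * (zL - base_mean_log2) +
      sqrt(1 - rho^2) * stats::rnorm(n_s, 0, base_sd_log2)
    zero_mask <- stats::runif(n_s) < zero_fraction
    for (clutch in c("t", "u")) {
      oL <- zL + stats::rnorm(n_s, 0, noise_sd_log2)
      oS <- zS + stats::rnorm(n_s, 0, noise_sd_log2)
      tpm_L <- pmax(2^oL - 1, 0); tpm_L[zero_mask] <- 0
      tpm_S <- pmax(2^oS - 1, 0); tpm_S[zero_mask] <- 0
      if (clutch == "t") {
        clutch_t[2L * i - 1L, ] <- tpm_L; clutch_t[2L * i, ] <- tpm_S
      } else {
        clutch_u[2L * i - 1L, ] <- tpm_L; clutch_u[2L * i, ] <- tpm_S
      }
    }
  }
  list(clutch_t = clutch_t, clutch_u = clutch_u,
       truth = data.frame(gene_symbol = gene_ids, rho = rho,
                          offset_log2 = offset_log2, stringsAsFactors = FALSE))
}

#' Simulate a codon alignment pair evolved at a target dN/dS
#'
#' A random stop-free ancestral sequence (codons drawn uniformly from the 61
#' sense codons) is evolved independently along two branches. Each branch
#' receives a Poisson(`branch_subs_expected`) number of substitution
#' attempts; an attempt proposes a uniform single-base change, rejects
#' proposals creating stop codons, and otherwise accepts synonymous and
#' nonsynonymous changes with probabilities (1, `omega_target`) when
#' `omega_target <= 1`, or (`1/omega_target`, 1) when `omega_target > 1`. The
#' realized nonsynonymous/synonymous ratio therefore increases monotonically
#' with `omega_target` without claiming numerical equality.
#'
#' @param n_codons number of codons (>= 10).
#' @param omega_target target dN/dS, >= 0 (0 forbids nonsynonymous change).
#' @param branch_subs_expected expected substitution attempts per branch.
#' @param seed integer seed.
#' @return list of class `codon_alignment` with `id_a`, `id_b`, `seq_a`,
#'   `seq_b` (ungapped, equal length `3 * n_codons`), and `ancestor`.
#' @examples
#' aln <- simulate_codon_pair(50, omega_target = 0.5,
#'                            branch_subs_expected = 10, seed = 1)
#' nchar(aln$seq_a)
#' @export
simulate_codon_pair <- function(n_codons, omega_target = 0.5,
                                branch_subs_expected = 0.2 * n_codons,
                                seed = 1L) {
  stopifnot(n_codons >= 10, omega_target >= 0, branch_subs_expected >= 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  p_syn <- if (omega_target > 1) 1 / omega_target else 1
  p_non <- min(1, omega_target)

  ancestor <- sample(SENSE_CODONS, n_codons, replace = TRUE)

  evolve <- function(codons) {
    n_attempts <- stats::rpois(1L, branch_subs_expected)
    for (k in seq_len(n_attempts)) {
      ci <- sample.int(n_codons, 1L)
      pos <- sample.int(3L, 1L)
      codon <- codons[ci]
      cur_base <- substr(codon, pos, pos)
      new_base <- sample(setdiff(BASES, cur_base), 1L)
      prop <- codon
      substr(prop, pos, pos) <- new_base
      if (is_stop(prop)) next
      syn <- translate_codon(prop) == translate_codon(codon)
      p_acc <- if (syn) p_syn else p_non
      if (stats::runif(1L) < p_acc) codons[ci] <- prop
    }
    codons
  }

  seq_a <- paste(evolve(ancestor), collapse = "")
  seq_b <- paste(evolve(ancestor), collapse = "")
  structure(list(id_a = "sim.L", id_b = "sim.S",
                 seq_a = seq_a, seq_b = seq_b,
                 ancestor = paste(ancestor, collapse = "")),
            class = "codon_alignment")
}
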