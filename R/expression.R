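## Two-clutch transcriptome correlation analysis for homeolog pairs.
##
## Pipeline per clutch and sample set, in this fixed order:
##   1. floor:    TPM values <= 0.5 are set to 0 (irreproducible signal)
##   2. filter:   a pair is dropped ("n/a") if either copy is never expressed
##   3. log:      log2(TPM + 1)
##   4. tests:    Pearson correlation (profile shape) and paired t test
##                (expression level), both on the transformed profiles
## giving one of HCSE / HCDE / NCSE / NCDE per clutch; the two clutches are
## then reconciled (see reconcile_categories).

#' Default sample sets
#'
#' The developmental series spans egg to tadpole stage 40 (11 samples); the
#' adult set covers 14 organs. Oocyte stages are not part of either default
#' set: they lack a biological replicate and never enter classification.
#'
#' @name sample_sets
#' @export
DEVELOPMENTAL_SAMPLES <- c("egg", "st8", "st9", "st10.5", "st12", "st15",
                           "st20", "st25", "st30", "st35", "st40")

#' @rdname sample_sets
#' @export
TISSUE_SAMPLES <- c("brain", "eye", "lung", "stomach", "intestine", "liver",
                    "pancreas", "kidney", "testis", "ovary", "heart",
                    "muscle", "skin", "spleen")

#' Floor low TPM values
#'
#' TPM values at or below the floor are reduced to exactly 0; values above it
#' are untouched. Idempotent.
#'
#' @param x numeric vector or matrix of nonnegative TPM values.
#' @param floor nonnegative cutoff (default 0.5; signal at or below this level
#'   is considered irreproducible).
#' @return `x` with all values `<= floor` replaced by 0.
#' @examples
#' floor_tpm(c(0.5, 0.50001, 7.2))
#' @export
floor_tpm <- function(x, floor = 0.5) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
  if (any(x < 0, na.rm = TRUE)) stop("negative TPM value", call. = FALSE)
  x[x <= floor] <- 0
  x
}

#' Log-transform TPM values
#'
#' @param x nonnegative numeric vector or matrix.
#' @return `log2(x + 1)`, so 0 maps to 0.
#' @export
log2_tpm <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative TPM value", call. = FALSE)
  log2(x + 1)
}

#' Is a gene expressed anywhere?
#'
#' A gene passes the expression filter when at least one sample exceeds the
#' floor; a gene at or below the floor in every sample is removed from
#' classification (labelled `"n/a"`).
#'
#' @inheritParams floor_tpm
#' @return logical scalar.
#' @examples
#' is_expressed(c(0, 0, 0.5))   # FALSE
#' is_expressed(c(0, 0, 0.51))  # TRUE
#' @export
is_expressed <- function(x, floor = 0.5) {
  length(x) > 0L && any(x > floor, na.rm = TRUE)
}

#' Pearson correlation test
#'
#' Sample Pearson coefficient with the usual two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (as in
#' [stats::cor.test()], to which the regular case is delegated). When either
#' vector is constant the coefficient is undefined and both values are
#' returned as `NA`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  # exactly collinear profiles make cor.test's t statistic infinite; keep the
  # limit (p = 0) rather than a numerical warning
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) return(list(r = r, p = 0))
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Paired t test on expression levels
#'
#' Two-sided paired Student t test, `t = mean(d) / (sd(d) / sqrt(n))` with
#' `d = x - y` and the n - 1 denominator for `sd` (delegated to
#' [stats::t.test()] in the regular case). Degenerate differences are handled
#' as limits: all-zero differences give `t = 0, p = 1`; constant nonzero
#' differences give an infinite `t` with `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return list with `t` and `p`.
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least 2 paired samples", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Classify one homeolog pair within one clutch
#'
#' Applies the fixed pipeline (floor, expression filter, log2 transform, then
#' the two tests) to the L and S profiles of one homeolog pair and combines
#' the test outcomes into a four-way category:
#' correlation axis HC (`p <= alpha`) vs NC, level axis SE (`p > alpha`) vs DE
#' (`p <= alpha`). If either copy fails the expression filter the pair is
#' `"n/a"` and no test is run. An undefined correlation (a constant
#' transformed profile after flooring) is classified NC: high correlation
#' cannot be established, and the undefined statistic is preserved in the
#' returned stats.
#'
#' @param profile_L,profile_S nonnegative TPM vectors over the same ordered
#'   samples.
#' @param alpha significance level for both tests (default 0.05); `p = alpha`
#'   counts as HC and as DE.
#' @param tpm_floor floor passed to [floor_tpm()].
#' @return list with `category` and `stats` (`r`, `p_cor`, `t`, `p_t`).
#' @examples
#' v <- c(1, 5, 20, 3, 80, 2, 1, 9, 40, 12, 6, 2, 1, 7)
#' classify_clutch(v, v)$category           # "HCSE"
#' classify_clutch(v, v * 8)$category       # "HCDE"
#' classify_clutch(v, rep(0, 14))$category  # "n/a"
#' @export
classify_clutch <- function(profile_L, profile_S, alpha = 0.05, tpm_floor = 0.5) {
  stopifnot(length(profile_L) == length(profile_S),
            is.numeric(alpha), alpha > 0, alpha < 1)
  fL <- floor_tpm(profile_L, tpm_floor)
  fS <- floor_tpm(profile_S, tpm_floor)
  na_stats <- list(r = NA_real_, p_cor = NA_real_, t = NA_real_, p_t = NA_real_)
  if (!is_expressed(fL, tpm_floor) || !is_expressed(fS, tpm_floor))
    return(list(category = "n/a", stats = na_stats))
  lL <- log2_tpm(fL)
  lS <- log2_tpm(fS)
  ct <- pearson_test(lL, lS)
  tt <- paired_t_test(lL, lS)
  corr <- if (!is.na(ct$p) && ct$p <= alpha) "HC" else "NC"
  lvl  <- if (tt$p <= alpha) "DE" else "SE"
  list(category = paste0(corr, lvl),
       stats = list(r = ct$r, p_cor = ct$p, t = tt$t, p_t = tt$p))
}

#' Run the full two-clutch expression analysis
#'
#' Classifies every homeolog pair in each clutch separately, then reconciles
#' the per-clutch categories into a final label. The two clutches must cover
#' the same gene pairs and the same sample set; developmental and tissue
#' sample sets are never mixed within one run.
#'
#' @param clutch_t,clutch_u numeric matrices (gene copies x samples) of TPM
#'   values with rownames using the `.L`/`.S` homeolog suffix convention,
#'   e.g. `"cxcl12.L"`. Column (sample) order must match between clutches.
#' @param pairs optional character vector of gene symbols to analyse; by
#'   default every symbol with both an `.L` and an `.S` row in clutch T. A
#'   requested pair missing from either clutch is an error naming the gene.
#' @param alpha,tpm_floor see [classify_clutch()].
#' @return A `data.frame` of class `homeolog_classification`: one row per
#'   pair with per-clutch categories, the reconciled `final` label, and the
#'   per-clutch test statistics. The NA-precedence rule (either copy failing
#'   the expression filter drops the pair for that clutch) is recorded in the
#'   `na_rule` attribute.
#' @export
classify_homeologs <- function(clutch_t, clutch_u, pairs = NULL,
                               alpha = 0.05, tpm_floor = 0.5) {
  stopifnot(is.matrix(clutch_t), is.matrix(clutch_u))
  if (ncol(clutch_t) != ncol(clutch_u))
    stop("clutches must share the sample set", call. = FALSE)
  if (is.null(pairs)) {
    rn <- rownames(clutch_t)
    syms <- sub("\\.[LS]$", "", rn[grepl("\\.[LS]$", rn)])
    pairs <- sort(unique(syms[duplicated(syms)]))
  }
  cols <- c("gene_symbol", "category_T", "category_U", "final",
            "r_T", "p_cor_T", "t_T", "p_t_T",
            "r_U", "p_cor_U", "t_U", "p_t_U")
  rows <- lapply(pairs, function(g) {
    res <- lapply(list(T = clutch_t, U = clutch_u), function(m) {
      for (copy in paste0(g, c(".L", ".S")))
        if (!copy %in% rownames(m))
          stop("homeolog copy '", copy, "' missing from a clutch", call. = FALSE)
      classify_clutch(m[paste0(g, ".L"), ], m[paste0(g, ".S"), ],
                      alpha = alpha, tpm_floor = tpm_floor)
    })
    data.frame(gene_symbol = g,
               category_T = res$T$category, category_U = res$U$category,
               final = reconcile_categories(res$T$category, res$U$category),
               r_T = res$T$stats$r, p_cor_T = res$T$stats$p_cor,
               t_T = res$T$stats$t, p_t_T = res$T$stats$p_t,
               r_U = res$U$stats$r, p_cor_U = res$U$stats$p_cor,
               t_U = res$U$stats$t, p_t_U = res$U$stats$p_t,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "tpm_floor") <- tpm_floor
  attr(out, "na_rule") <- "pair is n/a for a clutch if either homeolog fails the expression filter"
  class(out) <- c("homeolog_classification", "data.frame")
  out
}

#' @export
print.homeolog_classification <- function(x, ...) {
  cat("Homeolog expression classification: ", nrow(x), " pairs (alpha = ",
      attr(x, "alpha"), ", TPM floor = ", attr(x, "tpm_floor"), ")\n", sep = "")
  if (nrow(x)) {
    tab <- table(factor(category_base(x$final),
                        levels = c(CATEGORY_FOUR, "n/a", "inc")))
    cat("final categories: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n",
        sep = "")
  }
  invisible(as.data.frame(x))
}

#' Read a TPM expression matrix
#'
#' Tab-separated, first column the gene copy identifier (`.L`/`.S` suffix
#' convention), remaining columns samples; `#`-prefixed lines are ignored.
#'
#' @param path file path.
#' @return numeric matrix, gene copies x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs id + sample columns", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (any(is.na(m))) stop("non-numeric TPM value in ", path, call. = FALSE)
  if (any(m < 0)) stop("negative TPM value in ", path, call. = FALSE)
  m
}

#' Write a TPM expression matrix
#'
#' @param m matrix as returned by [read_expression_matrix()].
#' @param path output file.
#' @param header optional character vector of `#`-prefixed metadata lines.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}
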