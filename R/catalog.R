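## Homeolog catalog: loading and subgenome retention accounting.
##
## The catalog is a flat gene-family table, one row per gene family member,
## recording presence in the diploid reference (X. tropicalis) and in the two
## allotetraploid subgenomes (X. laevis L and S), peptide identity between
## homeologs, per-copy dN/dS against the diploid reference, and the
## expression-divergence categories from the two-clutch transcriptome
## correlation analysis. The packaged fixture covers the chemokine ligand and
## receptor repertoire.

CATALOG_COLUMNS <- c("gene_symbol", "role", "family",
                     "present_xtr", "present_L", "present_S",
                     "identity_pct", "dnds_L", "dnds_S",
                     "category_embryonic", "category_tissue", "notes")

#' Load a homeolog catalog
#'
#' Reads a tab-separated catalog with one header row and the columns
#' `gene_symbol`, `role` (ligand/receptor), `family` (CXC/CC/XC), `present_xtr`,
#' `present_L`, `present_S` (1/0 presence flags), `identity_pct`, `dnds_L`,
#' `dnds_S`, `category_embryonic`, `category_tissue`, `notes`. Missing values
#' use the single sentinel token `NA`. Category labels use the vocabulary of
#' [parse_category()].
#'
#' @param path path to a tab-separated catalog file; defaults to the packaged
#'   chemokine catalog.
#' @return A `data.frame` of class `homeolog_catalog`, one row per gene family
#'   member, with logical presence columns and numeric identity/dN/dS columns.
#' @examples
#' cat <- read_catalog()
#' nrow(cat)
#' @export
read_catalog <- function(path = system.file("extdata", "chemokine_catalog.tsv",
                                            package = "homeologdiv")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA",
                          quote = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[CATALOG_COLUMNS]
  if (nrow(df) == 0L) {
    out <- df
    class(out) <- c("homeolog_catalog", "data.frame")
    return(out)
  }

  dup <- df$gene_symbol[duplicated(df$gene_symbol)]
  if (length(dup))
    stop("duplicate gene symbol(s) in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)

  to_flag <- function(col) {
    v <- df[[col]]
    if (any(is.na(v) | !v %in% c("0", "1")))
      stop("column '", col, "' must be 0/1", call. = FALSE)
    v == "1"
  }
  df$present_xtr <- to_flag("present_xtr")
  df$present_L   <- to_flag("present_L")
  df$present_S   <- to_flag("present_S")

  to_num <- function(col, lo, hi) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("malformed numeric value in column '", col, "', row ", bad[1L],
           " (", df$gene_symbol[bad[1L]], ")", call. = FALSE)
    out_of_range <- which(!is.na(v) & (v < lo | v > hi))
    if (length(out_of_range))
      stop("value out of range in column '", col, "', row ", out_of_range[1L],
           " (", df$gene_symbol[out_of_range[1L]], ")", call. = FALSE)
    v
  }
  df$identity_pct <- to_num("identity_pct", 0, 100)
  df$dnds_L <- to_num("dnds_L", 0, Inf)
  df$dnds_S <- to_num("dnds_S", 0, Inf)

  for (col in c("category_embryonic", "category_tissue"))
    invisible(lapply(df[[col]], parse_category))  # rejects unknown labels

  bad_role <- which(!df$role %in% c("ligand", "receptor"))
  if (length(bad_role))
    stop("unknown role in row ", bad_role[1L], ": '", df$role[bad_role[1L]], "'",
         call. = FALSE)
  orphan <- which(!df$present_xtr & !df$present_L & !df$present_S)
  if (length(orphan))
    stop("row ", orphan[1L], " (", df$gene_symbol[orphan[1L]],
         ") is present in no genome", call. = FALSE)
  # identity/dN/dS only meaningful where the corresponding copies exist
  if (any(!is.na(df$identity_pct) & !(df$present_L & df$present_S)))
    stop("identity_pct set for a gene without both homeologs", call. = FALSE)
  if (any(!is.na(df$dnds_L) & !df$present_L) || any(!is.na(df$dnds_S) & !df$present_S))
    stop("dN/dS set for an absent homeolog", call. = FALSE)

  class(df) <- c("homeolog_catalog", "data.frame")
  df
}

filter_role <- function(entries, role = c("all", "ligand", "receptor")) {
  role <- match.arg(role)
  if (role != "all") entries <- entries[entries$role == role, , drop = FALSE]
  entries
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Subgenome retention summary
#'
#' Counts how many genes of the diploid reference set are retained on each
#' allotetraploid subgenome, and tallies homeolog pairs and singletons among
#' the polyploid's genes. Retention rates use the reference-present genes as
#' denominator; pair/singleton tallies cover all polyploid entries regardless
#' of reference presence.
#'
#' @param entries a `homeolog_catalog`.
#' @param role `"ligand"`, `"receptor"`, or `"all"`.
#' @return A list with `role`, `n_xtr`, `n_L`, `n_S`, `rate_L`, `rate_S`
#'   (fractions, `NA` when `n_xtr` is 0), `n_pairs`, `n_L_singletons`,
#'   `n_S_singletons`.
#' @examples
#' retention_summary(read_catalog(), "ligand")
#' @export
retention_summary <- function(entries, role = c("all", "ligand", "receptor")) {
  e <- filter_role(entries, role)
  if (nrow(e) == 0L) stop("no catalog entries after role filter", call. = FALSE)
  ref <- e[e$present_xtr, , drop = FALSE]
  n_xtr <- nrow(ref)
  n_L <- sum(ref$present_L)
  n_S <- sum(ref$present_S)
  list(role = match.arg(role),
       n_xtr = n_xtr, n_L = n_L, n_S = n_S,
       rate_L = if (n_xtr > 0) n_L / n_xtr else NA_real_,
       rate_S = if (n_xtr > 0) n_S / n_xtr else NA_real_,
       n_pairs = sum(e$present_L & e$present_S),
       n_L_singletons = sum(e$present_L & !e$present_S),
       n_S_singletons = sum(!e$present_L & e$present_S))
}

#' Homeolog pair and singleton tally
#'
#' @inheritParams retention_summary
#' @return A list with `n_pairs` (genes retained on both subgenomes),
#'   `n_singletons` (retained on exactly one), and `n_genes`, the number of
#'   polyploid gene copies: `2 * n_pairs + n_singletons`.
#' @examples
#' pair_singleton_tally(read_catalog(), "ligand")
#' @export
pair_singleton_tally <- function(entries, role = c("all", "ligand", "receptor")) {
  e <- filter_role(entries, role)
  if (nrow(e) == 0L) stop("no catalog entries after role filter", call. = FALSE)
  n_pairs <- sum(e$present_L & e$present_S)
  n_singletons <- sum(xor(e$present_L, e$present_S))
  list(n_pairs = n_pairs, n_singletons = n_singletons,
       n_genes = 2L * n_pairs + n_singletons)
}

#' Mean peptide identity between homeologs
#'
#' Arithmetic mean over the non-missing identity percentages; reported both
#' unrounded and rounded to the nearest integer (half away from zero, the
#' convention used for all printed percentages in this package).
#'
#' @inheritParams retention_summary
#' @return list with `mean` (unrounded), `rounded`, `n` (values used).
#' @examples
#' mean_identity(read_catalog(), "receptor")
#' @export
mean_identity <- function(entries, role = c("all", "ligand", "receptor")) {
  e <- filter_role(entries, role)
  v <- e$identity_pct[!is.na(e$identity_pct)]
  if (length(v) == 0L)
    return(list(mean = NA_real_, rounded = NA_real_, n = 0L))
  m <- mean(v)
  list(mean = m, rounded = round_half_up(m), n = length(v))
}

#' Screen homeolog pairs for elevated dN/dS
#'
#' A pair is eligible when both per-copy dN/dS values are present; it is
#' flagged when either copy's ratio strictly exceeds the threshold (so a copy
#' at exactly 1.00 is not flagged at the default threshold).
#'
#' @inheritParams retention_summary
#' @param threshold positive ratio cutoff (default 1, the neutral boundary).
#' @return list with `n_exceeding_pairs`, `n_eligible_pairs`, and
#'   `flagged_copies`, a character vector of copy names like `"xcl1.L"`.
#' @examples
#' omega_exceedance(read_catalog(), "ligand")
#' @export
omega_exceedance <- function(entries, role = c("all", "ligand", "receptor"),
                             threshold = 1) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  e <- filter_role(entries, role)
  eligible <- !is.na(e$dnds_L) & !is.na(e$dnds_S)
  el <- e[eligible, , drop = FALSE]
  hit_L <- el$dnds_L > threshold
  hit_S <- el$dnds_S > threshold
  flagged <- c(paste0(el$gene_symbol[hit_L], ".L", recycle0 = TRUE),
               paste0(el$gene_symbol[hit_S], ".S", recycle0 = TRUE))
  list(n_exceeding_pairs = sum(hit_L | hit_S),
       n_eligible_pairs = nrow(el),
       flagged_copies = sort(flagged))
}

#' Tally expression-divergence categories
#'
#' Counts catalog entries per category base for one analysis (embryonic
#' developmental series or adult tissues). Inconsistent labels are counted
#' under `inc` whatever their recorded common axis; rows with no label at all
#' (singletons, no data) are reported as `unlabeled`.
#'
#' @inheritParams retention_summary
#' @param which `"embryonic"` or `"tissue"`.
#' @return Named integer vector with counts for `HCSE`, `HCDE`, `NCSE`,
#'   `NCDE`, `n/a`, `inc`, and `unlabeled`.
#' @examples
#' category_tally(read_catalog(), "tissue")
#' @export
category_tally <- function(entries, which = c("tissue", "embryonic"),
                           role = c("all", "ligand", "receptor")) {
  which <- match.arg(which)
  e <- filter_role(entries, role)
  col <- if (which == "tissue") e$category_tissue else e$category_embryonic
  base <- category_base(col)
  levels <- c(CATEGORY_FOUR, "n/a", "inc")
  counts <- vapply(levels, function(l) sum(!is.na(base) & base == l), integer(1))
  c(counts, unlabeled = sum(is.na(base)))
}

#' @export
print.homeolog_catalog <- function(x, ...) {
  cat("Homeolog catalog: ", nrow(x), " gene family members (",
      sum(x$role == "ligand"), " ligands, ",
      sum(x$role == "receptor"), " receptors)\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Overview summary of a homeolog catalog
#'
#' Convenience wrapper computing, per role, the retention summary, the
#' pair/singleton tally, mean homeolog identity and the dN/dS exceedance
#' screen, plus the tissue and embryonic category tallies.
#'
#' @param object a `homeolog_catalog`.
#' @param omega_threshold cutoff passed to [omega_exceedance()].
#' @param ... unused.
#' @return A list of class `homeolog_catalog_summary`.
#' @method summary homeolog_catalog
#' @export
summary.homeolog_catalog <- function(object, omega_threshold = 1, ...) {
  per_role <- lapply(c(ligand = "ligand", receptor = "receptor"), function(r) {
    list(retention = retention_summary(object, r),
         tally = pair_singleton_tally(object, r),
         identity = mean_identity(object, r),
         omega = omega_exceedance(object, r, omega_threshold))
  })
  out <- list(roles = per_role,
              tissue = category_tally(object, "tissue"),
              embryonic = category_tally(object, "embryonic"),
              omega_threshold = omega_threshold)
  class(out) <- "homeolog_catalog_summary"
  out
}

#' @export
print.homeolog_catalog_summary <- function(x, ...) {
  for (r in names(x$roles)) {
    z <- x$roles[[r]]
    cat(sprintf("%s: %d genes (%d pairs + %d singletons)\n",
                r, z$tally$n_genes, z$tally$n_pairs, z$tally$n_singletons))
    cat(sprintf("  retention: L %d/%d (%.0f%%), S %d/%d (%.0f%%)\n",
                z$retention$n_L, z$retention$n_xtr, 100 * z$retention$rate_L,
                z$retention$n_S, z$retention$n_xtr, 100 * z$retention$rate_S))
    if (z$identity$n > 0)
      cat(sprintf("  mean homeolog identity: %.2f%% (rounded %d%%) over %d pairs\n",
                  z$identity$mean, as.integer(z$identity$rounded), z$identity$n))
    cat(sprintf("  dN/dS > %g: %d/%d pairs%s\n", x$omega_threshold,
                z$omega$n_exceeding_pairs, z$omega$n_eligible_pairs,
                if (length(z$omega$flagged_copies))
                  paste0(" [", paste(z$omega$flagged_copies, collapse = ", "), "]")
                else ""))
  }
  cat("tissue categories:   ",
      paste(names(x$tissue), x$tissue, sep = "=", collapse = " "), "\n")
  cat("embryonic categories:",
      paste(names(x$embryonic), x$embryonic, sep = "=", collapse = " "), "\n")
  invisible(x)
}
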