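## Category labels for homeolog expression divergence.
##
## A pair classified within one clutch gets one of five labels:
##   HCSE, HCDE, NCSE, NCDE  -- High/No Correlation x Same/Different Expression
##   n/a                     -- pair dropped by the expression filter
## After reconciling two clutches the label may also be:
##   inc                     -- clutches disagree, no axis in common
##   inc:HC / inc:NC / inc:SE / inc:DE -- disagree, one axis agrees
##   inc:NA                  -- one clutch classified, the other was n/a
## A missing label (no data at all, e.g. a singleton) is NA_character_.

CATEGORY_FOUR   <- c("HCSE", "HCDE", "NCSE", "NCDE")
CATEGORY_CLUTCH <- c(CATEGORY_FOUR, "n/a")
CATEGORY_INC    <- c("inc", "inc:HC", "inc:NC", "inc:SE", "inc:DE", "inc:NA")
CATEGORY_ALL    <- c(CATEGORY_CLUTCH, CATEGORY_INC)

#' Validate and decompose a category label
#'
#' Category labels are plain strings (`"HCSE"`, `"n/a"`, `"inc:HC"`, ...).
#' `parse_category()` checks a label against the known vocabulary and splits
#' an inconsistent label into its base and the axis the clutches agreed on.
#'
#' @param x character scalar, or `NA` for a missing label.
#' @return A list with elements `base` (one of `HCSE`, `HCDE`, `NCSE`, `NCDE`,
#'   `n/a`, `inc`, or `NA` for missing) and `inc_common` (`"HC"`, `"NC"`,
#'   `"SE"`, `"DE"`, `"NA"`, or `NA` when absent; only ever set for `inc`).
#' @examples
#' parse_category("inc:HC")
#' parse_category("NCDE")
#' @export
parse_category <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x)) return(list(base = NA_character_, inc_common = NA_character_))
  x <- as.character(x)
  if (!x %in% CATEGORY_ALL)
    stop("unknown category label: '", x, "'", call. = FALSE)
  if (startsWith(x, "inc")) {
    common <- if (x == "inc") NA_character_ else sub("^inc:", "", x)
    list(base = "inc", inc_common = common)
  } else {
    list(base = x, inc_common = NA_character_)
  }
}

#' @rdname parse_category
#' @export
category_base <- function(x) {
  vapply(x, function(xi) parse_category(xi)$base, character(1), USE.NAMES = FALSE)
}

## axis accessors for the four-way labels
corr_axis  <- function(x) substr(x, 1L, 2L)   # "HC" / "NC"
level_axis <- function(x) substr(x, 3L, 4L)   # "SE" / "DE"

#' Reconcile per-clutch categories into a final label
#'
#' Two biological replicate clutches are classified independently; a pair is
#' only assigned a definitive category when both clutches agree. Disagreement
#' yields an "inconsistent" label that records the axis (correlation or
#' expression level) on which the clutches did agree, if any; a pair that was
#' filtered out (`"n/a"`) in one clutch but classified in the other is
#' `"inc:NA"`. The operation is symmetric in its two arguments.
#'
#' @param cat_a,cat_b per-clutch labels, each one of `"HCSE"`, `"HCDE"`,
#'   `"NCSE"`, `"NCDE"`, `"n/a"`.
#' @return A single reconciled label string.
#' @examples
#' reconcile_categories("HCSE", "HCSE")  # "HCSE"
#' reconcile_categories("HCSE", "HCDE")  # "inc:HC"
#' reconcile_categories("NCDE", "n/a")   # "inc:NA"
#' @export
reconcile_categories <- function(cat_a, cat_b) {
  stopifnot(length(cat_a) == 1L, length(cat_b) == 1L,
            !is.na(cat_a), !is.na(cat_b))
  if (!cat_a %in% CATEGORY_CLUTCH || !cat_b %in% CATEGORY_CLUTCH)
    stop("per-clutch labels must be one of: ",
         paste(CATEGORY_CLUTCH, collapse = ", "), call. = FALSE)
  if (cat_a == cat_b) return(cat_a)            # includes n/a + n/a -> n/a
  if (cat_a == "n/a" || cat_b == "n/a") return("inc:NA")
  if (corr_axis(cat_a) == corr_axis(cat_b))  return(paste0("inc:", corr_axis(cat_a)))
  if (level_axis(cat_a) == level_axis(cat_b)) return(paste0("inc:", level_axis(cat_a)))
  "inc"
}
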