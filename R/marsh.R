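#' Marsh grade vocabulary
#'
#' Histological grading of the duodenal mucosa under the modified Marsh
#' criteria: `M0` normal, `M1` lymphocytic duodenosis, `M2` crypt
#' hyperplasia, `M3a`--`M3c` increasing degrees of villous atrophy.
#' `UNKNOWN` marks records without an interpretable biopsy and carries no
#' ordering.
#'
#' @format Character vector of the seven recognised grade labels.
#' @export
marsh_levels <- c("M0", "M1", "M2", "M3a", "M3b", "M3c", "UNKNOWN")

# graded levels only, in severity order (UNKNOWN excluded)
marsh_ordered_levels <- c("M0", "M1", "M2", "M3a", "M3b", "M3c")

#' Coerce to a Marsh grade factor
#'
#' Builds an ordered factor over the graded levels `M0 < M1 < M2 < M3a <
#' M3b < M3c`; the label `UNKNOWN` maps to `NA` in the ordered scale.
#' Unrecognised labels are an error.
#'
#' @param x character vector of grade labels.
#' @return Ordered factor with levels `M0` through `M3c`; `UNKNOWN`
#'   becomes `NA`.
#' @examples
#' marsh_grade(c("M0", "M3b", "UNKNOWN"))
#' @export
marsh_grade <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% marsh_levels
  if (any(bad)) {
    stop("unrecognised Marsh grade(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x[x == "UNKNOWN"] <- NA_character_
  factor(x, levels = marsh_ordered_levels, ordered = TRUE)
}

#' Does a Marsh grade denote villous atrophy?
#'
#' Villous atrophy is present exactly for grades M3a, M3b and M3c; all
#' other grades, including `UNKNOWN` and `NA`, return `FALSE`.
#'
#' @param marsh character vector (or Marsh factor) of grade labels.
#' @return Logical vector.
#' @examples
#' has_villous_atrophy(c("M1", "M3a", "UNKNOWN"))
#' @export
has_villous_atrophy <- function(marsh) {
  as.character(marsh) %in% c("M3a", "M3b", "M3c")
}

#' Diagnosis vocabulary
#'
#' The three mutually exclusive outcomes of the coeliac case definition:
#' `COELIAC`, `NOT_COELIAC`, and `INDETERMINATE` (villous atrophy with
#' negative or missing serology that HLA typing cannot resolve).
#'
#' @format Character vector of the three diagnosis labels.
#' @export
diagnosis_levels <- c("COELIAC", "NOT_COELIAC", "INDETERMINATE")
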