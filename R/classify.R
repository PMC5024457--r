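#' Apply the coeliac disease case definition
#'
#' A record is `COELIAC` when it shows villous atrophy (Marsh 3a-3c) with
#' a positive IgA-EMA or IgA-TTG. Seronegative villous atrophy is
#' resolved by HLA-DQ2/DQ8: a negative phenotype rules coeliac disease
#' out (`NOT_COELIAC`); a positive or unknown phenotype leaves the record
#' `INDETERMINATE`. Without villous atrophy the record is `NOT_COELIAC`
#' regardless of serology. Missing serology counts as not-positive, never
#' as negative evidence on its own.
#'
#' Every record must be biopsied with a graded biopsy; an `UNKNOWN` Marsh
#' grade is an error, as the definition is histology-anchored.
#'
#' @param cohort a `patient_cohort` data frame (or any data frame with
#'   the same columns).
#' @return Character vector of diagnoses, one per record, over
#'   [diagnosis_levels].
#' @examples
#' g2 <- group2_cohort()
#' table(classify_coeliac(g2))
#' @export
classify_coeliac <- function(cohort) {
  unclassifiable <- is.na(cohort$biopsied) | !cohort$biopsied |
    cohort$marsh == "UNKNOWN"
  if (any(unclassifiable)) {
    stop("unclassifiable record(s) (not biopsied or Marsh UNKNOWN): ",
         paste(cohort$id[unclassifiable], collapse = ", "),
         call. = FALSE)
  }
  va <- has_villous_atrophy(cohort$marsh)
  sero_pos <- (!is.na(cohort$ema_positive) & cohort$ema_positive) |
    (!is.na(cohort$tta_positive) & cohort$tta_positive)
  out <- rep("NOT_COELIAC", nrow(cohort))
  out[va & sero_pos] <- "COELIAC"
  seroneg_va <- va & !sero_pos
  out[seroneg_va & cohort$hla_dq2_dq8 == "negative"] <- "NOT_COELIAC"
  out[seroneg_va & cohort$hla_dq2_dq8 != "negative"] <- "INDETERMINATE"
  out
}

#' Summarise the histological yield of a biopsied cohort
#'
#' Tallies a fully biopsied cohort into histology categories (normal,
#' lymphocytic duodenosis, crypt hyperplasia, villous atrophy, plus any
#' labels in an optional `finding` column, which override "normal"), and
#' computes coeliac prevalence under a chosen policy for
#' `INDETERMINATE` records: count them as coeliac, as not coeliac, or
#' report them separately (the default, in which case prevalence counts
#' only confirmed cases).
#'
#' Records graded Marsh 2 with positive serology do not meet the villous
#' atrophy requirement; they are counted in
#' `n_review_marsh2_seropositive` for manual review rather than silently
#' dropped.
#'
#' @param cohort a `patient_cohort` data frame; every record biopsied.
#' @param diagnoses per-record diagnoses; defaults to
#'   [classify_coeliac()] on `cohort`.
#' @param indeterminate_policy `"report_separately"` (default),
#'   `"count_as_coeliac"` or `"count_as_not"`.
#' @return Object of class `audit_summary`: totals per category, coeliac
#'   count and prevalence, indeterminate count, review count, and a
#'   `category_breakdown` table summing to `n_total`.
#' @examples
#' audit_cohort(group3_cohort(), indeterminate_policy = "count_as_coeliac")
#' @export
audit_cohort <- function(cohort, diagnoses = classify_coeliac(cohort),
                         indeterminate_policy = c("report_separately",
                                                  "count_as_coeliac",
                                                  "count_as_not")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (any(!cohort$biopsied)) {
    stop("audit requires every record biopsied", call. = FALSE)
  }
  finding <- if ("finding" %in% names(cohort)) {
    as.character(cohort$finding)
  } else {
    rep(NA_character_, nrow(cohort))
  }
  va <- has_villous_atrophy(cohort$marsh)
  category <- ifelse(va, "villous_atrophy",
              ifelse(cohort$marsh == "M1", "lymphocytic_duodenosis",
              ifelse(cohort$marsh == "M2", "crypt_hyperplasia",
              ifelse(!is.na(finding), finding, "normal"))))
  n_total <- nrow(cohort)
  n_indeterminate <- sum(diagnoses == "INDETERMINATE")
  n_coeliac <- sum(diagnoses == "COELIAC") +
    if (indeterminate_policy == "count_as_coeliac") n_indeterminate else 0L
  sero_pos <- (!is.na(cohort$ema_positive) & cohort$ema_positive) |
    (!is.na(cohort$tta_positive) & cohort$tta_positive)
  breakdown <- table(category)
  res <- list(
    n_total = n_total,
    n_normal = sum(category == "normal"),
    n_marsh1 = sum(category == "lymphocytic_duodenosis"),
    n_villous_atrophy = sum(category == "villous_atrophy"),
    n_coeliac = as.integer(n_coeliac),
    n_indeterminate = as.integer(n_indeterminate),
    n_other_findings = sum(!category %in% c(
      "normal", "lymphocytic_duodenosis", "crypt_hyperplasia",
      "villous_atrophy")),
    n_review_marsh2_seropositive = sum(cohort$marsh == "M2" & sero_pos),
    prevalence = n_coeliac / n_total,
    indeterminate_policy = indeterminate_policy,
    category_breakdown = breakdown
  )
  stopifnot(sum(breakdown) == n_total)
  structure(res, class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("Histology audit of %d biopsied patients\n", x$n_total))
  b <- x$category_breakdown
  for (k in names(b)) {
    cat(sprintf("  %-24s %4d (%.1f%%)\n", k, b[[k]],
                100 * b[[k]] / x$n_total))
  }
  cat(sprintf("Coeliac disease: %d (prevalence %.1f%%, indeterminate %s)\n",
              x$n_coeliac, 100 * x$prevalence,
              switch(x$indeterminate_policy,
                     count_as_coeliac = "counted as coeliac",
                     count_as_not = "counted as not coeliac",
                     report_separately =
                       sprintf("reported separately: %d",
                               x$n_indeterminate))))
  if (x$n_review_marsh2_seropositive > 0) {
    cat(sprintf("Flagged for review (Marsh 2, seropositive): %d\n",
                x$n_review_marsh2_seropositive))
  }
  invisible(x)
}

#' Pre-endoscopy serology availability
#'
#' Proportion of endoscoped patients whose coeliac serology was available
#' beforehand, with an exact Clopper-Pearson interval.
#'
#' @param n_with_serology count with serology available.
#' @param n_total cohort size (>= 1).
#' @param conf_level two-sided confidence level.
#' @return A [proportion_estimate].
#' @examples
#' serology_availability(315, 934)
#' @export
serology_availability <- function(n_with_serology, n_total,
                                  conf_level = 0.95) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  if (n_with_serology < 0 || n_with_serology > n_total) {
    stop("n_with_serology must lie in [0, n_total]", call. = FALSE)
  }
  proportion_estimate(n_with_serology, n_total, conf_level)
}
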