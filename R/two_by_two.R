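#' Construct a 2x2 diagnostic contingency table
#'
#' Cross-classification of an index-test result against a disease
#' reference standard: `tp` diseased and test-positive, `fp` non-diseased
#' test-positive, `fn` diseased test-negative, `tn` non-diseased
#' test-negative.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @param n_excluded number of records excluded while tabulating (missing
#'   test result or indeterminate reference), zero for hand-built tables.
#' @return Object of class `two_by_two`.
#' @examples
#' two_by_two(26, 19, 0, 88)
#' @export
two_by_two <- function(tp, fp, fn, tn, n_excluded = 0L) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table has no observations", call. = FALSE)
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn),
         n_excluded = as.integer(n_excluded)),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("disease", "no disease"),
                              c("test+", "test-")))
  print(m)
  if (x$n_excluded > 0) cat("(", x$n_excluded, "record(s) excluded )\n")
  invisible(x)
}

#' Tabulate an index test against a reference diagnosis
#'
#' Builds the 2x2 table of one index test over a cohort. Records with a
#' missing result for that test, or whose reference diagnosis is
#' `INDETERMINATE` or missing, are excluded and counted in
#' `n_excluded` -- missing is never coerced to negative.
#'
#' @param cohort a `patient_cohort` data frame.
#' @param index_test which test to tabulate: `"poc"` (point-of-care
#'   DGP test), `"tta"` (IgA-TTG) or `"ema"` (IgA-EMA).
#' @param reference character vector of per-record diagnoses
#'   (`COELIAC` / `NOT_COELIAC` / `INDETERMINATE`), typically from
#'   [classify_coeliac()]. Defaults to classifying `cohort` itself.
#' @return A [two_by_two] table.
#' @examples
#' g2 <- group2_cohort()
#' make_two_by_two(g2, "poc")
#' @export
make_two_by_two <- function(cohort,
                            index_test = c("poc", "tta", "ema"),
                            reference = classify_coeliac(cohort)) {
  index_test <- match.arg(index_test)
  col <- switch(index_test, poc = "poc_result", tta = "tta_positive",
                ema = "ema_positive")
  result <- cohort[[col]]
  if (length(reference) != nrow(cohort)) {
    stop("reference must supply one diagnosis per record", call. = FALSE)
  }
  bad <- !is.na(reference) & !reference %in% diagnosis_levels
  if (any(bad)) {
    stop("invalid diagnosis label(s): ",
         paste(unique(reference[bad]), collapse = ", "), call. = FALSE)
  }
  usable <- !is.na(result) & !is.na(reference) &
    reference != "INDETERMINATE"
  if (!any(usable)) {
    stop("no analyzable records: every record has a missing ",
         index_test, " result or an indeterminate reference",
         call. = FALSE)
  }
  disease <- reference[usable] == "COELIAC"
  pos <- result[usable]
  two_by_two(
    tp = sum(disease & pos), fp = sum(!disease & pos),
    fn = sum(disease & !pos), tn = sum(!disease & !pos),
    n_excluded = sum(!usable)
  )
}
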