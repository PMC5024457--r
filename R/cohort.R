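#' @keywords internal
"_PACKAGE"

# canonical column order of a patient cohort data frame
cohort_columns <- c("id", "anaemic", "poc_result", "tta_titre",
                    "tta_positive", "ema_positive", "iga_deficient",
                    "marsh", "hla_dq2_dq8", "biopsied", "sample_date")

#' IgA-TTG positivity cutoff eras
#'
#' The assay cutoff changed twice over the study window: titres were
#' positive above 15 U/ml before 2014-05-20, above 9 U/ml from 2014-05-20
#' to 2014-12-11, and above 7 U/ml from 2014-12-12 onwards. Returned as a
#' data frame of era start dates and cutoffs, oldest first; the first era
#' is open-ended into the past.
#'
#' @return Data frame with columns `from` (Date) and `cutoff` (U/ml).
#' @export
ttg_cutoff_eras <- function() {
  data.frame(
    from   = as.Date(c("1900-01-01", "2014-05-20", "2014-12-12")),
    cutoff = c(15, 9, 7)
  )
}

#' TTG cutoff applicable on a date
#'
#' @param date Date vector of sample dates.
#' @param eras cutoff-era table as returned by [ttg_cutoff_eras()].
#' @return Numeric vector of positivity cutoffs in U/ml.
#' @export
ttg_cutoff <- function(date, eras = ttg_cutoff_eras()) {
  date <- as.Date(date)
  idx <- findInterval(as.numeric(date), as.numeric(eras$from))
  idx[idx == 0L] <- 1L
  eras$cutoff[idx]
}

#' Construct a patient cohort table
#'
#' One row per subject. Test results (`poc_result`, `tta_positive`,
#' `ema_positive`, `iga_deficient`) are ternary: `TRUE` positive, `FALSE`
#' negative, `NA` missing -- missing is distinct from negative and
#' excludes the record from tables built on that test. `marsh` uses the
#' [marsh_levels] vocabulary and must be `"UNKNOWN"` whenever `biopsied`
#' is `FALSE`. `hla_dq2_dq8` is `"positive"`, `"negative"` or
#' `"unknown"`. When both a titre and a sample date are present,
#' `tta_positive` must agree with the cutoff of the corresponding era.
#'
#' @param id character subject identifiers (opaque; no ordering
#'   semantics).
#' @param anaemic logical, iron deficiency with (`TRUE`) or without
#'   (`FALSE`) anaemia.
#' @param poc_result,tta_positive,ema_positive,iga_deficient logical
#'   ternaries as above.
#' @param tta_titre numeric IgA-TTG titre in U/ml, `NA` when unmeasured.
#' @param marsh character Marsh grade labels.
#' @param hla_dq2_dq8 character HLA-DQ2/DQ8 status.
#' @param biopsied logical.
#' @param sample_date Date of serology sampling (`NA` allowed).
#' @param extra optional data frame of additional columns carried along
#'   untouched.
#' @return A `patient_cohort` data frame.
#' @examples
#' patient_cohort(id = "p1", anaemic = TRUE, poc_result = TRUE,
#'                tta_positive = TRUE, ema_positive = TRUE,
#'                marsh = "M3a", biopsied = TRUE)
#' @export
patient_cohort <- function(id, anaemic = NA, poc_result = NA,
                           tta_titre = NA_real_, tta_positive = NA,
                           ema_positive = NA, iga_deficient = NA,
                           marsh = "UNKNOWN", hla_dq2_dq8 = "unknown",
                           biopsied = TRUE, sample_date = as.Date(NA),
                           extra = NULL) {
  n <- length(id)
  df <- data.frame(
    id            = as.character(id),
    anaemic       = rep_len(as.logical(anaemic), n),
    poc_result    = rep_len(as.logical(poc_result), n),
    tta_titre     = rep_len(as.numeric(tta_titre), n),
    tta_positive  = rep_len(as.logical(tta_positive), n),
    ema_positive  = rep_len(as.logical(ema_positive), n),
    iga_deficient = rep_len(as.logical(iga_deficient), n),
    marsh         = rep_len(as.character(marsh), n),
    hla_dq2_dq8   = rep_len(as.character(hla_dq2_dq8), n),
    biopsied      = rep_len(as.logical(biopsied), n),
    sample_date   = rep(as.Date(sample_date), length.out = n),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  validate_cohort(df)
}

#' Validate a patient cohort data frame
#'
#' Checks column presence and types, vocabulary membership, the
#' biopsy/Marsh consistency rule, non-negative titres, duplicate ids, and
#' titre/cutoff agreement where derivable. Extra columns are preserved.
#'
#' @param df data frame with at least the columns of a patient cohort
#'   (`sample_date` optional, defaulting to `NA`).
#' @param eras TTG cutoff-era table, see [ttg_cutoff_eras()].
#' @return `df` invisibly classed as `patient_cohort`, columns in
#'   canonical order first.
#' @export
validate_cohort <- function(df, eras = ttg_cutoff_eras()) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("cohort has no records", call. = FALSE)
  if (!"sample_date" %in% names(df)) df$sample_date <- as.Date(NA)
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicate patient ids", call. = FALSE)
  bad_marsh <- !df$marsh %in% marsh_levels
  if (any(bad_marsh)) {
    stop("invalid Marsh grade(s): ",
         paste(unique(df$marsh[bad_marsh]), collapse = ", "),
         call. = FALSE)
  }
  bad_hla <- !df$hla_dq2_dq8 %in% c("positive", "negative", "unknown")
  if (any(bad_hla)) {
    stop("invalid HLA status value(s): ",
         paste(unique(df$hla_dq2_dq8[bad_hla]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(df$tta_titre) & df$tta_titre < 0)) {
    stop("negative TTG titre", call. = FALSE)
  }
  unbiopsied_graded <- !is.na(df$biopsied) & !df$biopsied &
    df$marsh != "UNKNOWN"
  if (any(unbiopsied_graded)) {
    stop("record(s) not biopsied but carrying a Marsh grade: ",
         paste(df$id[unbiopsied_graded], collapse = ", "), call. = FALSE)
  }
  derivable <- !is.na(df$tta_titre) & !is.na(df$sample_date) &
    !is.na(df$tta_positive)
  if (any(derivable)) {
    expect <- df$tta_titre[derivable] >
      ttg_cutoff(df$sample_date[derivable], eras)
    clash <- expect != df$tta_positive[derivable]
    if (any(clash)) {
      stop("tta_positive inconsistent with titre and cutoff era for: ",
           paste(df$id[derivable][clash], collapse = ", "), call. = FALSE)
    }
  }
  df <- df[, c(cohort_columns, setdiff(names(df), cohort_columns)),
           drop = FALSE]
  class(df) <- unique(c("patient_cohort", class(df)))
  df
}
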