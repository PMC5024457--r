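ternary_to_string <- function(x) {
  ifelse(is.na(x), "", ifelse(x, "positive", "negative"))
}

string_to_ternary <- function(x) {
  x <- trimws(tolower(x))
  out <- rep(NA, length(x))
  out[x == "positive"] <- TRUE
  out[x == "negative"] <- FALSE
  out
}

#' Write a patient cohort to CSV
#'
#' Serialises the cohort in the package's patient table schema: ternary
#' results as `positive`/`negative`/empty, booleans as `true`/`false`,
#' dates ISO-8601. Extra columns are written verbatim, so simulated and
#' observed cohorts round-trip identically.
#'
#' @param cohort a `patient_cohort` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in c("poc_result", "tta_positive", "ema_positive",
                "iga_deficient")) {
    out[[col]] <- ternary_to_string(out[[col]])
  }
  for (col in c("anaemic", "biopsied")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "true", "false"))
  }
  out$sample_date <- ifelse(is.na(out$sample_date), "",
                            format(out$sample_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

#' Read a patient cohort from delimited text
#'
#' Parses a patient table (comma-delimited by default, tab accepted)
#' against the fixed schema. The header row is mandatory and must
#' contain every schema column (`sample_date` may be absent); unknown
#' columns are preserved but ignored by the analyses. Empty strings and
#' `NA` map to missing. Rows violating a field vocabulary or a record
#' invariant are skipped, never silently coerced; their row numbers and
#' messages are returned in the `validation` attribute.
#'
#' @param path file to read.
#' @param sep field delimiter, `","` or `"\t"`.
#' @return A `patient_cohort`; attribute `validation` is a data frame
#'   of skipped rows (zero rows when the file is clean).
#' @examples
#' path <- system.file("extdata", "group2_synthetic.csv",
#'                     package = "coeliactriage")
#' nrow(read_patient_table(path))
#' @export
read_patient_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", comment.char = ""),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  required <- setdiff(cohort_columns, "sample_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("malformed header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("file has no data rows", call. = FALSE)
  if (!"sample_date" %in% names(raw)) raw$sample_date <- ""

  blank_to_na <- function(x) {
    x <- trimws(x)
    x[x == "" | toupper(x) == "NA"] <- NA
    x
  }
  raw[] <- lapply(raw, blank_to_na)

  parse_logical <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    out
  }

  errs <- data.frame(row = integer(), message = character())
  note <- function(rows, msg) {
    if (any(rows)) {
      errs <<- rbind(errs, data.frame(row = which(rows), message = msg))
    }
  }

  tern_cols <- c("poc_result", "tta_positive", "ema_positive",
                 "iga_deficient")
  for (col in tern_cols) {
    bad <- !is.na(raw[[col]]) &
      !tolower(trimws(raw[[col]])) %in% c("positive", "negative")
    note(bad, paste0("invalid ", col, " value"))
  }
  for (col in c("anaemic", "biopsied")) {
    bad <- !is.na(raw[[col]]) &
      !tolower(raw[[col]]) %in% c("true", "t", "1", "yes", "false",
                                  "f", "0", "no")
    note(bad, paste0("invalid ", col, " value"))
  }
  marsh <- raw$marsh
  marsh[is.na(marsh)] <- "UNKNOWN"
  note(!marsh %in% marsh_levels, "invalid marsh value")
  hla <- raw$hla_dq2_dq8
  hla[is.na(hla)] <- "unknown"
  note(!tolower(hla) %in% c("positive", "negative", "unknown"),
       "invalid hla_dq2_dq8 value")
  titre <- suppressWarnings(as.numeric(raw$tta_titre))
  note(!is.na(raw$tta_titre) & is.na(titre), "unparseable tta_titre")
  note(!is.na(titre) & titre < 0, "negative tta_titre")
  date <- suppressWarnings(as.Date(raw$sample_date,
                                   format = "%Y-%m-%d"))
  note(!is.na(raw$sample_date) & is.na(date), "unparseable sample_date")
  biopsied <- parse_logical(raw$biopsied)
  note(!is.na(biopsied) & !biopsied & marsh != "UNKNOWN",
       "marsh grade present but record not biopsied")
  note(is.na(raw$id), "missing id")

  keep <- !seq_len(nrow(raw)) %in% errs$row
  if (!any(keep)) {
    stop("no valid rows in ", path, " (",
         nrow(errs), " rejected)", call. = FALSE)
  }
  extra_cols <- setdiff(names(raw), c(cohort_columns, ""))
  cohort <- patient_cohort(
    id = raw$id[keep],
    anaemic = parse_logical(raw$anaemic)[keep],
    poc_result = string_to_ternary(raw$poc_result)[keep],
    tta_titre = titre[keep],
    tta_positive = string_to_ternary(raw$tta_positive)[keep],
    ema_positive = string_to_ternary(raw$ema_positive)[keep],
    iga_deficient = string_to_ternary(raw$iga_deficient)[keep],
    marsh = marsh[keep],
    hla_dq2_dq8 = tolower(hla)[keep],
    biopsied = biopsied[keep],
    sample_date = date[keep],
    extra = if (length(extra_cols)) {
      raw[keep, extra_cols, drop = FALSE]
    }
  )
  rownames(cohort) <- NULL
  attr(cohort, "validation") <- errs
  cohort
}

#' End-to-end triage evaluation report
#'
#' Runs the whole analysis on one cohort: classifies every record,
#' builds the 2x2 and full accuracy panel for each index test present,
#' audits the histology yield, and costs the biopsy-avoidance strategy
#' from the point-of-care-negative count. Optionally writes a
#' machine-readable JSON report (full precision, monetary values in
#' pence plus display strings, versioned schema) and a plain-text
#' summary rounded as conventionally printed (percentages to 1 decimal
#' place, likelihood ratios to 2, money to whole pounds).
#'
#' @param cohort a `patient_cohort`, or a path to a patient CSV.
#' @param econ an [econ_params] object, or a path to a JSON/YAML
#'   config.
#' @param output_json,output_text optional output paths.
#' @param conf_level confidence level for all intervals.
#' @param indeterminate_policy passed to [audit_cohort()].
#' @return The report as a list (class `triage_report`), invisibly when
#'   written to file.
#' @examples
#' rep <- run_report(group2_cohort())
#' rep$economics$net_saving_per_100_display
#' @export
run_report <- function(cohort, econ = econ_params(),
                       output_json = NULL, output_text = NULL,
                       conf_level = 0.95,
                       indeterminate_policy = "count_as_coeliac") {
  if (is.character(cohort)) cohort <- read_patient_table(cohort)
  if (is.character(econ)) econ <- read_econ_config(econ)
  if (!any(cohort$biopsied)) {
    stop("cohort has no biopsied records; reference standard ",
         "(duodenal histology) unavailable", call. = FALSE)
  }
  if (any(!cohort$biopsied)) {
    stop("unbiopsied record(s) present; reference standard requires ",
         "histology for every analysed patient", call. = FALSE)
  }
  dx <- classify_coeliac(cohort)

  tests <- c(poc = "Point-of-care DGP", tta = "IgA-TTG",
             ema = "IgA-EMA")
  panels <- list()
  for (t in names(tests)) {
    col <- switch(t, poc = "poc_result", tta = "tta_positive",
                  ema = "ema_positive")
    if (all(is.na(cohort[[col]]))) next
    tab <- make_two_by_two(cohort, t, dx)
    panels[[t]] <- performance_panel(tab, tests[[t]], conf_level)
  }
  if (!length(panels)) {
    stop("no index-test columns with any results present ",
         "(need poc_result, tta_positive or ema_positive)",
         call. = FALSE)
  }
  audit <- audit_cohort(cohort, dx, indeterminate_policy)

  econ_result <- NULL
  if (!is.null(panels$poc)) {
    tab <- panels$poc$table
    n_used <- tab$tp + tab$fp + tab$fn + tab$tn
    econ_result <- cohort_economics(n_used, tab$fn + tab$tn, econ)
  }

  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("coeliactriage")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(cohort),
    conf_level = conf_level,
    panels = lapply(panels, panel_to_list),
    audit = audit_to_list(audit),
    economics = if (!is.null(econ_result)) econ_to_list(econ_result)
  )
  class(report) <- "triage_report"

  if (!is.null(output_json)) {
    jsonlite::write_json(unclass(report), output_json,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  if (!is.null(output_text)) {
    writeLines(utils::capture.output(print(report)), output_text)
  }
  if (is.null(output_json) && is.null(output_text)) report
  else invisible(report)
}

prop_to_list <- function(p) {
  list(numerator = p$numerator, denominator = p$denominator,
       point = p$point, lower = p$lower, upper = p$upper)
}

panel_to_list <- function(panel) {
  tab <- panel$table
  list(
    test_name = panel$test_name,
    table = list(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
                 n_excluded = tab$n_excluded),
    sensitivity = prop_to_list(panel$sensitivity),
    specificity = prop_to_list(panel$specificity),
    ppv = prop_to_list(panel$ppv),
    npv = prop_to_list(panel$npv),
    prevalence = prop_to_list(panel$prevalence),
    plr = if (is.na(panel$plr)) NULL else panel$plr,
    nlr = if (is.na(panel$nlr)) NULL else panel$nlr
  )
}

audit_to_list <- function(a) {
  list(n_total = a$n_total, n_normal = a$n_normal,
       n_marsh1 = a$n_marsh1,
       n_villous_atrophy = a$n_villous_atrophy,
       n_coeliac = a$n_coeliac,
       n_indeterminate = a$n_indeterminate,
       n_other_findings = a$n_other_findings,
       n_review_marsh2_seropositive = a$n_review_marsh2_seropositive,
       prevalence = a$prevalence,
       indeterminate_policy = a$indeterminate_policy,
       category_breakdown = as.list(a$category_breakdown))
}

econ_to_list <- function(e) {
  cl <- e$params$currency_label
  disp <- function(p) sprintf("%s%d", cl, round_half_away(p / 100))
  list(
    n_total = e$n_total, n_negative = e$n_negative,
    avoided_fraction = e$avoided_fraction,
    gross_saving_pence = e$gross_saving_pence,
    kit_spend_pence = e$kit_spend_pence,
    net_saving_pence = e$net_saving_pence,
    net_saving_per_100_pence = e$net_saving_per_100_pence,
    tariff_saving_per_100_pence = e$tariff_saving_per_100_pence,
    gross_saving_display = disp(e$gross_saving_pence),
    kit_spend_display = disp(e$kit_spend_pence),
    net_saving_display = disp(e$net_saving_pence),
    net_saving_per_100_display = disp(e$net_saving_per_100_pence),
    tariff_saving_per_100_display = disp(e$tariff_saving_per_100_pence),
    currency_label = cl
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("Coeliac triage report (schema %s, n = %d)\n",
              x$schema_version, x$n_records))
  for (p in x$panels) {
    fmt <- function(pr) {
      sprintf("%.1f (%.1f-%.1f)", 100 * pr$point, 100 * pr$lower,
              100 * pr$upper)
    }
    cat(sprintf("\n%s: TP %d FP %d FN %d TN %d\n", p$test_name,
                p$table$tp, p$table$fp, p$table$fn, p$table$tn))
    cat(sprintf("  sens %s  spec %s\n  PPV  %s  NPV  %s\n",
                fmt(p$sensitivity), fmt(p$specificity), fmt(p$ppv),
                fmt(p$npv)))
    if (!is.null(p$plr)) {
      cat(sprintf("  PLR %s  NLR %s\n",
                  if (is.infinite(p$plr)) "Inf"
                  else sprintf("%.2f", p$plr),
                  sprintf("%.2f", p$nlr)))
    }
  }
  a <- x$audit
  cat(sprintf("\nHistology audit: %d patients, %d normal (%.1f%%), %d Marsh 1 (%.1f%%), prevalence %.1f%%\n",
              a$n_total, a$n_normal, 100 * a$n_normal / a$n_total,
              a$n_marsh1, 100 * a$n_marsh1 / a$n_total,
              100 * a$prevalence))
  e <- x$economics
  if (!is.null(e)) {
    cat(sprintf("\nEconomics: %.1f%% biopsies avoided; gross %s, kits %s, net %s; per 100: net %s, tariff %s\n",
                100 * e$avoided_fraction, e$gross_saving_display,
                e$kit_spend_display, e$net_saving_display,
                e$net_saving_per_100_display,
                e$tariff_saving_per_100_display))
  }
  invisible(x)
}
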