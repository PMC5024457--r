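#' Economic parameters of the biopsy-avoidance model
#'
#' Three unit costs drive the model: the histopathology charge for
#' reporting one patient's duodenal biopsy set (default GBP 86), the
#' price of one point-of-care test kit (default GBP 20), and the tariff
#' difference between a gastroscopy with and without biopsy (default
#' GBP 38) -- the saving accruing to the national payer per avoided
#' biopsy. Amounts are given in major units (pounds) and stored
#' internally in integer pence so cohort-level arithmetic is exact.
#'
#' @param biopsy_histology_cost cost of biopsy histology per patient,
#'   major units.
#' @param kit_cost cost of one test kit, major units.
#' @param tariff_delta per-procedure tariff difference, major units.
#' @param currency_label display label.
#' @return Object of class `econ_params` with `*_pence` integer fields.
#' @examples
#' econ_params()
#' @export
econ_params <- function(biopsy_histology_cost = 86, kit_cost = 20,
                        tariff_delta = 38, currency_label = "£") {
  to_pence <- function(x, what) {
    if (is.na(x) || x < 0) {
      stop(what, " must be a non-negative amount", call. = FALSE)
    }
    p <- round(x * 100)
    if (abs(p - x * 100) > 1e-6) {
      stop(what, " has sub-pence precision", call. = FALSE)
    }
    as.integer(p)
  }
  structure(
    list(biopsy_histology_cost_pence =
           to_pence(biopsy_histology_cost, "biopsy_histology_cost"),
         kit_cost_pence = to_pence(kit_cost, "kit_cost"),
         tariff_delta_pence = to_pence(tariff_delta, "tariff_delta"),
         currency_label = currency_label),
    class = "econ_params"
  )
}

#' @export
print.econ_params <- function(x, ...) {
  cl <- x$currency_label
  cat(sprintf(
    "Economic parameters: biopsy histology %s%.2f, kit %s%.2f, tariff delta %s%.2f\n",
    cl, x$biopsy_histology_cost_pence / 100,
    cl, x$kit_cost_pence / 100, cl, x$tariff_delta_pence / 100))
  invisible(x)
}

#' Read economic parameters from a JSON or YAML config
#'
#' Expects keys `biopsy_histology_cost`, `kit_cost`, `tariff_delta` and
#' optionally `currency_label`, amounts in major units. The format is
#' chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path config file path.
#' @return An [econ_params] object.
#' @export
read_econ_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config extension: .", ext, call. = FALSE))
  need <- c("biopsy_histology_cost", "kit_cost", "tariff_delta")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("config missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  econ_params(
    biopsy_histology_cost = as.numeric(cfg$biopsy_histology_cost),
    kit_cost = as.numeric(cfg$kit_cost),
    tariff_delta = as.numeric(cfg$tariff_delta),
    currency_label = if (!is.null(cfg$currency_label)) {
      cfg$currency_label
    } else "£"
  )
}

# round half away from zero to whole major units, as printed figures do
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cost chain of the biopsy-only-if-positive strategy
#'
#' Under the triage strategy every patient is tested and only
#' test-positives are biopsied, so the `n_negative` test-negative
#' patients avoid biopsy histology. The gross saving is
#' `n_negative x biopsy_histology_cost`, the kit spend
#' `n_total x kit_cost`, and the departmental net saving their
#' difference (possibly negative). Per-100-gastroscopy figures rescale
#' by `100 / n_total` without intermediate rounding; the
#' `tariff_saving_per_100` applies the tariff delta instead of the
#' histology cost, giving the payer-level figure.
#'
#' Fractional counts are accepted so that expected (average) cohorts can
#' be costed; with integer counts all cohort-level amounts are exact in
#' pence.
#'
#' @param n_total number tested (>= 1).
#' @param n_negative number test-negative, in `[0, n_total]`.
#' @param params an [econ_params] object.
#' @return Object of class `econ_result`; monetary fields in pence,
#'   with a print method in major units.
#' @examples
#' cohort_economics(133, 88, econ_params())
#' @export
cohort_economics <- function(n_total, n_negative,
                             params = econ_params()) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  if (n_negative < 0 || n_negative > n_total) {
    stop("n_negative must lie in [0, n_total]", call. = FALSE)
  }
  gross <- n_negative * params$biopsy_histology_cost_pence
  kit <- n_total * params$kit_cost_pence
  net <- gross - kit
  structure(
    list(n_total = n_total, n_negative = n_negative,
         avoided_fraction = n_negative / n_total,
         gross_saving_pence = gross, kit_spend_pence = kit,
         net_saving_pence = net,
         net_saving_per_100_pence = net * 100 / n_total,
         tariff_saving_per_100_pence =
           params$tariff_delta_pence * n_negative * 100 / n_total,
         params = params),
    class = "econ_result"
  )
}

#' @export
print.econ_result <- function(x, ...) {
  cl <- x$params$currency_label
  pounds <- function(p) sprintf("%s%d", cl, round_half_away(p / 100))
  cat(sprintf("Biopsy-avoidance economics (n = %g, %g test-negative, %.1f%% avoided)\n",
              x$n_total, x$n_negative, 100 * x$avoided_fraction))
  cat(sprintf("  gross saving (avoided histology)  %s\n",
              pounds(x$gross_saving_pence)))
  cat(sprintf("  kit spend                         %s\n",
              pounds(x$kit_spend_pence)))
  cat(sprintf("  net departmental saving           %s\n",
              pounds(x$net_saving_pence)))
  cat(sprintf("  net saving per 100 gastroscopies  %s\n",
              pounds(x$net_saving_per_100_pence)))
  cat(sprintf("  tariff saving per 100 (payer)     %s\n",
              pounds(x$tariff_saving_per_100_pence)))
  invisible(x)
}

#' Expected test-negative fraction of a screened population
#'
#' For prevalence `p` and a test with the given sensitivity and
#' specificity, the expected proportion testing negative is
#' `(1 - p) sp + p (1 - se)`: true negatives plus false negatives. At a
#' cohort's own empirical parameters this reproduces its observed
#' negative fraction identically.
#'
#' @param prevalence,sensitivity,specificity proportions in `[0, 1]`.
#' @return Expected negative fraction.
#' @examples
#' expected_negative_fraction(26/133, 1, 88/107)  # = 88/133
#' @export
expected_negative_fraction <- function(prevalence, sensitivity,
                                       specificity) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (1 - prevalence) * specificity + prevalence * (1 - sensitivity)
}

#' Expected savings across a prevalence grid
#'
#' Applies the cost chain to the expected (fractional) counts of a
#' reference cohort of `n_reference` patients at each prevalence in
#' `p_grid`, holding test accuracy and costs fixed. Money is computed on
#' expectations; no integer rounding of counts.
#'
#' @param p_grid strictly increasing prevalences in `[0, 1]`.
#' @param sensitivity,specificity test accuracy assumed constant across
#'   prevalences.
#' @param params an [econ_params] object.
#' @param n_reference reference cohort size (default 100).
#' @return Data frame with one row per prevalence: expected negative
#'   fraction, expected net saving and tariff saving per `n_reference`
#'   (major units, unrounded).
#' @examples
#' prevalence_sweep(c(0.05, 26/133), 1, 88/107)
#' @export
prevalence_sweep <- function(p_grid, sensitivity, specificity,
                             params = econ_params(),
                             n_reference = 100) {
  if (length(p_grid) == 0) stop("empty prevalence grid", call. = FALSE)
  if (any(p_grid < 0 | p_grid > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(p_grid, strictly = TRUE)) {
    stop("p_grid must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(p_grid, function(p) {
    f_neg <- expected_negative_fraction(p, sensitivity, specificity)
    econ <- cohort_economics(n_reference, f_neg * n_reference, params)
    data.frame(
      prevalence = p,
      expected_negative_fraction = f_neg,
      net_saving = econ$net_saving_pence / 100,
      tariff_saving = econ$tariff_saving_per_100_pence / 100 *
        n_reference / 100
    )
  })
  do.call(rbind, rows)
}

#' Break-even analysis of the triage strategy
#'
#' The per-patient net saving is
#' `f_neg x biopsy_histology_cost - kit_cost`, so the strategy breaks
#' even at a negative fraction of `kit_cost / biopsy_histology_cost`,
#' and, for a given negative fraction, at a kit cost of
#' `f_neg x biopsy_histology_cost`. When sensitivity and specificity are
#' supplied the break-even negative fraction is also translated into a
#' break-even prevalence through [expected_negative_fraction()].
#'
#' @param params an [econ_params] object with positive biopsy cost.
#' @param sensitivity,specificity optional test accuracy for the
#'   prevalence translation.
#' @return List with `break_even_negative_fraction`,
#'   `break_even_kit_cost_at` (a function of the negative fraction,
#'   returning major units), and `break_even_prevalence` (`NA` when not
#'   derivable).
#' @examples
#' break_even(econ_params())$break_even_negative_fraction  # 20/86
#' @export
break_even <- function(params = econ_params(), sensitivity = NULL,
                       specificity = NULL) {
  b <- params$biopsy_histology_cost_pence
  if (b <= 0) stop("biopsy histology cost must be positive", call. = FALSE)
  f_star <- params$kit_cost_pence / b
  prev_star <- NA_real_
  if (!is.null(sensitivity) && !is.null(specificity)) {
    slope <- specificity - (1 - sensitivity)
    if (slope != 0) {
      p <- (specificity - f_star) / slope
      if (p >= 0 && p <= 1) prev_star <- p
    }
  }
  list(
    break_even_negative_fraction = f_star,
    break_even_kit_cost_at = function(f_neg) f_neg * b / 100,
    break_even_prevalence = prev_star
  )
}
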