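# End-to-end study replication: cohort table in, agreement report and
# maturity regression out.

#' Study configuration
#'
#' Settings for [run_study()]: the significance level of the
#' normality-gated location tests, the acceptability thresholds, which
#' equations to assess and which columns hold the reference values.
#'
#' @param alpha two-tailed significance level, default 0.05.
#' @param icc_threshold,cv_threshold acceptability thresholds, defaults
#'   0.8 and 10 (percent).
#' @param equations equation ids to assess (default all five).
#' @param reference_columns named character vector with entries `fm`
#'   and `lm` giving the reference column names.
#' @return list of class `study_config`.
#' @export
study_config <- function(alpha = 0.05, icc_threshold = 0.8,
                         cv_threshold = 10,
                         equations = equation_ids(),
                         reference_columns = c(fm = "dxa_fm_kg",
                                               lm = "dxa_lm_kg")) {
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(icc_threshold, "icc_threshold")
  check_number(cv_threshold, "cv_threshold", lower = 0)
  equations <- match.arg(equations, equation_ids(), several.ok = TRUE)
  if (!all(c("fm", "lm") %in% names(reference_columns))) {
    stop_input("reference_columns must name entries 'fm' and 'lm'")
  }
  structure(list(alpha = alpha, icc_threshold = icc_threshold,
                 cv_threshold = cv_threshold, equations = equations,
                 reference_columns = reference_columns),
            class = "study_config")
}

summarise_mean_sd <- function(x) c(mean = mean(x), sd = sd(x))

#' Run the full validity study on a cohort
#'
#' Applies every configured prediction equation, derives fat and lean
#' mass in kg, estimates each subject's maturity offset and post-PHV
#' group, and computes the complete agreement report of each equation
#' against the reference columns (fat mass and lean mass compared in
#' kg), a regression of each equation's lean mass on maturity offset,
#' and — when second-replicate skinfold columns are present — the
#' intra-rater reliability block (pooled ICC, pooled %TEM and the
#' per-site typical-error CV range). Deterministic for a fixed cohort.
#'
#' @param cohort cohort data.frame (schema of [cohort_schema()]).
#' @param config a [study_config()].
#' @param input optional label recorded in the provenance block (e.g.
#'   the input file path).
#' @return object of class `study_report`: a list with elements
#'   `estimates` (per-subject long table), `estimate_summary`,
#'   `reference_summary`, `maturity` (per-subject offset and group),
#'   `maturity_counts`, `agreement` (one row per equation x outcome),
#'   `regression` (one row per equation), `intra_rater` (or NULL),
#'   `ba_coords` (per-subject Bland-Altman coordinates) and
#'   `provenance`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 12, seed = 3))
#' report <- run_study(cohort)
#' report$agreement[, c("equation", "outcome", "icc", "verdict")]
#' @export
run_study <- function(cohort, config = study_config(), input = NA) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (n < 3L) stop_input("need at least 3 subjects, got %d", n)
  cfg <- config
  ref_fm <- cohort[[cfg$reference_columns[["fm"]]]]
  ref_lm <- cohort[[cfg$reference_columns[["lm"]]]]

  estimates <- estimate_all(cohort, equations = cfg$equations)
  offsets <- maturity_offset(cohort$age_yr, cohort$height_cm,
                             cohort$sitting_height_cm,
                             cohort$body_mass_kg)
  maturity <- data.frame(id = cohort$id, offset = offsets,
                         group = classify_maturity_group(offsets))

  agreement <- list()
  regression <- list()
  ba_coords <- list()
  for (eq in cfg$equations) {
    est <- estimates[estimates$equation == eq, ]
    for (outc in c("fm", "lm")) {
      x <- if (outc == "fm") est$fm_kg else est$lm_kg
      y <- if (outc == "fm") ref_fm else ref_lm
      agreement[[paste(eq, outc)]] <- agreement_report(
        x, y, equation = eq, outcome = outc, alpha = cfg$alpha,
        icc_threshold = cfg$icc_threshold,
        cv_threshold = cfg$cv_threshold)
      co <- bland_altman_coords(x, y, ids = est$id)
      co$equation <- eq
      co$outcome <- outc
      ba_coords[[paste(eq, outc)]] <- co
    }
    reg <- lm_maturity_regression(est$lm_kg, offsets)
    regression[[eq]] <- data.frame(equation = eq, slope = reg$slope,
                                   intercept = reg$intercept,
                                   r2 = reg$r2, r2_adj = reg$r2_adj,
                                   f = reg$f, df1 = reg$df1,
                                   df2 = reg$df2, p = reg$p, n = reg$n)
  }
  agreement <- do.call(rbind, c(unname(agreement),
                                list(make.row.names = FALSE)))
  regression <- do.call(rbind, c(unname(regression),
                                 list(make.row.names = FALSE)))
  ba_coords <- do.call(rbind, c(unname(ba_coords),
                                list(make.row.names = FALSE)))

  est_summary <- do.call(rbind, lapply(split(estimates,
                                             estimates$equation),
    function(d) data.frame(equation = d$equation[1L],
                           fm_percent_mean = mean(d$fm_percent),
                           fm_percent_sd = sd(d$fm_percent),
                           fm_kg_mean = mean(d$fm_kg),
                           fm_kg_sd = sd(d$fm_kg),
                           lm_kg_mean = mean(d$lm_kg),
                           lm_kg_sd = sd(d$lm_kg))))
  rownames(est_summary) <- NULL

  structure(list(
    estimates = estimates,
    estimate_summary = est_summary,
    reference_summary = data.frame(
      fm_kg_mean = mean(ref_fm), fm_kg_sd = sd(ref_fm),
      lm_kg_mean = mean(ref_lm), lm_kg_sd = sd(ref_lm)),
    maturity = maturity,
    maturity_counts = as.data.frame(table(group = maturity$group),
                                    responseName = "count"),
    agreement = agreement,
    regression = regression,
    intra_rater = intra_rater_block(cohort),
    ba_coords = ba_coords,
    provenance = list(
      input = input, n = n,
      package = "anthroval",
      version = as.character(packageVersion("anthroval")),
      alpha = cfg$alpha, icc_threshold = cfg$icc_threshold,
      cv_threshold = cfg$cv_threshold,
      equations = cfg$equations,
      reference_columns = as.list(cfg$reference_columns),
      timestamp = format(Sys.time(), tz = "UTC",
                         "%Y-%m-%dT%H:%M:%SZ"))
  ), class = "study_report")
}

# pooled intra-rater reliability over the ten sites, NULL when the
# cohort carries no replicate columns
intra_rater_block <- function(cohort) {
  rep_cols <- paste0("sf_", skinfold_sites(), "_mm_rep2")
  if (!all(rep_cols %in% names(cohort))) return(NULL)
  first_cols <- paste0("sf_", skinfold_sites(), "_mm")
  first <- as.matrix(cohort[, first_cols])
  second <- as.matrix(cohort[, rep_cols])
  pooled_tem <- tem(as.vector(first), as.vector(second))
  site_cv <- vapply(seq_along(first_cols), function(j)
    typical_error_cv(first[, j], second[, j])$cv_mean, numeric(1))
  list(icc = icc_a1(cbind(as.vector(first), as.vector(second))),
       tem_abs_mm = pooled_tem$tem_abs,
       tem_percent = pooled_tem$tem_percent,
       tem_pass = pooled_tem$pass,
       cv_min = min(site_cv), cv_max = max(site_cv))
}

#' @export
print.study_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Skinfold-equation validity study (n = %d)\n", p$n))
  cat(sprintf("  thresholds: ICC >= %.3g, CV <= %.3g%%, alpha = %.3g\n",
              p$icc_threshold, p$cv_threshold, p$alpha))
  a <- x$agreement
  cat("\nAgreement vs reference:\n")
  print(data.frame(equation = a$equation, outcome = a$outcome,
                   icc = round(a$icc, 3), cv = round(a$cv_mean, 1),
                   bias = round(a$bias, 2), verdict = a$verdict),
        row.names = FALSE)
  if (!is.null(x$intra_rater)) {
    cat(sprintf("\nIntra-rater: ICC %.3f, TEM %.2f%%, CV %.2f-%.2f%%\n",
                x$intra_rater$icc, x$intra_rater$tem_percent,
                x$intra_rater$cv_min, x$intra_rater$cv_max))
  }
  invisible(x)
}

#' Write study outputs
#'
#' `write_study_report()` serialises the full report (full-precision
#' values) to JSON. `write_agreement_csv()` emits the agreement table
#' with exactly the columns equation, outcome, n, icc, cv_mean, cv_sd,
#' bias, loa_lower, loa_upper, pct_diff_mean, pct_diff_sd, effect_size,
#' es_band, test, statistic, p, verdict. `write_ba_csv()` emits the
#' per-subject Bland-Altman coordinates for plotting.
#'
#' @param report a `study_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_report
#' @export
write_agreement_csv <- function(report, path) {
  cols <- c("equation", "outcome", "n", "icc", "cv_mean", "cv_sd",
            "bias", "loa_lower", "loa_upper", "pct_diff_mean",
            "pct_diff_sd", "effect_size", "es_band", "test",
            "statistic", "p", "verdict")
  readr::write_csv(report$agreement[, cols], path)
  invisible(path)
}

#' @rdname write_study_report
#' @export
write_ba_csv <- function(report, path) {
  readr::write_csv(report$ba_coords, path)
  invisible(path)
}

round_df <- function(d, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(d)) d[[nm]] <- round(d[[nm]], digits[[nm]])
  }
  d
}

#' Render a study report as text tables
#'
#' Markdown (or CSV) rendering of the agreement and regression tables
#' in the style of a published validity study: kg and percent values to
#' one decimal, ICC and p to three.
#'
#' @param report a `study_report` (or a path to a JSON report).
#' @param format `"md"` or `"csv"`.
#' @return character vector of lines.
#' @export
report_tables <- function(report, format = c("md", "csv")) {
  format <- match.arg(format)
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  agr <- round_df(as.data.frame(report$agreement),
                  c(icc = 3, cv_mean = 1, cv_sd = 1, bias = 2,
                    sd_diff = 2, loa_lower = 2, loa_upper = 2,
                    pct_diff_mean = 1, pct_diff_sd = 1,
                    effect_size = 2, statistic = 2, p = 3))
  reg <- round_df(as.data.frame(report$regression),
                  c(slope = 2, intercept = 1, r2 = 3, r2_adj = 3,
                    f = 2, p = 3))
  if (format == "csv") {
    return(c(readr::format_csv(agr), readr::format_csv(reg)))
  }
  md_table <- function(d, title) {
    header <- paste0("| ", paste(names(d), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
    rows <- apply(d, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(title, "", header, sep, rows, "")
  }
  c(md_table(agr, "## Agreement vs reference"),
    md_table(reg, "## Lean mass on maturity offset"))
}
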