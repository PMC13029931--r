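# Synthetic cohorts with known ground truth. The reference (DXA-like)
# fat mass is generated from one designated prediction equation plus a
# configurable bias and (optionally heteroscedastic) noise, so the true
# agreement parameters between that equation and the reference are known
# exactly — the basis of every parameter-recovery test downstream.

default_site_base <- function() {
  # per-site median thickness (mm) of a lean late-adolescent male
  # athlete cohort; calibrated so the five equations land at
  # low-teens FM% on a 79 kg frame
  c(biceps = 4, triceps = 7, subscapular = 7.5, suprailiac = 8,
    supraspinale = 5.5, abdominal = 10, thigh = 8.5, calf = 5.5,
    chest = 5.5, midaxillary = 5.5)
}

#' Synthetic cohort parameters
#'
#' Configuration for [generate_cohort()]. Defaults emulate a squad of 25
#' late-adolescent male academy soccer players (age 18.6 +/- 0.8 y,
#' height 182.7 +/- 5.9 cm, body mass 79.3 +/- 7.6 kg) with skinfolds
#' correlated through a shared adiposity factor and a DXA-like reference
#' sitting about 1.6 kg below the Durnin-Womersley fat-mass estimate.
#'
#' @param n number of subjects, at least 3.
#' @param seed integer seed; the generator is deterministic given it.
#' @param age_mean,age_sd age distribution, years.
#' @param height_mean,height_sd standing height, cm.
#' @param sitting_height_ratio_mean,sitting_height_ratio_sd sitting
#'   height as a fraction of standing height.
#' @param mass_mean,mass_sd body mass, kg.
#' @param adiposity_factor_sd SD of the shared lognormal adiposity
#'   factor multiplying every skinfold site of a subject; controls
#'   between-subject skinfold spread and inter-site correlation.
#' @param site_base named vector of per-site median thicknesses, mm.
#' @param site_noise_cv per-site lognormal noise CV, percent; controls
#'   within-subject site-to-site scatter.
#' @param dxa_fm_bias systematic offset of the reference fat mass from
#'   the generating equation's estimate, kg (reference = equation +
#'   bias + noise; negative means the equation overestimates the
#'   reference).
#' @param dxa_fm_noise_sd baseline SD of the reference fat-mass noise,
#'   kg.
#' @param dxa_heteroscedasticity additional noise SD per kg of equation
#'   fat mass (dimensionless slope); positive values reproduce the
#'   fanning-out seen in Bland-Altman plots at higher fat mass.
#' @param replicate_cv intra-rater re-measurement error CV, percent;
#'   both caliper pulls of each site are perturbed multiplicatively
#'   with this CV.
#' @param reference_equation equation id generating the latent truth.
#' @param bmc_mean,bmc_sd simulated bone mineral content, kg (the
#'   reference lean mass is body mass minus reference fat mass minus
#'   BMC).
#' @param replicates include a second replicate of the ten skinfold
#'   columns (`*_rep2`) for reliability analysis.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n = 25L, seed = 1L,
                          age_mean = 18.6, age_sd = 0.8,
                          height_mean = 182.7, height_sd = 5.9,
                          sitting_height_ratio_mean = 0.52,
                          sitting_height_ratio_sd = 0.01,
                          mass_mean = 79.3, mass_sd = 7.6,
                          adiposity_factor_sd = 0.25,
                          site_base = default_site_base(),
                          site_noise_cv = 10,
                          dxa_fm_bias = -1.6,
                          dxa_fm_noise_sd = 1.0,
                          dxa_heteroscedasticity = 0.02,
                          replicate_cv = 3.5,
                          reference_equation = "durnin_womersley",
                          bmc_mean = 3.0, bmc_sd = 0.25,
                          replicates = TRUE) {
  p <- list(n = as.integer(n), seed = as.integer(seed),
            age_mean = age_mean, age_sd = age_sd,
            height_mean = height_mean, height_sd = height_sd,
            sitting_height_ratio_mean = sitting_height_ratio_mean,
            sitting_height_ratio_sd = sitting_height_ratio_sd,
            mass_mean = mass_mean, mass_sd = mass_sd,
            adiposity_factor_sd = adiposity_factor_sd,
            site_base = site_base, site_noise_cv = site_noise_cv,
            dxa_fm_bias = dxa_fm_bias,
            dxa_fm_noise_sd = dxa_fm_noise_sd,
            dxa_heteroscedasticity = dxa_heteroscedasticity,
            replicate_cv = replicate_cv,
            reference_equation = match.arg(reference_equation,
                                           equation_ids()),
            bmc_mean = bmc_mean, bmc_sd = bmc_sd,
            replicates = isTRUE(replicates))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n < 3L) stop_input("n must be at least 3")
  sds <- c("age_sd", "height_sd", "sitting_height_ratio_sd", "mass_sd",
           "adiposity_factor_sd", "site_noise_cv", "dxa_fm_noise_sd",
           "replicate_cv", "bmc_sd")
  for (nm in sds) check_number(p[[nm]], nm, lower = 0)
  check_number(p$dxa_heteroscedasticity, "dxa_heteroscedasticity",
               lower = 0)
  sites <- skinfold_sites()
  if (!all(sites %in% names(p$site_base))) {
    stop_input("site_base must name all ten sites; missing: %s",
               paste(setdiff(sites, names(p$site_base)), collapse = ", "))
  }
  check_number(unname(p$site_base[sites]), "site_base", lower = 0,
               strict_lower = TRUE)
  invisible(p)
}

# rejection sampling from a truncated normal; bounds are loose
# physiologic guards that essentially never bind with the defaults
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop_input("impossible truncation bounds")
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_input("impossible truncation bounds for degenerate draw")
    }
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop_input("truncation bounds too tight for the given mean/sd")
}

# lognormal sdlog giving a multiplicative factor with the requested CV%
cv_to_sdlog <- function(cv_percent) sqrt(log1p((cv_percent / 100)^2))

#' Generate a synthetic athlete cohort
#'
#' Draws anthropometry from (truncated) normal distributions, builds
#' each subject's ten skinfolds as `site_base * adiposity_factor *
#' site_noise` (all multiplicative lognormal, so skinfolds are positive
#' and right-skewed and sites are correlated within subject), perturbs
#' each site with intra-rater measurement error to give the recorded
#' value and an optional second replicate, and generates the reference
#' body composition from the designated equation plus bias and
#' heteroscedastic noise. Deterministic given `params$seed`; the global
#' RNG state is left untouched.
#'
#' @param params a [cohort_params()] object.
#' @return data.frame in the cohort CSV schema (see [cohort_schema()]),
#'   one row per subject.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 10, seed = 7))
#' head(cohort[, 1:6])
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, as.list(params))
  }
  validate_cohort_params(params)
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n
  sites <- skinfold_sites()

  age <- rnorm_trunc(n, p$age_mean, p$age_sd, 14, 30)
  height <- rnorm_trunc(n, p$height_mean, p$height_sd, 150, 210)
  ratio <- rnorm_trunc(n, p$sitting_height_ratio_mean,
                       p$sitting_height_ratio_sd, 0.45, 0.60)
  mass <- rnorm_trunc(n, p$mass_mean, p$mass_sd, 45, 130)
  sitting <- height * ratio

  # lognormal factors with tails truncated at 3 SD: keeps every
  # skinfold physiologic (and every equation in its valid range) even
  # in very large cohorts, at a negligible distortion of the body
  rlnorm_trunc <- function(n, sdlog) {
    if (sdlog == 0) return(rep(1, n))
    exp(rnorm_trunc(n, 0, sdlog, -3 * sdlog, 3 * sdlog))
  }
  adiposity <- rlnorm_trunc(n, p$adiposity_factor_sd)
  sd_site <- cv_to_sdlog(p$site_noise_cv)
  sd_rep <- cv_to_sdlog(p$replicate_cv)

  true_sites <- sapply(sites, function(s) {
    p$site_base[[s]] * adiposity * rlnorm_trunc(n, sd_site)
  })
  # two caliper pulls of every site; the first is the recorded value
  rep1 <- true_sites * exp(matrix(rnorm(n * 10L, 0, sd_rep), n, 10L))
  rep2 <- true_sites * exp(matrix(rnorm(n * 10L, 0, sd_rep), n, 10L))
  colnames(rep1) <- colnames(rep2) <- sites

  cohort <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age_yr = age, height_cm = height, sitting_height_cm = sitting,
    body_mass_kg = mass,
    stringsAsFactors = FALSE
  )
  for (s in sites) cohort[[paste0("sf_", s, "_mm")]] <- rep1[, s]

  est <- estimate_all(cohort, equations = p$reference_equation)
  eq_fm_kg <- est$fm_kg

  noise_sd <- p$dxa_fm_noise_sd + p$dxa_heteroscedasticity * eq_fm_kg
  fm_ref <- eq_fm_kg + p$dxa_fm_bias + rnorm(n, 0, 1) * noise_sd
  bmc <- rnorm_trunc(n, p$bmc_mean, p$bmc_sd, 0.5, 6)
  lm_ref <- mass - fm_ref - bmc
  # redraw the reference noise for the rare subject pushed non-physical
  # by an extreme draw; never binds at default settings
  for (i in 1:100) {
    bad <- fm_ref <= 0 | lm_ref <= 0
    if (!any(bad)) break
    fm_ref[bad] <- eq_fm_kg[bad] + p$dxa_fm_bias +
      rnorm(sum(bad), 0, 1) * noise_sd[bad]
    lm_ref <- mass - fm_ref - bmc
  }
  if (any(fm_ref <= 0) || any(lm_ref <= 0)) {
    stop_input(paste("parameters produced non-physical reference body",
                     "composition (fat or lean mass <= 0)"))
  }
  cohort$dxa_fm_kg <- fm_ref
  cohort$dxa_lm_kg <- lm_ref

  if (p$replicates) {
    for (s in sites) cohort[[paste0("sf_", s, "_mm_rep2")]] <- rep2[, s]
  }
  cohort
}

#' Calibrate the replicate-error CV for a target pooled %TEM
#'
#' To first order in the error CV, the pooled technical error of
#' measurement over all sites and subjects is
#' `TEM% = replicate_cv * sqrt(E[v^2]) / E[v]`, where `v` runs over the
#' recorded site thicknesses: the heterogeneity of site magnitudes
#' inflates %TEM above the per-measurement CV. This computes the
#' inflation factor on a noise-free realisation of `params` and returns
#' the `replicate_cv` whose expected pooled %TEM equals
#' `target_tem_percent`.
#'
#' @param target_tem_percent desired pooled %TEM.
#' @param params a [cohort_params()] object supplying the site
#'   dispersion structure.
#' @return the calibrated `replicate_cv` in percent.
#' @export
calibrate_replicate_cv <- function(target_tem_percent,
                                   params = cohort_params()) {
  check_number(target_tem_percent, "target_tem_percent", lower = 0,
               strict_lower = TRUE)
  p <- do.call(cohort_params, utils::modifyList(
    unclass_params(params), list(replicate_cv = 0)))
  cohort <- generate_cohort(p)
  v <- as.matrix(cohort[, paste0("sf_", skinfold_sites(), "_mm")])
  inflation <- sqrt(mean(v^2)) / mean(v)
  target_tem_percent / inflation
}

unclass_params <- function(params) {
  p <- unclass(params)
  p[setdiff(names(p), "")]
}

#' Cohort CSV schema
#'
#' Column names of the cohort interchange format: subject id,
#' anthropometry, the ten recorded skinfold sites, the reference body
#' composition, and (optionally) the ten second-replicate skinfold
#' columns.
#'
#' @param replicates include the `*_rep2` columns.
#' @return character vector of column names in canonical order.
#' @export
cohort_schema <- function(replicates = FALSE) {
  base <- c("id", "age_yr", "height_cm", "sitting_height_cm",
            "body_mass_kg",
            paste0("sf_", skinfold_sites(), "_mm"),
            "dxa_fm_kg", "dxa_lm_kg")
  if (replicates) {
    base <- c(base, paste0("sf_", skinfold_sites(), "_mm_rep2"))
  }
  base
}

#' Validate a cohort table against the schema
#'
#' Checks column presence and value sanity (positive masses and
#' heights, skinfolds in (0, 100] mm, sitting below standing height).
#' Unknown extra columns are preserved with a warning. Violations raise
#' a schema error naming every offending column.
#'
#' @param cohort a data.frame.
#' @return the cohort, invisibly, on success.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop_schema("cohort must be a data.frame")
  required <- cohort_schema(replicates = FALSE)
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0L) {
    stop_schema("cohort is missing required columns: %s",
                paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(cohort),
                   cohort_schema(replicates = TRUE))
  if (length(extra) > 0L) {
    warning(sprintf("ignoring unknown cohort columns: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(required, "id")
  bad <- num_cols[vapply(num_cols, function(cl) {
    v <- cohort[[cl]]
    !is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)
  }, logical(1))]
  if (length(bad) > 0L) {
    stop_schema("non-positive or missing values in columns: %s",
                paste(bad, collapse = ", "))
  }
  if (any(cohort$sitting_height_cm >= cohort$height_cm)) {
    stop_schema("sitting_height_cm must be below height_cm")
  }
  sf_cols <- grep("^sf_.*_mm(_rep2)?$", names(cohort), value = TRUE)
  over <- sf_cols[vapply(sf_cols, function(cl)
    any(cohort[[cl]] > 100), logical(1))]
  if (length(over) > 0L) {
    stop_schema("skinfold thicknesses above 100 mm in columns: %s",
                paste(over, collapse = ", "))
  }
  invisible(cohort)
}

#' Read and write cohort CSV files
#'
#' Plain UTF-8 CSV with dot decimal separator and the schema of
#' [cohort_schema()]. Doubles are written with a shortest round-trip
#' representation, so `read_cohort_csv(write_cohort_csv(c))` returns
#' the cohort to full float precision. Reading validates the schema.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort_csv()`: the validated cohort data.frame.
#'   `write_cohort_csv()`: `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  # base strtod parsing is correctly rounded, so values written with a
  # shortest round-trip representation come back bit-identical
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}
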