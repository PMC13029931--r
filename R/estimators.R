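#' Skinfold site vocabulary and per-equation requirements
#'
#' Ten caliper sites are recognised: biceps, triceps, subscapular,
#' suprailiac, supraspinale, abdominal, thigh (anterior thigh), calf
#' (medial calf), chest and midaxillary, all in mm. `equation_sites()`
#' returns the sites each prediction equation needs.
#'
#' @return `skinfold_sites()`: character vector of the ten site names.
#'   `equation_sites()`: named list mapping equation id to required sites.
#' @export
skinfold_sites <- function() {
  c("biceps", "triceps", "subscapular", "suprailiac", "supraspinale",
    "abdominal", "thigh", "calf", "chest", "midaxillary")
}

#' @rdname skinfold_sites
#' @export
equation_ids <- function() {
  c("durnin_womersley", "slaughter", "withers", "wilmore_behnke", "oliver")
}

#' @rdname skinfold_sites
#' @export
equation_sites <- function() {
  list(
    durnin_womersley = c("biceps", "triceps", "subscapular", "suprailiac"),
    slaughter        = c("triceps", "subscapular"),
    withers          = c("triceps", "biceps", "subscapular", "supraspinale",
                         "abdominal", "thigh", "calf"),
    wilmore_behnke   = c("abdominal", "thigh"),
    oliver           = c("chest", "triceps", "subscapular", "midaxillary",
                         "suprailiac", "abdominal", "thigh")
  )
}

# Calipers cannot read <= 0 mm, and folds beyond 100 mm push the
# density equations non-physical, so both are rejected outright.
check_sites <- function(sites, equation) {
  for (nm in names(sites)) {
    v <- sites[[nm]]
    if (is.null(v) || length(v) == 0L || anyNA(v)) {
      stop_input("%s: required skinfold site '%s' is missing", equation, nm)
    }
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0) || any(v > 100)) {
      stop_input("%s: skinfold site '%s' must be a thickness in (0, 100] mm",
                 equation, nm)
    }
  }
  invisible(lengths(sites))
}

#' Convert whole-body density to percent fat
#'
#' Siri-type two-compartment transform, `FM% = 495 / D - 450`, with the
#' constants in the 495/450 form.
#'
#' @param density whole-body density in g/cm^3; must be positive.
#' @return fat mass as a percentage of body mass.
#' @export
siri_fm_percent <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    stop_domain("body density must be positive and finite")
  }
  495 / density - 450
}

#' Skinfold fat-mass prediction equations
#'
#' Five published equations predicting fat-mass percentage from skinfold
#' thicknesses in late-adolescent male athletes. The density-based
#' equations (Durnin & Womersley, Withers, Wilmore & Behnke) first predict
#' whole-body density from skinfolds and then convert it through
#' [siri_fm_percent()]; Slaughter and Oliver predict FM% directly.
#' All arguments are skinfold thicknesses in mm and may be vectors
#' (one element per subject).
#'
#' * `fm_durnin_womersley()`: `D = 1.1631 - 0.0632 log10(biceps + triceps +
#'   subscapular + suprailiac)`.
#' * `fm_slaughter()`: two-branch in `s = triceps + subscapular`;
#'   `s <= 35` mm uses the quadratic `1.21 s - 0.008 s^2 - 5.5`,
#'   `s > 35` mm the linear `0.783 s + 1.6`. The branch that fired is
#'   recorded; the jump at the 35 mm boundary (27.05 vs 29.0) is a
#'   property of the published equation, not smoothed over here.
#' * `fm_withers()`: `D = 1.0988 - 0.0004 S7` with `S7 = triceps + biceps +
#'   subscapular + supraspinale + abdominal + thigh + calf`.
#' * `fm_wilmore_behnke()`: `D = 1.08543 - 0.000886 abdominal -
#'   0.0004 thigh`.
#' * `fm_oliver()`: `FM% = 0.132 S7 + 3.530` with `S7 = chest + triceps +
#'   subscapular + midaxillary + suprailiac + abdominal + thigh`.
#'
#' @param biceps,triceps,subscapular,suprailiac,supraspinale,abdominal
#'   skinfold thickness in mm.
#' @param thigh,calf,chest,midaxillary skinfold thickness in mm (anterior
#'   thigh, medial calf).
#' @return a data.frame with one row per subject and columns `fm_percent`,
#'   plus `body_density` for the density-based equations and `branch`
#'   (`"quadratic"` or `"linear"`) for Slaughter.
#' @examples
#' fm_durnin_womersley(biceps = 5, triceps = 9, subscapular = 9,
#'                     suprailiac = 7)
#' fm_slaughter(triceps = 8, subscapular = 7)
#' @export
fm_durnin_womersley <- function(biceps, triceps, subscapular, suprailiac) {
  check_sites(list(biceps = biceps, triceps = triceps,
                   subscapular = subscapular, suprailiac = suprailiac),
              "durnin_womersley")
  sum4 <- biceps + triceps + subscapular + suprailiac
  density <- 1.1631 - 0.0632 * log10(sum4)
  data.frame(body_density = density, fm_percent = siri_fm_percent(density))
}

#' @rdname fm_durnin_womersley
#' @export
fm_slaughter <- function(triceps, subscapular) {
  check_sites(list(triceps = triceps, subscapular = subscapular), "slaughter")
  s <- triceps + subscapular
  quadratic <- s <= 35
  fm <- ifelse(quadratic,
               1.21 * s - 0.008 * s^2 - 5.5,
               0.783 * s + 1.6)
  data.frame(fm_percent = fm,
             branch = ifelse(quadratic, "quadratic", "linear"))
}

#' @rdname fm_durnin_womersley
#' @export
fm_withers <- function(triceps, biceps, subscapular, supraspinale,
                       abdominal, thigh, calf) {
  check_sites(list(triceps = triceps, biceps = biceps,
                   subscapular = subscapular, supraspinale = supraspinale,
                   abdominal = abdominal, thigh = thigh, calf = calf),
              "withers")
  s7 <- triceps + biceps + subscapular + supraspinale + abdominal +
    thigh + calf
  density <- 1.0988 - 0.0004 * s7
  data.frame(body_density = density, fm_percent = siri_fm_percent(density))
}

#' @rdname fm_durnin_womersley
#' @export
fm_wilmore_behnke <- function(abdominal, thigh) {
  check_sites(list(abdominal = abdominal, thigh = thigh), "wilmore_behnke")
  density <- 1.08543 - 0.000886 * abdominal - 0.0004 * thigh
  data.frame(body_density = density, fm_percent = siri_fm_percent(density))
}

#' @rdname fm_durnin_womersley
#' @export
fm_oliver <- function(chest, triceps, subscapular, midaxillary, suprailiac,
                      abdominal, thigh) {
  check_sites(list(chest = chest, triceps = triceps,
                   subscapular = subscapular, midaxillary = midaxillary,
                   suprailiac = suprailiac, abdominal = abdominal,
                   thigh = thigh),
              "oliver")
  s7 <- chest + triceps + subscapular + midaxillary + suprailiac +
    abdominal + thigh
  data.frame(fm_percent = 0.132 * s7 + 3.530)
}

#' Derive lean mass from body mass and fat-mass percentage
#'
#' `LM = BM * (1 - FM%/100)`, so that with `FM kg = BM * FM%/100` the two
#' compartments reconstruct body mass exactly.
#'
#' @param body_mass body mass in kg, positive.
#' @param fm_percent fat mass as percent of body mass, in `[0, 100)`.
#' @return lean mass in kg.
#' @examples
#' lean_mass_kg(80, 10)   # 72 kg
#' @export
lean_mass_kg <- function(body_mass, fm_percent) {
  check_number(body_mass, "body_mass", lower = 0, strict_lower = TRUE)
  if (!is.numeric(fm_percent) || anyNA(fm_percent) ||
      any(!is.finite(fm_percent)) || any(fm_percent < 0) ||
      any(fm_percent >= 100)) {
    stop_domain("fm_percent must lie in [0, 100)")
  }
  body_mass * (1 - fm_percent / 100)
}

#' Apply every prediction equation to a cohort
#'
#' Runs all requested fat-mass equations over a cohort table (schema of
#' [cohort_schema()]), converts FM% to kg and derives lean mass. An
#' equation whose required sites are absent or missing is an error unless
#' `skip_missing = TRUE`, in which case it is reported in the `"skipped"`
#' attribute of the result, never silently dropped.
#'
#' @param cohort a data.frame with `id`, `body_mass_kg` and `sf_<site>_mm`
#'   columns.
#' @param equations character vector of equation ids (default all five).
#' @param skip_missing skip (and report) equations with missing sites
#'   instead of erroring.
#' @return long data.frame with columns `id`, `equation`, `body_density`
#'   (NA where not applicable), `fm_percent`, `fm_kg`, `lm_kg`,
#'   `slaughter_branch` (NA except for Slaughter); attribute `skipped` is
#'   a data.frame naming skipped equations and their missing sites.
#' @export
estimate_all <- function(cohort, equations = equation_ids(),
                         skip_missing = FALSE) {
  if (!is.data.frame(cohort)) stop_input("cohort must be a data.frame")
  equations <- match.arg(equations, equation_ids(), several.ok = TRUE)
  if (!all(c("id", "body_mass_kg") %in% names(cohort))) {
    stop_schema("cohort lacks required columns: %s",
                paste(setdiff(c("id", "body_mass_kg"), names(cohort)),
                      collapse = ", "))
  }
  bm <- cohort$body_mass_kg
  check_number(bm, "body_mass_kg", lower = 0, strict_lower = TRUE)

  site_col <- function(site) paste0("sf_", site, "_mm")
  have_site <- function(site) {
    col <- site_col(site)
    col %in% names(cohort) && !anyNA(cohort[[col]])
  }

  rows <- list()
  skipped <- list()
  for (eq in equations) {
    need <- equation_sites()[[eq]]
    missing <- need[!vapply(need, have_site, logical(1))]
    if (length(missing) > 0L) {
      if (!skip_missing) {
        stop_input("%s: required skinfold site '%s' is missing",
                   eq, missing[[1L]])
      }
      skipped[[eq]] <- data.frame(equation = eq,
                                  missing_sites = paste(missing,
                                                        collapse = ";"))
      next
    }
    args <- lapply(need, function(s) cohort[[site_col(s)]])
    names(args) <- need
    frag <- switch(eq,
      durnin_womersley = do.call(fm_durnin_womersley, args),
      slaughter        = do.call(fm_slaughter, args),
      withers          = do.call(fm_withers, args),
      wilmore_behnke   = do.call(fm_wilmore_behnke, args),
      oliver           = do.call(fm_oliver, args)
    )
    fm_pct <- frag$fm_percent
    rows[[eq]] <- data.frame(
      id = cohort$id,
      equation = eq,
      body_density = if ("body_density" %in% names(frag))
        frag$body_density else NA_real_,
      fm_percent = fm_pct,
      fm_kg = bm * fm_pct / 100,
      lm_kg = lean_mass_kg(bm, fm_pct),
      slaughter_branch = if ("branch" %in% names(frag))
        frag$branch else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(id = character(), equation = character(),
                      body_density = numeric(), fm_percent = numeric(),
                      fm_kg = numeric(), lm_kg = numeric(),
                      slaughter_branch = character())
  }
  attr(out, "skipped") <- if (length(skipped) > 0L) {
    do.call(rbind, c(unname(skipped), list(make.row.names = FALSE)))
  } else {
    data.frame(equation = character(), missing_sites = character())
  }
  out
}
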