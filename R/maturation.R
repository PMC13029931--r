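#' Mirwald maturity offset
#'
#' Somatic maturity estimated as years from peak height velocity (PHV)
#' using the Mirwald sex-specific (male) anthropometric regression:
#'
#' `offset = -9.236 + 0.0002708 (leg * sit) - 0.001663 (age * leg) +
#'  0.007216 (age * sit) + 0.02292 (100 * mass / height)`
#'
#' where `leg = standing_height - sitting_height`. Heights enter in cm,
#' age in decimal years, body mass in kg. The weight/height ratio term is
#' `kg per cm` scaled by 100; feeding height in metres silently shifts the
#' offset by roughly +2 years, so units are validated strictly.
#'
#' @param age chronological age in decimal years, positive.
#' @param standing_height standing height in cm.
#' @param sitting_height sitting height in cm; must be below standing
#'   height.
#' @param body_mass body mass in kg, positive.
#' @return maturity offset in years (negative before PHV, positive after).
#' @examples
#' maturity_offset(14, 170, 88, 55)    # about +0.44 y post-PHV
#' @export
maturity_offset <- function(age, standing_height, sitting_height,
                            body_mass) {
  check_number(age, "age", lower = 0, strict_lower = TRUE)
  check_number(standing_height, "standing_height", lower = 0,
               strict_lower = TRUE)
  check_number(sitting_height, "sitting_height", lower = 0,
               strict_lower = TRUE)
  check_number(body_mass, "body_mass", lower = 0, strict_lower = TRUE)
  if (any(sitting_height >= standing_height)) {
    stop_input("sitting_height must be smaller than standing_height")
  }
  leg <- standing_height - sitting_height
  whr <- body_mass / standing_height
  -9.236 +
    0.0002708 * leg * sitting_height -
    0.001663 * age * leg +
    0.007216 * age * sitting_height +
    0.02292 * whr * 100
}

#' Post-PHV maturity groups
#'
#' Bins a maturity offset into the four post-PHV groups used for
#' late-adolescent cohorts: 1-2, 2-3, 3-4 and 4+ years after PHV. Bins
#' are half-open `[lower, upper)`, so an offset of exactly 2 falls in the
#' 2-3 group. Offsets below 1 year post-PHV are outside the grouping and
#' flagged `OUT_OF_RANGE` rather than clamped into the nearest bin.
#'
#' @param offset maturity offset in years, finite; may be a vector.
#' @return factor with levels `OUT_OF_RANGE`, `PHV1_2`, `PHV2_3`,
#'   `PHV3_4`, `PHV4_PLUS`.
#' @examples
#' classify_maturity_group(c(0.4, 1.5, 2, 3.9, 6))
#' @export
classify_maturity_group <- function(offset) {
  check_number(offset, "offset")
  lev <- c("OUT_OF_RANGE", "PHV1_2", "PHV2_3", "PHV3_4", "PHV4_PLUS")
  idx <- findInterval(offset, c(1, 2, 3, 4)) + 1L
  factor(lev[idx], levels = lev)
}
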