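#' Alcohol dose specification
#'
#' Anthropometrics and dosing constants for the intoxication protocol:
#' the dose is expressed in grams of ethanol per estimated liter of total
#' body water (TBW), administered as brandy (36 vol%, 14 g per 50 mL
#' serving) or red wine (9.5 vol%, 15 g per 200 mL serving).
#'
#' @param age_years,height_cm,weight_kg Positive anthropometrics.
#' @param sex Only `"male"` is supported (the protocol's scope).
#' @param dose_g_per_L_tbw Grams of ethanol per liter TBW (default 2.6375).
#' @param beverage `"brandy"` or `"red_wine"`.
#' @return An object of class `dose_spec`.
#' @export
dose_spec <- function(age_years, height_cm, weight_kg, sex = "male",
                      dose_g_per_L_tbw = 2.6375,
                      beverage = c("brandy", "red_wine")) {
  beverage <- match.arg(beverage)
  if (!identical(sex, "male"))
    stop("only the male TBW equation is supported")
  if (age_years <= 0 || height_cm <= 0 || weight_kg <= 0)
    stop("anthropometrics must be positive")
  if (dose_g_per_L_tbw <= 0) stop("dose must be positive")
  structure(list(sex = sex, age_years = age_years, height_cm = height_cm,
                 weight_kg = weight_kg,
                 dose_g_per_L_tbw = dose_g_per_L_tbw, beverage = beverage),
            class = "dose_spec")
}

beverage_table <- data.frame(
  beverage = c("brandy", "red_wine"),
  vol_percent = c(36, 9.5),
  grams_per_serving = c(14, 15),
  ml_per_serving = c(50, 200),
  stringsAsFactors = FALSE
)

#' Total body water by the Watson equation (males)
#'
#' `TBW = 2.447 - 0.09516 * age + 0.1074 * height_cm + 0.3362 * weight_kg`
#' liters.
#'
#' @param spec A [dose_spec()].
#' @return TBW in liters.
#' @export
#' @examples
#' watson_tbw(dose_spec(21.5, 183.4, 80.5))  # ~47.2 L
watson_tbw <- function(spec) {
  stopifnot(inherits(spec, "dose_spec"))
  2.447 - 0.09516 * spec$age_years + 0.1074 * spec$height_cm +
    0.3362 * spec$weight_kg
}

#' Predicted peak blood alcohol concentration
#'
#' Widmark-style prediction: a dose of `dose_g_per_L_tbw` grams of ethanol
#' per liter of body water, of which a fraction `resorption_deficit` never
#' reaches circulation, yields a peak BAC (per mille, g/kg blood) of
#' `dose * (1 - deficit) * blood_water_fraction / blood_density`. With the
#' standard constants (blood is ~80% water, density 1.055 g/mL) the
#' protocol dose of 2.6375 g/L maps to 2.0 permille at a hypothetical zero
#' deficit, 1.6 at 20% (empty stomach) and 1.2 at 40% (full stomach).
#'
#' @param dose_g_per_L_tbw Ethanol dose per liter TBW.
#' @param resorption_deficit Fraction in `[0, 1]` of the dose lost to
#'   first-pass resorption.
#' @param blood_water_fraction,blood_density Conversion constants
#'   (defaults 0.80 and 1.055).
#' @return Predicted peak BAC in per mille.
#' @export
#' @examples
#' predict_peak_bac(2.6375, 0.40)  # 1.2
predict_peak_bac <- function(dose_g_per_L_tbw, resorption_deficit,
                             blood_water_fraction = 0.80,
                             blood_density = 1.055) {
  stopifnot(resorption_deficit >= 0, resorption_deficit <= 1,
            dose_g_per_L_tbw >= 0)
  dose_g_per_L_tbw * (1 - resorption_deficit) *
    blood_water_fraction / blood_density
}

#' Beverage volume delivering a gram dose of ethanol
#'
#' @param dose_g Grams of ethanol (> 0).
#' @param beverage `"brandy"` (14 g per 50 mL) or `"red_wine"` (15 g per
#'   200 mL).
#' @return Volume in milliliters.
#' @export
#' @examples
#' beverage_volume(14, "brandy")  # 50 mL
beverage_volume <- function(dose_g, beverage = c("brandy", "red_wine")) {
  beverage <- match.arg(beverage)
  stopifnot(dose_g > 0)
  row <- beverage_table[beverage_table$beverage == beverage, ]
  dose_g / row$grams_per_serving * row$ml_per_serving
}

#' Grams of ethanol in a beverage volume
#'
#' @param volume_ml Volume in milliliters (> 0).
#' @inheritParams beverage_volume
#' @return Grams of ethanol.
#' @export
beverage_grams <- function(volume_ml, beverage = c("brandy", "red_wine")) {
  beverage <- match.arg(beverage)
  stopifnot(volume_ml > 0)
  row <- beverage_table[beverage_table$beverage == beverage, ]
  volume_ml / row$ml_per_serving * row$grams_per_serving
}

#' Full dosing computation for one participant
#'
#' @param spec A [dose_spec()].
#' @param deficits Resorption-deficit grid for the BAC prediction curve.
#' @return A list: `tbw_l`, `dose_g`, `volume_ml`, `beverage`, and a data
#'   frame `bac_curve` (`resorption_deficit`, `peak_bac_permille`).
#' @export
compute_dose <- function(spec, deficits = c(0, 0.2, 0.4)) {
  stopifnot(inherits(spec, "dose_spec"))
  tbw <- watson_tbw(spec)
  dose_g <- spec$dose_g_per_L_tbw * tbw
  list(
    tbw_l = tbw,
    dose_g = dose_g,
    volume_ml = beverage_volume(dose_g, spec$beverage),
    beverage = spec$beverage,
    bac_curve = data.frame(
      resorption_deficit = deficits,
      peak_bac_permille = vapply(deficits, function(d)
        predict_peak_bac(spec$dose_g_per_L_tbw, d), numeric(1)))
  )
}
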