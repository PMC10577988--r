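#' Glucose-ketone index (GKI) and ketosis call
#'
#' The glucose-ketone index is the ratio of blood glucose to blood ketone,
#' both in mM: `GKI = glucose (mM) / ketone (mM)`.  A GKI below 9 is the
#' human ketosis criterion and the default classification threshold.  Meter
#' glucose readings in mg/dL are converted to mM by dividing by `divisor`
#' (default 18.016 = glucose molar mass / 10; 18.0 is the other convention in
#' the GKI literature and is configurable since published reports rarely say
#' which they used).  Vectorised over readings.
#'
#' @param glucose Glucose reading(s), in `glucose_unit`.
#' @param ketone Ketone reading(s) in mM (> 0).
#' @param glucose_unit `"mg/dL"` (meter default) or `"mM"`.
#' @param divisor mg/dL to mM conversion factor.
#' @param threshold Ketosis threshold on the GKI (default 9).
#' @return Data.frame of class `metabolic_panel`: `glucose_mM`, `ketone_mM`,
#'   `gki`, `is_ketosis`; attributes `divisor`, `threshold`, `glucose_unit`.
#' @examples
#' gki(90, 0.5)                      # GKI ~ 9.99, not ketosis
#' gki(2, 1, glucose_unit = "mM")    # GKI 2, ketosis
#' @export
gki <- function(glucose, ketone, glucose_unit = c("mg/dL", "mM"),
                divisor = 18.016, threshold = 9) {
  glucose_unit <- match.arg(glucose_unit)
  stopifnot(is.numeric(glucose), is.numeric(ketone),
            length(glucose) == length(ketone), divisor > 0, threshold > 0)
  if (any(glucose < 0)) stop("negative glucose reading", call. = FALSE)
  if (any(ketone <= 0)) {
    stop("GKI undefined: ketone must be > 0 mM", call. = FALSE)
  }
  glucose_mM <- if (glucose_unit == "mg/dL") glucose / divisor else glucose
  g <- glucose_mM / ketone
  structure(data.frame(glucose_mM = glucose_mM, ketone_mM = ketone,
                       gki = g, is_ketosis = g < threshold),
            class = c("metabolic_panel", "data.frame"),
            divisor = divisor, threshold = threshold,
            glucose_unit = glucose_unit)
}

#' Diet component description
#'
#' One feed component with its nutrient percentages by weight and gross
#' caloric density, as printed in feed nutrition tables.
#'
#' @param name Component label.
#' @param protein_pct,lipid_pct,carb_pct Percent by weight (>= 0).
#' @param kcal_per_g Gross caloric density (> 0).
#' @return One-row data.frame of class `diet_component`.
#' @seealso [study_diets()] for the components used in the feeding study.
#' @export
diet_component <- function(name, protein_pct, lipid_pct, carb_pct, kcal_per_g) {
  stopifnot(protein_pct >= 0, lipid_pct >= 0, carb_pct >= 0, kcal_per_g > 0)
  structure(data.frame(name = name, protein_pct = protein_pct,
                       lipid_pct = lipid_pct, carb_pct = carb_pct,
                       kcal_per_g = kcal_per_g),
            class = c("diet_component", "data.frame"))
}

#' Feed components of the ketogenic-diet study
#'
#' The three base feeds: live brine shrimp larvae (standard rearing diet),
#' the Zeigler zebrafish standard irradiated diet, and the KetoCal 3:1 human
#' ketogenic formula.  Percentages are the printed nutrient table values;
#' caloric densities use the stated gross values (6.99 kcal/g KetoCal,
#' 3.89 kcal/g Zeigler).  The study's ketogenic diet (KD) is KetoCal:Zeigler
#' mixed 5:1 by weight, and its control diet (CD) is the same pair at 1:5 -
#' see [mix_diets()].
#'
#' @return Data.frame of class `diet_component`, one row per feed.
#' @export
study_diets <- function() {
  rbind(
    diet_component("brine_shrimp", 58.4, 14.7, 5.2, 5.9),
    diet_component("zeigler", 54.0, 14.4, 11.6, 3.89),
    diet_component("ketocal_3_1", 15.3, 67.7, 7.2, 6.99))
}

#' Mix diet components by weight ratio
#'
#' Each nutrient percentage and the caloric density of the blend is the
#' weight-ratio-weighted mean of the component values; mixing is exactly
#' linear, so the result is unchanged under permutation of the
#' (component, ratio) pairs and a self-mix is the identity.  Values are kept
#' at full precision; round only at presentation (see `round_half_up()` logic
#' in [format()] via `digits`).
#'
#' @param components A `diet_component` data.frame (one row per component).
#' @param weight_ratio Positive weights, one per component (e.g. `c(5, 1)`
#'   for a 5:1 blend).
#' @param name Label for the blend.
#' @return A one-row [diet_component()].
#' @examples
#' d <- study_diets()
#' pair <- rbind(d[d$name == "ketocal_3_1", ], d[d$name == "zeigler", ])
#' format(mix_diets(pair, c(5, 1), name = "KD"))  # ketogenic diet column
#' format(mix_diets(pair, c(1, 5), name = "CD"))  # control diet column
#' @export
mix_diets <- function(components, weight_ratio, name = "mix") {
  stopifnot(is.data.frame(components),
            all(c("protein_pct", "lipid_pct", "carb_pct", "kcal_per_g") %in%
                  names(components)))
  if (length(weight_ratio) != nrow(components)) {
    stop("weight_ratio length must match the number of components", call. = FALSE)
  }
  if (any(weight_ratio <= 0)) stop("weight ratios must be > 0", call. = FALSE)
  w <- weight_ratio / sum(weight_ratio)
  diet_component(name,
                 protein_pct = sum(w * components$protein_pct),
                 lipid_pct = sum(w * components$lipid_pct),
                 carb_pct = sum(w * components$carb_pct),
                 kcal_per_g = sum(w * components$kcal_per_g))
}

#' Presentation rounding of a diet component
#'
#' Rounds nutrient percentages and caloric density half away from zero at
#' `digits` decimals, the convention of printed nutrition tables (47.55
#' prints as 47.6).
#'
#' @param x A `diet_component` data.frame.
#' @param digits Decimals (default 1).
#' @param ... Unused.
#' @return The data.frame with rounded numeric columns.
#' @export
format.diet_component <- function(x, digits = 1, ...) {
  for (col in c("protein_pct", "lipid_pct", "carb_pct", "kcal_per_g")) {
    x[[col]] <- round_half_up(x[[col]], digits)
  }
  x
}

#' Supplement dose conversion for agar feed
#'
#' Converts a supplement concentration in the prepared agar feed into the
#' per-meal intake of a fish, using the feeding model of the supplementation
#' experiments: a fish consumes `meal_fraction` (default 3%) of its body
#' weight per meal, and 1 mg of agar-suspended feed occupies about 1 uL
#' (the density assumption implied by the 30 mg ~ 30 uL equivalence).
#' Mass and molar amounts interconvert through `molar_mass`, which is always
#' an explicit input.
#'
#' @param body_g Fish body weight in grams (> 0).
#' @param conc Supplement concentration in the feed, in `conc_unit`.
#' @param conc_unit `"mg/mL"` or `"umol/mL"`.
#' @param molar_mass Molar mass in g/mol (required to interconvert mass and
#'   moles; e.g. 176 for the ketone ester).
#' @param meal_fraction Fraction of body weight eaten per meal (default 0.03).
#' @param density_mg_per_uL Feed density (default 1 mg/uL).
#' @return List of class `dose_result`: `meal_mass_mg`, `meal_volume_mL`,
#'   `dose_mg`, `dose_umol`, `dose_mg_per_g`, `dose_umol_per_g`,
#'   `conc_mg_per_mL`, `conc_umol_per_mL`.
#' @examples
#' # ketone ester: 19.1 mg/mL at MW 176 is 108.5 umol/mL; a 1-g fish's 3%
#' # meal (30 mg ~ 30 uL) delivers 3.26 umol per gram of body weight
#' dose_convert(body_g = 1, conc = 19.1, conc_unit = "mg/mL", molar_mass = 176)
#' @export
dose_convert <- function(body_g, conc, conc_unit = c("mg/mL", "umol/mL"),
                         molar_mass = NULL, meal_fraction = 0.03,
                         density_mg_per_uL = 1) {
  conc_unit <- match.arg(conc_unit)
  stopifnot(body_g > 0, conc > 0, meal_fraction > 0, meal_fraction < 1,
            density_mg_per_uL > 0)
  if (is.null(molar_mass)) {
    if (conc_unit == "umol/mL") {
      stop("molar_mass required to convert molar concentration to mass",
           call. = FALSE)
    }
    molar_mass <- NA_real_
  } else {
    stopifnot(molar_mass > 0)
  }
  conc_mg <- if (conc_unit == "mg/mL") conc else conc * molar_mass / 1000
  conc_umol <- if (conc_unit == "umol/mL") conc else
    if (is.na(molar_mass)) NA_real_ else conc / molar_mass * 1000

  meal_mass_mg <- meal_fraction * body_g * 1000
  meal_volume_mL <- meal_mass_mg / density_mg_per_uL / 1000
  dose_mg <- conc_mg * meal_volume_mL
  dose_umol <- conc_umol * meal_volume_mL
  structure(list(
    meal_mass_mg = meal_mass_mg, meal_volume_mL = meal_volume_mL,
    dose_mg = dose_mg, dose_umol = dose_umol,
    dose_mg_per_g = dose_mg / body_g, dose_umol_per_g = dose_umol / body_g,
    conc_mg_per_mL = conc_mg, conc_umol_per_mL = conc_umol,
    molar_mass = molar_mass, meal_fraction = meal_fraction),
    class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf(
    "<dose_result> meal %.3g mg (~%.3g mL): %.4g mg = %.4g umol supplement (%.4g umol per body g)\n",
    x$meal_mass_mg, x$meal_volume_mL, x$dose_mg, x$dose_umol, x$dose_umol_per_g))
  invisible(x)
}
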