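#' Diet specification
#'
#' Describes a synthetic rodent diet by its per-kilogram macronutrient masses
#' and derives the quantities the calorimetry analysis needs: metabolizable
#' energy fractions, energy density and food quotient (FQ).
#'
#' Energy is attributed with the usual factors 16.7 kJ/g for carbohydrate
#' (starch + sucrose) and protein, and 37.7 kJ/g for fat; cellulose, minerals,
#' vitamins and choline are treated as non-metabolizable. The food quotient is
#' the RQ the diet would produce on complete oxidation: the energy-fraction
#' weighted sum with weights 1 (carbohydrate), 0.825 (protein) and 0.7 (fat).
#'
#' @param protein_g,starch_g,sucrose_g,oil_g masses in g per kg of diet.
#' @param minerals_g,vitamins_g,cellulose_g,choline_g non-energetic components,
#'   g per kg.
#' @param name optional label, e.g. `"HCD"`.
#' @return A `diet_spec` list with the input masses plus `energy_frac`
#'   (named numeric: protein, carbohydrate, fat, summing to 1),
#'   `energy_density_kj_g` and `food_quotient`.
#' @examples
#' d <- diet_spec(protein_g = 140, starch_g = 622.4, sucrose_g = 100.3,
#'                oil_g = 40, name = "HCD")
#' d$food_quotient
#' @export
diet_spec <- function(protein_g, starch_g, sucrose_g, oil_g,
                      minerals_g = 35, vitamins_g = 10, cellulose_g = 50,
                      choline_g = 2.3, name = NULL) {
  masses <- c(protein_g = protein_g, starch_g = starch_g,
              sucrose_g = sucrose_g, oil_g = oil_g, minerals_g = minerals_g,
              vitamins_g = vitamins_g, cellulose_g = cellulose_g,
              choline_g = choline_g)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    abort("diet masses must be finite and non-negative")
  }
  kj_per_kg <- c(
    protein      = 16.7 * protein_g,
    carbohydrate = 16.7 * (starch_g + sucrose_g),
    fat          = 37.7 * oil_g
  )
  total_kj <- sum(kj_per_kg)
  if (total_kj <= 0) abort("diet has no metabolizable energy")
  frac <- kj_per_kg / total_kj
  out <- list(
    masses_g_per_kg = masses,
    energy_frac = frac,
    energy_density_kj_g = total_kj / 1000,
    food_quotient = food_quotient(frac[["carbohydrate"]], frac[["protein"]],
                                  frac[["fat"]]),
    name = name
  )
  structure(out, class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("<diet_spec>", if (!is.null(x$name)) x$name else "", "\n")
  cat(sprintf("  energy fractions: carb %.3f, protein %.3f, fat %.3f\n",
              x$energy_frac[["carbohydrate"]], x$energy_frac[["protein"]],
              x$energy_frac[["fat"]]))
  cat(sprintf("  energy density: %.2f kJ/g   food quotient: %.3f\n",
              x$energy_density_kj_g, x$food_quotient))
  invisible(x)
}

#' Food quotient from macronutrient energy fractions
#'
#' The RQ a diet would produce if fully oxidised, computed as the
#' energy-fraction weighted sum with weights 1 for carbohydrate, 0.825 for
#' protein and 0.7 for fat.
#'
#' @param carbohydrate,protein,fat metabolizable energy fractions (each in
#'   \[0, 1\]; they must sum to 1 within 0.005, so rounded printed
#'   percentages are accepted as-is).
#' @return dimensionless food quotient in \[0.7, 1\].
#' @examples
#' food_quotient(0.759, 0.147, 0.094) # high-carbohydrate diet: 0.946
#' food_quotient(0.429, 0.144, 0.428) # high-fat diet: 0.847
#' @export
food_quotient <- function(carbohydrate, protein, fat) {
  fr <- c(carbohydrate, protein, fat)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    abort("energy fractions must be finite and non-negative")
  }
  if (abs(sum(fr) - 1) > 5e-3) {
    abort(paste0("energy fractions must sum to 1, got ", sum(fr)))
  }
  carbohydrate * 1 + protein * 0.825 + fat * 0.7
}

#' Test-meal mass for a given energy
#'
#' @param energy_kj meal energy, kJ.
#' @param energy_density_kj_g diet energy density, kJ/g.
#' @return meal mass in g, rounded to 0.1 g.
#' @examples
#' meal_mass(60, 19.82) # 3.0 g of high-fat diet
#' @export
meal_mass <- function(energy_kj, energy_density_kj_g) {
  check_scalar(energy_kj, "energy_kj", lower = 0)
  check_scalar(energy_density_kj_g, "energy_density_kj_g", lower = 1e-9)
  round(energy_kj / energy_density_kj_g, 1)
}

#' Reference high-carbohydrate and high-fat diets
#'
#' The two synthetic diets used throughout the package: an AIN93-style
#' high-carbohydrate diet (HCD) and a high-fat diet (HFD). `ref_diet()`
#' builds the [diet_spec] from the g/kg composition; the printed energy
#' densities of the commercial formulations (15.95 and 19.82 kJ/g, used for
#' test-meal mass bookkeeping) are kept in the `printed_energy_density_kj_g`
#' element because they differ from the factor-derived densities in the third
#' decimal.
#'
#' @param which `"HCD"` or `"HFD"`.
#' @return a [diet_spec] whose `food_quotient` and
#'   `printed_energy_density_kj_g` come from the datasheet energy fractions
#'   and density; the purely mass-derived values stay available as
#'   `food_quotient_from_masses` and `energy_density_kj_g`.
#' @examples
#' ref_diet("HCD")$food_quotient
#' @export
ref_diet <- function(which = c("HCD", "HFD")) {
  which <- match.arg(which)
  d <- switch(which,
    HCD = diet_spec(protein_g = 140.0, starch_g = 622.4, sucrose_g = 100.3,
                    oil_g = 40.0, name = "HCD"),
    HFD = diet_spec(protein_g = 170.0, starch_g = 436.6, sucrose_g = 71.1,
                    oil_g = 225.0, name = "HFD")
  )
  # datasheet energy percentages and density; they differ from the
  # factor-derived values in the last digit (rounding in the datasheet),
  # and are authoritative for the reference diets' derived metrics
  printed <- switch(which,
    HCD = list(frac = c(protein = 0.147, carbohydrate = 0.759, fat = 0.094),
               density = 15.95),
    HFD = list(frac = c(protein = 0.144, carbohydrate = 0.429, fat = 0.428),
               density = 19.82))
  d$printed_energy_frac <- printed$frac
  d$printed_energy_density_kj_g <- printed$density
  d$food_quotient_from_masses <- d$food_quotient
  d$food_quotient <- food_quotient(printed$frac[["carbohydrate"]],
                                   printed$frac[["protein"]],
                                   printed$frac[["fat"]])
  d
}

#' Summary metrics for a diet
#'
#' @param diet a [diet_spec].
#' @param meal_energy_kj test-meal energy for the meal-mass column (kJ).
#' @return one-row tibble: name, energy density (kJ/g), food quotient and the
#'   mass of a `meal_energy_kj` test meal. Meal mass uses the printed
#'   commercial energy density when the spec carries one, otherwise the
#'   factor-derived density.
#' @export
diet_metrics <- function(diet, meal_energy_kj = 60) {
  stopifnot(inherits(diet, "diet_spec"))
  density_for_meal <- diet$printed_energy_density_kj_g %||%
    diet$energy_density_kj_g
  tibble::tibble(
    name = diet$name %||% NA_character_,
    energy_density_kj_g = diet$energy_density_kj_g,
    food_quotient = diet$food_quotient,
    meal_mass_g = meal_mass(meal_energy_kj, density_for_meal)
  )
}
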