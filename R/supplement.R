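#' Packaged supplement commodity definitions
#'
#' Energy density and estimated commodity price for four candidate
#' supplements: Ready-to-Use Therapeutic Food (RUTF, a lipid-based
#' peanut-paste product), corn-soya blend flour (CSB), and two regional staple
#' foods (yellow maize meal and white rice). Prices are 2012 USD per kilogram
#' from published programme costs and FAO historical global food prices.
#'
#' The CSB price is stored as $0.481/kg: commodity price tables round it to
#' $0.48, but the published quarterly cost of $15.66 implies the extra digit,
#' and the fixture keeps it so the costing reproduces to the cent.
#'
#' @param source optional path to a commodity CSV
#'   (`product,kcal_per_100g,price_per_kg,protein_pct_kcal,fat_pct_kcal`);
#'   defaults to the packaged file.
#' @return a tibble with one row per product.
#' @export
#' @examples
#' supplement_products()
supplement_products <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "supplements.csv", package = "nutricea", mustWork = TRUE)
  }
  prods <- readr::read_csv(
    source,
    col_types = readr::cols(
      product = readr::col_character(),
      .default = readr::col_double()
    )
  )
  if (any(prods$kcal_per_100g <= 0) || any(prods$price_per_kg < 0)) {
    abort("products need positive energy density and non-negative price",
      class = "nutricea_validation_error"
    )
  }
  prods
}

#' Daily energy target for the supplement ration
#'
#' The ration's daily energy target is a fraction of a recommended minimum
#' daily intake, inflated for the elevated resting metabolic rate of advanced
#' HIV infection: `base_intake * fraction * (1 + metabolic_increase)`. With
#' the programme inputs (2100 kcal minimum intake, 50% share, 30% metabolic
#' increase) this yields 1365 kcal/day; the published costing rounds to a
#' 1360 kcal/day target, which [ration_spec()] adopts as its default.
#'
#' @param base_intake recommended minimum daily intake, kcal.
#' @param fraction share of that intake supplied by the supplement.
#' @param metabolic_increase proportional increase in energy requirement.
#' @return kcal per day.
#' @export
#' @examples
#' kcal_target(2100, 0.5, 0.3)
kcal_target <- function(base_intake = 2100, fraction = 0.5, metabolic_increase = 0.3) {
  stopifnot(base_intake > 0, fraction > 0, metabolic_increase >= 0)
  base_intake * fraction * (1 + metabolic_increase)
}

#' Supplement ration specification
#'
#' @param target_kcal_per_day daily energy target of the ration (kcal).
#' @param duration_days days the ration is supplied per quarter ("3 months" =
#'   90 days, matching the model cycle).
#' @return a list with the two fields.
#' @export
ration_spec <- function(target_kcal_per_day = 1360, duration_days = 90) {
  stopifnot(target_kcal_per_day > 0, duration_days > 0)
  list(target_kcal_per_day = target_kcal_per_day, duration_days = duration_days)
}

#' Quarterly supplement quantity and cost per product
#'
#' Mass of each commodity needed to supply the daily energy target for the
#' ration duration, and its cost: `kg = (kcal_per_day / kcal_per_100g) * 0.1 *
#' days`, `cost = kg * price_per_kg`. Cost is computed from the mass rounded
#' to `kg_digits` decimals (2 by default), the precision at which programme
#' ration tables quote masses and the convention under which the published
#' costs reproduce to the cent; pass `kg_digits = NULL` to cost the unrounded
#' mass.
#'
#' @param products a products tibble, see [supplement_products()].
#' @param ration a [ration_spec()].
#' @param kg_digits decimals the mass is rounded to before costing, or `NULL`.
#' @return the products tibble with added `quarterly_kg` (unrounded) and
#'   `quarterly_cost` (USD) columns.
#' @export
#' @examples
#' quarterly_cost(supplement_products(), ration_spec())
quarterly_cost <- function(products, ration = ration_spec(), kg_digits = 2) {
  kg <- quarterly_quantity_kg(products, ration)
  kg_costed <- if (is.null(kg_digits)) kg else round(kg, kg_digits)
  products %>%
    mutate(quarterly_kg = kg, quarterly_cost = kg_costed * .data$price_per_kg)
}

#' @rdname quarterly_cost
#' @return for `quarterly_quantity_kg`: numeric vector of kilograms, one per
#'   product, unrounded.
#' @export
quarterly_quantity_kg <- function(products, ration = ration_spec()) {
  if (any(products$kcal_per_100g <= 0)) {
    abort("energy density must be positive", class = "nutricea_validation_error")
  }
  (ration$target_kcal_per_day / products$kcal_per_100g) * 0.1 * ration$duration_days
}

#' Affordability of each product under each effect scenario
#'
#' Crosses the per-product quarterly supplement cost with the scenario matrix
#' of threshold prices: a product is cost-effective for a stratum and scenario
#' when its quarterly cost does not exceed the threshold price S*.
#'
#' @param products a products tibble, see [supplement_products()].
#' @param scenarios a scenario matrix from [scenario_table()] (wide, one
#'   `s_star` column per stratum).
#' @param ration a [ration_spec()].
#' @param kg_digits see [quarterly_cost()].
#' @return a long tibble with columns `product`, `quarterly_cost`, `scenario`,
#'   `r_mort`, `r_ltfu`, `stratum`, `s_star`, `cost_effective`.
#' @export
#' @examples
#' sc <- scenario_table(zambia_cohort(), econ_params())
#' affordability_report(supplement_products(), sc)
affordability_report <- function(products, scenarios, ration = ration_spec(),
                                 kg_digits = 2) {
  costed <- quarterly_cost(products, ration, kg_digits = kg_digits)
  long <- tidyr::pivot_longer(
    scenarios,
    cols = -c("scenario", "r_mort", "r_ltfu"),
    names_to = "stratum", values_to = "s_star"
  )
  tidyr::expand_grid(
    costed[, c("product", "quarterly_cost")],
    long
  ) %>%
    mutate(cost_effective = .data$quarterly_cost <= .data$s_star)
}
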