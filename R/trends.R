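# National trend normalisation: per-1000-population rates, inflation
# correction against a base-year consumer price index, straight-line
# prevalence extrapolation, per-patient rates and annual class shares.

#' Rate per 1000 population
#'
#' @param items numeric count(s).
#' @param population population size(s); must be positive.
#' @return `items / population * 1000`.
#' @export
per_capita <- function(items, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive")
  }
  items / population * 1000
}

#' Inflation-correct a nominal cost
#'
#' Converts nominal costs into base-year prices using a consumer price
#' index table: `nominal * index[base_year] / index[year]`.
#'
#' @param nominal nominal cost(s), GBP.
#' @param year calendar year(s) of the nominal cost.
#' @param cpi tibble with columns `year` and `index`; all indices positive.
#' @param base_year index base year (default 2016); must be present in
#'   `cpi`.
#' @return cost(s) in base-year GBP.
#' @export
#' @examples
#' cpi <- tibble::tibble(year = c(2008, 2016), index = c(80, 100))
#' inflation_adjust(100, 2008, cpi) # 125
inflation_adjust <- function(nominal, year, cpi, base_year = 2016) {
  stopifnot(all(c("year", "index") %in% names(cpi)))
  if (any(cpi$index <= 0)) stop("CPI indices must be positive")
  idx <- setNames(cpi$index, as.character(cpi$year))
  if (!as.character(base_year) %in% names(idx)) {
    stop("CPI table does not contain base year ", base_year)
  }
  have <- as.character(year) %in% names(idx)
  if (!all(have)) {
    stop("CPI index missing for year(s): ",
         paste(sort(unique(year[!have])), collapse = ", "))
  }
  nominal * unname(idx[as.character(base_year)]) / unname(idx[as.character(year)])
}

#' Extrapolate a prevalence series by straight line
#'
#' Ordinary least-squares line on (year, prevalence), used to extend an
#' observed prevalence series to the full analysis period. Observed years
#' keep their observed values; other target years take fitted values. The
#' coefficient of determination of the line is attached as attribute
#' `fit_r2` (with `slope` and `intercept`).
#'
#' @param observed tibble with columns `year` and `prevalence` (%).
#' @param target_years integer vector of years to cover.
#' @return tibble `year`, `prevalence`, `observed` with attributes
#'   `fit_r2`, `slope`, `intercept`.
#' @export
extrapolate_prevalence <- function(observed, target_years) {
  stopifnot(all(c("year", "prevalence") %in% names(observed)))
  if (nrow(observed) < 2) stop("need at least 2 observed (year, prevalence) points")
  if (any(observed$prevalence <= 0 | observed$prevalence >= 100)) {
    stop("prevalence must be strictly between 0 and 100")
  }
  fit <- lm(prevalence ~ year, data = observed)
  r2 <- summary(fit)$r.squared
  years <- sort(unique(c(observed$year, target_years)))
  pred <- unname(predict(fit, newdata = data.frame(year = years)))
  out <- tibble::tibble(year = years, prevalence = pred, observed = years %in% observed$year)
  out$prevalence[out$observed] <-
    observed$prevalence[match(out$year[out$observed], observed$year)]
  if (any(out$prevalence <= 0)) {
    stop("extrapolated prevalence is non-positive for year(s): ",
         paste(out$year[out$prevalence <= 0], collapse = ", "))
  }
  attr(out, "fit_r2") <- r2
  attr(out, "slope") <- unname(coef(fit)["year"])
  attr(out, "intercept") <- unname(coef(fit)["(Intercept)"])
  out
}

#' Per-patient rate from a per-1000-population rate
#'
#' Divides a rate per 1000 population by the prevalence rate per 1000
#' (i.e. `prevalence_percent * 10`), giving a rate per person with
#' diabetes.
#'
#' @param rate_per_1000 numeric rate(s) per 1000 population.
#' @param prevalence_percent prevalence in percent; must be positive.
#' @return per-patient rate(s).
#' @export
per_patient <- function(rate_per_1000, prevalence_percent) {
  if (any(!is.finite(prevalence_percent)) || any(prevalence_percent <= 0)) {
    stop("prevalence must be positive")
  }
  rate_per_1000 / (prevalence_percent * 10)
}

#' Percent change between two values
#'
#' `(end - start) / start * 100`, rounded half away from zero to an
#' integer for display; the unrounded value is attached as attribute
#' `"unrounded"`.
#'
#' @param start starting value; must be positive.
#' @param end ending value.
#' @return rounded integer percent change (with attribute `unrounded`).
#' @export
#' @examples
#' percent_change(4.1, 4.8) # 17
#' percent_change(66, 102)  # 55
percent_change <- function(start, end) {
  if (any(!is.finite(start)) || any(start <= 0)) stop("start must be positive")
  raw <- (end - start) / start * 100
  rounded <- sign(raw) * floor(abs(raw) + 0.5)
  structure(rounded, unrounded = raw)
}

#' Class shares of a set of item counts
#'
#' Per-class percentage of total items. Inputs are taken as already
#' classified (combination products resolved under the aggregated
#' convention upstream).
#'
#' @param items named numeric vector (names are class labels), or tibble
#'   with columns `class` and `items`.
#' @return tibble `class`, `items`, `share_percent`; shares sum to 100.
#' @export
class_share <- function(items) {
  if (is.numeric(items) && !is.null(names(items))) {
    items <- tibble::tibble(class = names(items), items = unname(items))
  }
  stopifnot(all(c("class", "items") %in% names(items)))
  if (any(items$items < 0)) stop("item counts must be non-negative")
  tab <- dplyr::summarise(
    dplyr::group_by(items, .data$class), items = sum(.data$items), .groups = "drop"
  )
  total <- sum(tab$items)
  if (total <= 0) stop("total item count is zero")
  dplyr::mutate(tab, share_percent = .data$items / total * 100)
}

#' National trend table from annual dispensing data
#'
#' Classifies an annual dispensing table (one row per year and chemical,
#' with item counts and net ingredient cost) under the aggregated
#' combination convention, then derives per class and year: raw items and
#' cost, inflation-corrected cost, rates per 1000 population, rates per
#' person with type 2 diabetes, and the class share of all items.
#'
#' @param pca tibble `year`, `chemical`, `items`, `nic` (nominal GBP).
#' @param cpi tibble `year`, `index` (see [inflation_adjust()]).
#' @param population tibble `year`, `population`.
#' @param prevalence tibble `year`, `prevalence` (% with type 2 diabetes),
#'   covering every data year (see [extrapolate_prevalence()]).
#' @param class_map a `drug_class_map`.
#' @param base_year CPI base year, default 2016.
#' @return tibble with one row per (year, class): `items`, `nic`,
#'   `cost_real`, `items_per_1000`, `cost_per_1000`, `items_per_patient`,
#'   `cost_per_patient`, `class_share_percent`.
#' @export
trend_table <- function(pca, cpi, population, prevalence, class_map,
                        base_year = 2016) {
  stopifnot(all(c("year", "chemical", "items", "nic") %in% names(pca)))
  stopifnot(all(c("year", "population") %in% names(population)))
  stopifnot(all(c("year", "prevalence") %in% names(prevalence)))
  if (any(pca$items < 0) || any(pca$nic < 0)) {
    stop("items and nic must be non-negative")
  }
  years <- sort(unique(pca$year))
  for (tbl in list(population = population, prevalence = prevalence)) {
    miss <- setdiff(years, tbl$year)
    if (length(miss) > 0) {
      stop("denominator table missing year(s): ", paste(miss, collapse = ", "))
    }
  }
  cls <- classify_items(pca$chemical, mode = "aggregated", class_map = class_map)
  classified <- tibble::tibble(
    year = pca$year[cls$item],
    class = cls$class,
    items = pca$items[cls$item] * cls$weight,
    nic = pca$nic[cls$item] * cls$weight
  )
  agg <- dplyr::summarise(
    dplyr::group_by(classified, .data$year, .data$class),
    items = sum(.data$items), nic = sum(.data$nic), .groups = "drop"
  )
  agg$cost_real <- inflation_adjust(agg$nic, agg$year, cpi, base_year = base_year)
  pop <- setNames(population$population, as.character(population$year))
  prev <- setNames(prevalence$prevalence, as.character(prevalence$year))
  agg$items_per_1000 <- per_capita(agg$items, unname(pop[as.character(agg$year)]))
  agg$cost_per_1000 <- per_capita(agg$cost_real, unname(pop[as.character(agg$year)]))
  agg$items_per_patient <- per_patient(agg$items_per_1000,
                                       unname(prev[as.character(agg$year)]))
  agg$cost_per_patient <- per_patient(agg$cost_per_1000,
                                      unname(prev[as.character(agg$year)]))
  agg <- dplyr::mutate(
    dplyr::group_by(agg, .data$year),
    class_share_percent = .data$items / sum(.data$items) * 100
  )
  dplyr::arrange(dplyr::ungroup(agg), .data$year, .data$class)
}
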