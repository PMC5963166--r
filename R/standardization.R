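#' Stratified count tables
#'
#' Validates a long-format table of region-by-stratum population and death
#' counts, the input to indirect standardization. Strata are sex-by-age-band
#' combinations (16 in the default scheme: 2 sexes x 8 age bands).
#'
#' @param counts data.frame with columns `region_id`, `sex`, `age_band`,
#'   `population`, `deaths` — one row per region/stratum.
#' @param region_ids optional ordered id vector fixing region order
#'   (defaults to first appearance in `counts`).
#' @return the validated data.frame, class `stratified_counts`, with the
#'   region order stored in `attr(, "region_ids")`.
#' @export
stratified_counts <- function(counts, region_ids = NULL) {
  needed <- c("region_id", "sex", "age_band", "population", "deaths")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols)) {
    stop("counts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts$region_id <- as.character(counts$region_id)
  if (is.null(region_ids)) region_ids <- unique(counts$region_id)
  region_ids <- as.character(region_ids)
  if (!all(counts$region_id %in% region_ids)) {
    stop("counts contain region ids not in region_ids")
  }
  if (any(counts$population <= 0)) stop("population must be > 0 in every stratum row")
  if (any(counts$deaths < 0)) stop("deaths must be >= 0")
  if (any(counts$deaths != round(counts$deaths))) stop("deaths must be integer counts")
  key <- paste(counts$region_id, counts$sex, counts$age_band)
  if (anyDuplicated(key)) stop("duplicated region/stratum rows")
  counts <- counts[order(match(counts$region_id, region_ids)), , drop = FALSE]
  rownames(counts) <- NULL
  structure(counts, region_ids = region_ids,
            class = c("stratified_counts", "data.frame"))
}

stratum_key <- function(df) paste(df$sex, df$age_band, sep = "|")

#' National stratum-specific mortality rates
#'
#' Pools deaths and population over all regions within each sex-by-age
#' stratum: `rate_k = sum_i deaths_ik / sum_i population_ik`.
#'
#' @param counts a [stratified_counts()] table (or coercible data.frame).
#' @return data.frame with columns `sex`, `age_band`, `rate` (deaths per
#'   person), one row per stratum.
#' @export
national_rates <- function(counts) {
  counts <- as_counts(counts)
  key <- stratum_key(counts)
  pop <- tapply(counts$population, key, sum)
  dth <- tapply(counts$deaths, key, sum)
  if (any(pop == 0)) {
    stop("zero national population in stratum: ",
         paste(names(pop)[pop == 0], collapse = ", "))
  }
  first <- !duplicated(key)
  lab <- counts[first, c("sex", "age_band")]
  k <- key[first]
  data.frame(sex = lab$sex, age_band = lab$age_band,
             rate = as.numeric(dth[k] / pop[k]),
             stringsAsFactors = FALSE)
}

as_counts <- function(counts) {
  if (!inherits(counts, "stratified_counts")) counts <- stratified_counts(counts)
  counts
}

#' Expected deaths per region by indirect standardization
#'
#' Applies stratum-specific reference rates to each region's stratum
#' populations: `E_i = sum_k rate_k * population_ik`. Rates may come from
#' [national_rates()] on the same data (internal standardization, the
#' default elsewhere) or from an external reference population.
#'
#' @param counts a [stratified_counts()] table.
#' @param rates data.frame with columns `sex`, `age_band`, `rate`; its
#'   strata must exactly cover those present in `counts`.
#' @return data.frame with columns `region_id`, `expected`, in region order.
#' @export
expected_deaths <- function(counts, rates) {
  counts <- as_counts(counts)
  ck <- stratum_key(counts)
  rk <- stratum_key(rates)
  if (anyDuplicated(rk)) stop("duplicate strata in rates")
  if (!all(ck %in% rk)) {
    stop("rates are missing stratum label(s): ",
         paste(unique(ck[!(ck %in% rk)]), collapse = ", "))
  }
  r <- rates$rate[match(ck, rk)]
  region_ids <- attr(counts, "region_ids")
  e <- tapply(counts$population * r, counts$region_id, sum)[region_ids]
  data.frame(region_id = region_ids, expected = as.numeric(e),
             stringsAsFactors = FALSE)
}

#' Standardized mortality ratios
#'
#' `SMR_i = O_i / E_i` with `O_i` the region's total observed deaths and
#' `E_i` its expected deaths under the reference rates. With internal rates
#' (the default, `rates = NULL`) the standardization is self-consistent:
#' `sum(E_i) = sum(O_i)`.
#'
#' Regions with `E_i = 0` and no observed deaths are flagged (`smr = NA`)
#' with a warning; `E_i = 0` alongside observed deaths is an error.
#'
#' @param counts a [stratified_counts()] table.
#' @param rates optional external stratum rates (see [expected_deaths()]);
#'   when `NULL`, [national_rates()] of `counts` itself is used.
#' @return data.frame with columns `region_id`, `observed`, `expected`,
#'   `smr`, in region order.
#' @export
smr <- function(counts, rates = NULL) {
  counts <- as_counts(counts)
  if (is.null(rates)) rates <- national_rates(counts)
  region_ids <- attr(counts, "region_ids")
  e <- expected_deaths(counts, rates)
  o <- tapply(counts$deaths, counts$region_id, sum)[region_ids]
  o <- as.numeric(o)
  bad <- e$expected == 0 & o > 0
  if (any(bad)) {
    stop("zero expected deaths with observed deaths in region(s): ",
         paste(region_ids[bad], collapse = ", "))
  }
  undef <- e$expected == 0 & o == 0
  s <- ifelse(undef, NA_real_, o / e$expected)
  if (any(undef)) {
    warning("SMR undefined (0/0) for region(s), set NA: ",
            paste(region_ids[undef], collapse = ", "), call. = FALSE)
  }
  data.frame(region_id = region_ids, observed = o, expected = e$expected,
             smr = s, stringsAsFactors = FALSE)
}
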