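#' Construct an age-interval rates table
#'
#' Holds piecewise-constant breast-cancer incidence and competing
#' (non-breast-cancer death) hazards on contiguous age intervals, the form in
#' which national registries publish them (typically 5-year intervals).
#' Rates are stored per person-year.
#'
#' @param age_low,age_high integer vectors of interval bounds; intervals are
#'   `[age_low, age_high)`, must be contiguous, non-overlapping, ascending.
#' @param incidence breast-cancer incidence per person-year, one per interval.
#' @param mortality competing mortality per person-year, one per interval.
#' @param population optional population label (e.g. an ethnicity).
#' @return An object of class `rates_table`: a data.frame with columns
#'   `age_low`, `age_high`, `incidence`, `mortality` and a `population`
#'   attribute.
#' @examples
#' rates_table(c(50, 55), c(55, 60), c(0.0026, 0.0030), c(0.0004, 0.0006))
#' @export
rates_table <- function(age_low, age_high, incidence, mortality,
                        population = "overall") {
  n <- length(age_low)
  if (length(age_high) != n || length(incidence) != n || length(mortality) != n)
    stop("rates_table: all columns must have equal length")
  if (n == 0L) stop("rates_table: at least one interval required")
  if (any(!is.finite(incidence)) || any(!is.finite(mortality)) ||
      any(incidence < 0) || any(mortality < 0))
    stop("rates_table: rates must be finite and non-negative")
  if (any(age_high <= age_low))
    stop("rates_table: intervals must have age_high > age_low")
  o <- order(age_low)
  age_low <- age_low[o]; age_high <- age_high[o]
  incidence <- incidence[o]; mortality <- mortality[o]
  if (n > 1L) {
    gap <- which(age_low[-1L] != age_high[-n])
    if (length(gap))
      stop(sprintf(
        "rates_table: intervals must be contiguous; gap or overlap between age %g and %g",
        age_high[gap[1L]], age_low[gap[1L] + 1L]))
  }
  out <- data.frame(age_low = age_low, age_high = age_high,
                    incidence = incidence, mortality = mortality)
  attr(out, "population") <- population
  class(out) <- c("rates_table", "data.frame")
  out
}

#' Read a rates table from CSV
#'
#' Expects a header with columns `age_low`, `age_high`,
#' `incidence_per_100k_py`, `mortality_per_100k_py` and optionally
#' `population`; rates are converted to per person-year internally.
#'
#' @param path path to a CSV file.
#' @param population if the file carries several population labels, which one
#'   to load; default the first present.
#' @return A [rates_table()].
#' @export
load_rates <- function(path, population = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_low", "age_high", "incidence_per_100k_py", "mortality_per_100k_py")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("load_rates: missing column(s): ", paste(miss, collapse = ", "))
  if (!"population" %in% names(raw)) raw$population <- "overall"
  if (is.null(population)) population <- raw$population[1L]
  raw <- raw[raw$population == population, , drop = FALSE]
  if (!nrow(raw)) stop("load_rates: no rows for population '", population, "'")
  bad <- which(!is.finite(raw$incidence_per_100k_py) |
               !is.finite(raw$mortality_per_100k_py) |
               raw$incidence_per_100k_py < 0 | raw$mortality_per_100k_py < 0)
  if (length(bad))
    stop("load_rates: invalid rate at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  rates_table(raw$age_low, raw$age_high,
              raw$incidence_per_100k_py / 1e5,
              raw$mortality_per_100k_py / 1e5,
              population = population)
}

#' Write a rates table to CSV
#'
#' Inverse of [load_rates()]: rates are written per 100,000 person-years.
#'
#' @param rates a [rates_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rates_table"))
  out <- data.frame(age_low = rates$age_low, age_high = rates$age_high,
                    incidence_per_100k_py = rates$incidence * 1e5,
                    mortality_per_100k_py = rates$mortality * 1e5,
                    population = attr(rates, "population"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# index of the interval covering each age (error if uncovered)
.rate_interval <- function(rates, age) {
  idx <- findInterval(age, rates$age_low)
  ok <- idx >= 1L & age < rates$age_high[pmax(idx, 1L)]
  if (any(!ok))
    stop(sprintf("age %g outside rates coverage [%g, %g)",
                 age[!ok][1L], min(rates$age_low), max(rates$age_high)))
  idx
}

# split [age, age + window) at interval boundaries; returns data.frame with
# one row per sub-interval: start, end, idx (row of `rates`)
.split_window <- function(rates, age, window = 5, extra_cuts = numeric(0)) {
  end <- age + window
  if (age < min(rates$age_low) || end > max(rates$age_high))
    stop(sprintf("projection window [%g, %g) not covered by rates table [%g, %g)",
                 age, end, min(rates$age_low), max(rates$age_high)))
  cuts <- c(rates$age_low[rates$age_low > age & rates$age_low < end],
            extra_cuts[extra_cuts > age & extra_cuts < end])
  cuts <- sort(unique(c(age, end, cuts)))
  starts <- cuts[-length(cuts)]
  data.frame(start = starts, end = cuts[-1L],
             idx = .rate_interval(rates, starts))
}
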