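#' Rate schedules: year x age fertility and year x age x sex mortality
#'
#' A rate schedule bundles the period inputs the simulation consumes: an
#' age-specific fertility surface over reproductive ages 15--49 (rate per
#' woman-year), sex- and age-specific yearly death probabilities over ages
#' 0--50, and the per-year schedule TFR (the sum of the single-age fertility
#' rates). Years must be contiguous and cover every simulated year, burn-in
#' included.
#'
#' @param years integer vector of contiguous calendar years.
#' @param fertility numeric matrix, \code{length(years)} rows by 35 columns
#'   (ages 15--49), rates in \code{[0, 1]}.
#' @param mortality_female,mortality_male numeric matrices,
#'   \code{length(years)} rows by 51 columns (ages 0--50), yearly death
#'   probabilities in \code{[0, 1]}.
#' @return An object of class \code{srb_rate_schedule} with elements
#'   \code{years}, \code{fert_ages}, \code{mort_ages}, \code{fertility},
#'   \code{mortality} (list with \code{female} and \code{male}) and
#'   \code{schedule_tfr} (named by year).
#' @seealso [read_rate_schedule()], [synthesize_schedule()]
#' @export
rate_schedule <- function(years, fertility, mortality_female, mortality_male) {
  years <- as.integer(years)
  .assert(length(years) >= 1, "at least one year is required")
  .assert(all(diff(years) == 1L), "years must be contiguous")
  fert_ages <- 15:49
  mort_ages <- 0:50
  fertility <- as.matrix(fertility)
  mortality_female <- as.matrix(mortality_female)
  mortality_male <- as.matrix(mortality_male)
  .assert(nrow(fertility) == length(years) && ncol(fertility) == length(fert_ages),
          "fertility must be %d years x %d ages", length(years), length(fert_ages))
  for (m in list(mortality_female, mortality_male)) {
    .assert(nrow(m) == length(years) && ncol(m) == length(mort_ages),
            "mortality must be %d years x %d ages", length(years), length(mort_ages))
  }
  .assert(all(is.finite(fertility)) && all(fertility >= 0) && all(fertility <= 1),
          "fertility rates must lie in [0, 1]")
  .assert(all(is.finite(mortality_female)) && all(mortality_female >= 0) &&
            all(mortality_female <= 1) &&
            all(is.finite(mortality_male)) && all(mortality_male >= 0) &&
            all(mortality_male <= 1),
          "mortality probabilities must lie in [0, 1]")
  dimnames(fertility) <- list(years, fert_ages)
  dimnames(mortality_female) <- list(years, mort_ages)
  dimnames(mortality_male) <- list(years, mort_ages)
  structure(
    list(
      years = years,
      fert_ages = fert_ages,
      mort_ages = mort_ages,
      fertility = fertility,
      mortality = list(female = mortality_female, male = mortality_male),
      schedule_tfr = setNames(rowSums(fertility), years)
    ),
    class = "srb_rate_schedule"
  )
}

#' @export
print.srb_rate_schedule <- function(x, ...) {
  cat(sprintf(
    "<srb_rate_schedule> %d years (%d-%d); TFR %.3f -> %.3f\n",
    length(x$years), min(x$years), max(x$years),
    x$schedule_tfr[1], x$schedule_tfr[length(x$schedule_tfr)]
  ))
  invisible(x)
}

#' Check that a schedule covers a span of years
#' @param schedule a [rate_schedule()].
#' @param years integer vector of years that must be present.
#' @return invisibly \code{TRUE}; errors naming the missing years otherwise.
#' @export
assert_schedule_covers <- function(schedule, years) {
  missing <- setdiff(as.integer(years), schedule$years)
  .assert(length(missing) == 0, "schedule does not cover year(s): %s",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

.schedule_year_index <- function(schedule, year) {
  idx <- match(as.integer(year), schedule$years)
  .assert(!is.na(idx), "schedule does not cover year %d", year)
  idx
}

# Expand 5-year age-group rates (rows keyed by the group's lowest age) to
# single ages. "constant" repeats the group rate; "linear" interpolates
# between group midpoints and then rescales within each group so the group
# mean is preserved exactly.
.graduate_groups <- function(group_starts, group_rates, ages,
                             graduation = c("constant", "linear")) {
  graduation <- match.arg(graduation)
  group_starts <- as.integer(group_starts)
  width <- 5L
  group_of <- findInterval(ages, group_starts)
  .assert(all(group_of >= 1) && all(ages <= max(group_starts) + width - 1L),
          "age groups do not cover ages %d-%d", min(ages), max(ages))
  out <- group_rates[group_of]
  if (graduation == "linear" && length(group_starts) > 1) {
    mids <- group_starts + (width - 1) / 2
    interp <- stats::approx(mids, group_rates, xout = ages, rule = 2)$y
    for (g in seq_along(group_starts)) {
      sel <- group_of == g
      m <- mean(interp[sel])
      out[sel] <- if (m > 0) interp[sel] * group_rates[g] / m
                  else group_rates[g]
    }
  }
  out
}

#' Read a rate schedule from CSV tables
#'
#' Reads the fertility and mortality surfaces from plain CSV files laid out
#' like UN World Population Prospects extracts: fertility with columns
#' \code{year,age,rate}, mortality with columns \code{year,age,sex,rate}
#' (\code{sex} in \code{female}/\code{male}). The \code{age} column may hold
#' either single ages or the lowest age of a 5-year group (15, 20, ..., 45 for
#' fertility; 0, 5, ..., 50 for mortality), in which case rates are graduated
#' to single ages.
#'
#' Fertility rows are required for ages 15--49 and mortality rows for ages
#' 0--50 (or the covering 5-year groups) in every year; gaps raise an error
#' naming the missing year/age.
#'
#' @param fertility path to the fertility CSV.
#' @param mortality path to the mortality CSV.
#' @param graduation how 5-year group rates are expanded to single ages:
#'   \code{"constant"} (default; repeats the group rate, preserving the group
#'   mean exactly) or \code{"linear"} (midpoint interpolation rescaled to
#'   preserve the group mean).
#' @return A [rate_schedule()].
#' @export
read_rate_schedule <- function(fertility, mortality,
                               graduation = c("constant", "linear")) {
  graduation <- match.arg(graduation)
  .assert(file.exists(fertility), "fertility file not found: %s", fertility)
  .assert(file.exists(mortality), "mortality file not found: %s", mortality)
  fert <- read.csv(fertility, stringsAsFactors = FALSE)
  mort <- read.csv(mortality, stringsAsFactors = FALSE)
  .assert(all(c("year", "age", "rate") %in% names(fert)),
          "fertility CSV must have columns year,age,rate")
  .assert(all(c("year", "age", "sex", "rate") %in% names(mort)),
          "mortality CSV must have columns year,age,sex,rate")
  .assert(all(mort$sex %in% c("female", "male")),
          "mortality sex column must be 'female' or 'male'")
  .assert(all(fert$rate >= 0 & fert$rate <= 1),
          "fertility rates outside [0, 1]")
  .assert(all(mort$rate >= 0 & mort$rate <= 1),
          "mortality rates outside [0, 1]")

  years <- sort(unique(as.integer(fert$year)))
  .assert(identical(years, sort(unique(as.integer(mort$year)))),
          "fertility and mortality tables cover different years")
  .assert(all(diff(years) == 1L), "years must be contiguous; gap after %d",
          if (any(diff(years) != 1L)) years[which(diff(years) != 1L)[1]] else NA)

  expand_surface <- function(tab, ages, group_starts, label) {
    out <- matrix(NA_real_, nrow = length(years), ncol = length(ages))
    # dialect detection: a table whose distinct ages are exactly the 5-year
    # group starts is graduated; anything else must list every single age
    grouped <- setequal(unique(tab$age), group_starts)
    for (i in seq_along(years)) {
      rows <- tab[tab$year == years[i], , drop = FALSE]
      rows <- rows[order(rows$age), , drop = FALSE]
      if (grouped) {
        .assert(identical(sort(unique(rows$age)), as.numeric(group_starts)) ||
                  identical(sort(unique(rows$age)), as.integer(group_starts)),
                "%s table: year %d is missing age group(s)", label, years[i])
        out[i, ] <- .graduate_groups(rows$age, rows$rate, ages, graduation)
      } else {
        idx <- match(ages, rows$age)
        .assert(!anyNA(idx), "%s table: year %d is missing age(s) %s", label,
                years[i], paste(ages[is.na(idx)], collapse = ", "))
        out[i, ] <- rows$rate[idx]
      }
    }
    out
  }

  fert_mat <- expand_surface(fert, 15:49, seq(15, 45, 5), "fertility")
  mort_f <- expand_surface(mort[mort$sex == "female", ], 0:50, seq(0, 50, 5),
                           "mortality (female)")
  mort_m <- expand_surface(mort[mort$sex == "male", ], 0:50, seq(0, 50, 5),
                           "mortality (male)")
  rate_schedule(years, fert_mat, mort_f, mort_m)
}

#' Write a rate schedule to CSV tables
#'
#' Writes one row per (year, age) for fertility and per (year, age, sex) for
#' mortality, in the layout accepted by [read_rate_schedule()]. The
#' write/read round trip is the identity on rates.
#'
#' @param schedule a [rate_schedule()].
#' @param fertility,mortality output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_rate_schedule <- function(schedule, fertility, mortality) {
  .assert(inherits(schedule, "srb_rate_schedule"),
          "schedule must be an srb_rate_schedule")
  fert <- data.frame(
    year = rep(schedule$years, each = length(schedule$fert_ages)),
    age = rep(schedule$fert_ages, times = length(schedule$years)),
    rate = as.vector(t(schedule$fertility))
  )
  mort <- do.call(rbind, lapply(c("female", "male"), function(s) {
    data.frame(
      year = rep(schedule$years, each = length(schedule$mort_ages)),
      age = rep(schedule$mort_ages, times = length(schedule$years)),
      sex = s,
      rate = as.vector(t(schedule$mortality[[s]]))
    )
  }))
  write.csv(fert, fertility, row.names = FALSE, quote = FALSE)
  write.csv(mort, mortality, row.names = FALSE, quote = FALSE)
  invisible(c(fertility = fertility, mortality = mortality))
}

#' Read or write an initial population structure
#'
#' Initial populations are stored as CSV with columns \code{age,sex,count}
#' (ages 0--50, sex \code{female}/\code{male}).
#'
#' @param path CSV path.
#' @return For \code{read_initial_population}, an
#'   \code{srb_initial_population}: a 51 x 2 count matrix (ages 0--50 by
#'   female/male).
#' @export
read_initial_population <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("age", "sex", "count") %in% names(tab)),
          "initial population CSV must have columns age,sex,count")
  counts <- matrix(0, nrow = 51, ncol = 2,
                   dimnames = list(0:50, c("female", "male")))
  sel <- tab$age >= 0 & tab$age <= 50
  counts[cbind(tab$age[sel] + 1L, match(tab$sex[sel], c("female", "male")))] <-
    tab$count[sel]
  initial_population(counts)
}

#' @rdname read_initial_population
#' @param pop an \code{srb_initial_population}.
#' @export
write_initial_population <- function(pop, path) {
  .assert(inherits(pop, "srb_initial_population"),
          "pop must be an srb_initial_population")
  tab <- data.frame(
    age = rep(0:50, times = 2),
    sex = rep(c("female", "male"), each = 51),
    count = c(pop$counts[, "female"], pop$counts[, "male"])
  )
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an initial population structure
#' @param counts 51 x 2 non-negative count matrix (ages 0--50 by
#'   female/male columns).
#' @return An \code{srb_initial_population}.
#' @export
initial_population <- function(counts) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == 51 && ncol(counts) == 2,
          "counts must be 51 ages x 2 sexes")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(sum(counts) > 0, "total count must be positive")
  dimnames(counts) <- list(0:50, c("female", "male"))
  structure(list(counts = counts, total = as.integer(round(sum(counts)))),
            class = "srb_initial_population")
}

#' @export
print.srb_initial_population <- function(x, ...) {
  cat(sprintf("<srb_initial_population> %d individuals (%d female, %d male)\n",
              x$total, sum(x$counts[, "female"]), sum(x$counts[, "male"])))
  invisible(x)
}
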