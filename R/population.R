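#' Agent populations
#'
#' A population is a column-oriented collection of agent records. Each agent
#' carries: \code{id} (unique positive integer), \code{sex}
#' (1 = female, 2 = male), \code{birth_year}, \code{age} (completed years,
#' 0--50), and for females the reproductive state variables: \code{sp} (son
#' preference, 0/1, \code{NA} until assigned at reproductive age), \code{p}
#' (parity), \code{so} (living sons), \code{tech} (access to
#' sex-determination technology), \code{ab} (sex-selective abortions to
#' date). \code{mother_id} links children to their mother (\code{NA} for
#' founders) so a son's death can feed back on her stopping behavior.
#'
#' Column vectors are kept parallel; \code{so <= p} holds at all times, and
#' \code{ab} and \code{p} never decrease.
#'
#' @param init an [initial_population()] count structure.
#' @param year calendar year at which the structure is observed; founders get
#'   \code{birth_year = year - age}.
#' @return An object of class \code{srb_population}.
#' @export
population_from_counts <- function(init, year) {
  .assert(inherits(init, "srb_initial_population"),
          "init must be an srb_initial_population")
  counts <- init$counts
  age <- rep(rep(0:50, times = 2), times = as.vector(counts))
  sex <- rep(c(SEX_FEMALE, SEX_MALE), times = colSums(counts))
  n <- length(age)
  is_f <- sex == SEX_FEMALE
  structure(
    list(
      id = seq_len(n),
      sex = sex,
      birth_year = as.integer(year) - age,
      age = as.integer(age),
      sp = ifelse(is_f, NA_integer_, NA_integer_),
      p = ifelse(is_f, 0L, NA_integer_),
      so = ifelse(is_f, 0L, NA_integer_),
      tech = ifelse(is_f, FALSE, NA),
      ab = ifelse(is_f, 0L, NA_integer_),
      mother_id = rep(NA_integer_, n),
      next_id = n + 1L
    ),
    class = "srb_population"
  )
}

.pop_fields <- c("id", "sex", "birth_year", "age", "sp", "p", "so",
                 "tech", "ab", "mother_id")

pop_size <- function(pop) length(pop$id)

pop_subset <- function(pop, keep) {
  for (f in .pop_fields) pop[[f]] <- pop[[f]][keep]
  pop
}

# Append newborns (age 0) born in `year` to mothers `mother_id`.
pop_append_births <- function(pop, sex, mother_id, year) {
  n <- length(sex)
  if (n == 0) return(pop)
  ids <- pop$next_id + seq_len(n) - 1L
  is_f <- sex == SEX_FEMALE
  pop$id <- c(pop$id, ids)
  pop$sex <- c(pop$sex, sex)
  pop$birth_year <- c(pop$birth_year, rep(as.integer(year), n))
  pop$age <- c(pop$age, integer(n))
  pop$sp <- c(pop$sp, rep(NA_integer_, n))
  pop$p <- c(pop$p, ifelse(is_f, 0L, NA_integer_))
  pop$so <- c(pop$so, ifelse(is_f, 0L, NA_integer_))
  pop$tech <- c(pop$tech, ifelse(is_f, FALSE, NA))
  pop$ab <- c(pop$ab, ifelse(is_f, 0L, NA_integer_))
  pop$mother_id <- c(pop$mother_id, as.integer(mother_id))
  pop$next_id <- pop$next_id + n
  pop
}

#' @export
print.srb_population <- function(x, ...) {
  cat(sprintf("<srb_population> %d agents (%d female, %d male)\n",
              pop_size(x), sum(x$sex == SEX_FEMALE), sum(x$sex == SEX_MALE)))
  invisible(x)
}

#' Export a population snapshot as a data frame
#'
#' @param pop an \code{srb_population}.
#' @return A data frame with one row per agent and columns
#'   \code{id,sex,birth_year,age,sp,p,so,tech,ab,mother_id}; \code{sex} is
#'   \code{"female"}/\code{"male"}.
#' @export
population_snapshot <- function(pop) {
  data.frame(
    id = pop$id,
    sex = c("female", "male")[pop$sex],
    birth_year = pop$birth_year,
    age = pop$age,
    sp = pop$sp,
    p = pop$p,
    so = pop$so,
    tech = pop$tech,
    ab = pop$ab,
    mother_id = pop$mother_id
  )
}

#' Remove agents who have reached age 50
#'
#' The model tracks reproduction and the childhood/young-adult mortality that
#' feeds back on it; agents surviving to age 50 leave the simulation.
#'
#' @param pop an \code{srb_population}.
#' @return The population without agents aged 50 or older.
#' @export
retire_at_50 <- function(pop) {
  pop_subset(pop, pop$age < 50L)
}

#' Apply one year of mortality
#'
#' Each agent dies independently with the schedule's death probability for
#' their (age, sex) in \code{year}. Dead sons are reported as notices so the
#' engine can decrement their mothers' living-son counts: a woman who loses a
#' son may resume differential stopping behavior.
#'
#' @param pop an \code{srb_population}.
#' @param schedule a [rate_schedule()] covering \code{year}.
#' @param year calendar year.
#' @return A list with \code{population} (survivors) and \code{son_deaths},
#'   an integer vector of mother ids (one entry per dead son with a known
#'   mother; duplicated ids mean multiple sons lost).
#' @export
apply_mortality <- function(pop, schedule, year) {
  i <- .schedule_year_index(schedule, year)
  qf <- schedule$mortality$female[i, ]
  qm <- schedule$mortality$male[i, ]
  q <- ifelse(pop$sex == SEX_FEMALE, qf[pop$age + 1L], qm[pop$age + 1L])
  dead <- runif(pop_size(pop)) < q
  son_deaths <- pop$mother_id[dead & pop$sex == SEX_MALE]
  son_deaths <- son_deaths[!is.na(son_deaths)]
  list(population = pop_subset(pop, !dead), son_deaths = son_deaths)
}

#' Decrement mothers' living-son counts after sons' deaths
#'
#' Applies death notices from [apply_mortality()]: for each dead son whose
#' mother is still present, female and under 50, her \code{so} is reduced by
#' one (never below zero); notices for absent mothers are discarded.
#'
#' @param pop an \code{srb_population} (post-mortality survivors).
#' @param son_deaths integer vector of mother ids, one per dead son.
#' @return The updated population.
#' @export
register_son_deaths <- function(pop, son_deaths) {
  if (length(son_deaths) == 0) return(pop)
  idx <- match(son_deaths, pop$id)
  idx <- idx[!is.na(idx)]
  idx <- idx[pop$sex[idx] == SEX_FEMALE & pop$age[idx] < 50L]
  if (length(idx) == 0) return(pop)
  losses <- tabulate(idx, nbins = pop_size(pop))
  pop$so <- pmax(pop$so - losses, 0L)
  pop
}
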