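#' Reindeer-like life history for the non-Wright-Fisher simulator
#'
#' Ages are in calendar years (one simulator cycle = one year). Females aged
#' `first_repro_age..max_repro_age` each produce a litter every year they are
#' alive at reproduction time; with `first_repro_age = 1` a female gives birth
#' for the first time in the year she turns two. Sires are drawn from the
#' breeding males: each age-eligible male is allowed to breed in a given year
#' independently with probability `male_breeding_fraction` (a harem-like
#' system where only part of the males reproduce, re-drawn every year).
#'
#' Annual survival combines age-specific mortality, genetic fitness and
#' density dependence multiplicatively; `age_mortality` must have
#' `max_longevity + 1` entries (ages 0..max_longevity) and end in 1 so no
#' individual outlives `max_longevity`.
#'
#' The default litter-size distribution declines geometrically
#' (`p(k) proportional to 2^-(k-1)`, k = 1..8), a monotone-declining
#' distribution over 1..8 offspring; override `litter_probs` to change it.
#'
#' @param first_repro_age youngest reproducing age (years).
#' @param max_repro_age oldest reproducing age (years).
#' @param male_breeding_fraction probability an eligible male breeds in a year.
#' @param litter_probs probabilities of litter sizes 1..length(litter_probs);
#'   must sum to 1 and be non-increasing.
#' @param max_longevity maximum age (years).
#' @param age_mortality annual mortality probability per age 0..max_longevity.
#' @param generation_time generation time in years, used only for reporting
#'   conversions (e.g. the inbreeding clock).
#' @return an object of class `life_history`.
#' @export
life_history <- function(first_repro_age = 1L,
                         max_repro_age = 13L,
                         male_breeding_fraction = 0.5,
                         litter_probs = NULL,
                         max_longevity = 16L,
                         age_mortality = NULL,
                         generation_time = 6) {
  if (is.null(litter_probs)) {
    litter_probs <- 2^-(0:7)
    litter_probs <- litter_probs / sum(litter_probs)
  }
  if (is.null(age_mortality))
    age_mortality <- c(0.2, rep(0.05, 14), 0.74, 1.0)
  lh <- list(
    first_repro_age = as.integer(first_repro_age),
    max_repro_age = as.integer(max_repro_age),
    male_breeding_fraction = as.numeric(male_breeding_fraction),
    litter_probs = as.numeric(litter_probs),
    max_longevity = as.integer(max_longevity),
    age_mortality = as.numeric(age_mortality),
    generation_time = as.numeric(generation_time)
  )
  validate_life_history(lh)
  class(lh) <- "life_history"
  lh
}

validate_life_history <- function(lh) {
  probs <- c(lh$male_breeding_fraction, lh$litter_probs, lh$age_mortality)
  if (any(probs < 0 | probs > 1))
    stop("all life-history probabilities must be in [0, 1]")
  if (abs(sum(lh$litter_probs) - 1) > 1e-8)
    stop("litter_probs must sum to 1")
  if (any(diff(lh$litter_probs) > 1e-12))
    stop("litter_probs must be non-increasing in litter size")
  if (length(lh$age_mortality) != lh$max_longevity + 1)
    stop("age_mortality must have max_longevity + 1 entries (ages 0..max)")
  if (lh$age_mortality[lh$max_longevity + 1] != 1)
    stop("age_mortality at max_longevity must be 1")
  if (!(lh$first_repro_age < lh$max_repro_age &&
        lh$max_repro_age < lh$max_longevity))
    stop("need first_repro_age < max_repro_age < max_longevity")
  if (lh$generation_time <= 0) stop("generation_time must be positive")
  invisible(lh)
}

#' Expected litter size of a life history
#'
#' @param lh a [life_history()].
#' @return analytic mean of the configured litter-size distribution.
#' @export
mean_litter_size <- function(lh) {
  sum(seq_along(lh$litter_probs) * lh$litter_probs)
}
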