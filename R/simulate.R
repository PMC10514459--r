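# Orchestration of the C++ simulator core: burn-in construction, scenario
# execution, decennial sampling, and the TimeSeries result class.

.sim_lists <- function(arch, dfe, lh) {
  list(
    arch = list(n_chromosomes = arch$n_chromosomes,
                genes_per_chromosome = arch$genes_per_chromosome,
                gene_length = arch$gene_length,
                mutation_rate = arch$mutation_rate,
                intergene_recomb = arch$intergene_recomb),
    dfe = list(p_deleterious = dfe$p_deleterious,
               gamma_shape = dfe$gamma_shape,
               gamma_mean_s = dfe$gamma_mean_s,
               s_scale = dfe$s_scale,
               p_lethal = dfe$p_lethal),
    lh = list(first_repro_age = lh$first_repro_age,
              max_repro_age = lh$max_repro_age,
              max_longevity = lh$max_longevity,
              male_breeding_fraction = lh$male_breeding_fraction,
              litter_probs = lh$litter_probs,
              age_mortality = lh$age_mortality)
  )
}

#' Initialise a mainland population and run its burn-in
#'
#' Creates the simulator state, optionally seeds neutral variation at
#' mutation-drift equilibrium (the expected number of segregating neutral
#' sites at derived count i among 2N genomes is theta*L/i with
#' theta = 4*K*mu), and runs `burnin_years` yearly cycles so that the age
#' structure and the deleterious mutation classes reach a steady state.
#' Deleterious variation is never seeded analytically; it accumulates to
#' mutation-selection balance during the burn-in.
#'
#' The returned state can be passed to [continue_scenario()] (which clones
#' it), so one burn-in can serve several scenarios and sampling seeds.
#'
#' @param arch,dfe,lh architecture, DFE and life history — already rescaled
#'   if a scaling policy is in use (see [apply_scaling()]).
#' @param capacity mainland carrying capacity (already rescaled).
#' @param burnin_years number of burn-in cycles to run.
#' @param seed optional seed set before initialisation.
#' @param equilibrium seed neutral variation analytically before the burn-in.
#' @param ne_ratio effective-to-census size ratio used for the equilibrium
#'   seeding theta (`4 * ne_ratio * capacity * mu`). Under the default
#'   life history (harem mating, high litter-size variance, overlapping
#'   generations) trial runs place Ne/N near 0.25, the default; census-based
#'   seeding (ne_ratio = 1) starts far above equilibrium and takes several
#'   Ne generations to decay.
#' @param theta optional explicit per-site seeding theta, overriding
#'   `ne_ratio`.
#' @param label population label (default "mainland").
#' @param compact_interval internally compact fixed mutations every this many
#'   years.
#' @return an object of class `sim_state`.
#' @export
init_mainland <- function(arch, dfe, lh, capacity, burnin_years,
                          seed = NULL, equilibrium = TRUE, ne_ratio = 0.25,
                          theta = NULL, label = "mainland",
                          compact_interval = 100L) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- .sim_lists(arch, dfe, lh)
  ptr <- .sim_new(cfg$arch, cfg$dfe, cfg$lh)
  .sim_add_population(ptr, label, capacity, as.integer(round(capacity)),
                      init_age_max = min(10L, lh$max_repro_age))
  if (is.null(theta)) theta <- 4 * ne_ratio * capacity * arch$mutation_rate
  if (equilibrium && theta > 0)
    .sim_seed_neutral(ptr, label, theta)
  burnin_years <- as.integer(burnin_years)
  if (burnin_years > 0) {
    for (yr in seq_len(burnin_years)) {
      .sim_set_year(ptr, -(burnin_years - yr + 1L))
      .sim_reproduce(ptr)
      .sim_survive(ptr)
      if (yr %% compact_interval == 0L) .sim_compact(ptr)
    }
  }
  structure(list(ptr = ptr, arch = arch, dfe = dfe, lh = lh,
                 capacity = capacity, label = label,
                 burnin_years = burnin_years, seed = seed,
                 compact_interval = as.integer(compact_interval)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cen <- .sim_census(x$ptr)
  cat("<sim_state> populations:",
      paste(sprintf("%s (N = %d, K = %g)", cen$population, cen$N, cen$K),
            collapse = ", "), "\n")
  cat("  burn-in:", x$burnin_years, "years; genome:",
      format(x$arch$genome_bp, big.mark = ","), "bp\n")
  invisible(x)
}

.summary_row <- function(state_ptr, pop, n, year_bp, froh_min_len = 1e5) {
  samp <- .as_sim_sample(.sim_sample_state(state_ptr, pop, as.integer(n)))
  cc <- category_counts(samp)
  data.frame(year_bp = year_bp, population = pop,
             N = NA_integer_,
             mean_fitness = NA_real_,
             het_per_kb = sim_heterozygosity(samp),
             f_roh_100kb = sim_froh(samp, min_len = froh_min_len),
             realized_load = realized_load(samp),
             masked_load = masked_load(samp),
             n_weak = cc[["weak"]], n_moderate = cc[["moderate"]],
             n_strong = cc[["strong"]], n_very_strong = cc[["very_strong"]],
             stringsAsFactors = FALSE)
}

.na_row <- function(pop, year_bp) {
  data.frame(year_bp = year_bp, population = pop, N = 0L,
             mean_fitness = NA_real_, het_per_kb = NA_real_,
             f_roh_100kb = NA_real_, realized_load = NA_real_,
             masked_load = NA_real_, n_weak = NA_real_,
             n_moderate = NA_real_, n_strong = NA_real_,
             n_very_strong = NA_real_, stringsAsFactors = FALSE)
}

#' Run a scenario's event timeline from a burnt-in mainland state
#'
#' Clones `state`, then runs one yearly cycle per year from the oldest event
#' down to year 0. Cycle order within a year: reproduce, survive, apply any
#' events scheduled for that year (founding or capacity change), record
#' summaries if the year is a sampling year. Summaries are computed from a
#' uniform sample of `sample_size` individuals per population (the whole
#' population when N is smaller).
#'
#' @param state a [init_mainland()] state (left untouched).
#' @param sc the (rescaled) scenario whose events to run; its
#'   `mainland_capacity` must match the state's.
#' @param seed optional seed set before the clone, making the continuation
#'   reproducible independently of what produced `state`.
#' @param sample_size individuals sampled per population per record.
#' @param sample_interval record summaries every this many years (default 10).
#' @param replicate replicate id stored in the output rows.
#' @param froh_min_len minimum ROH tract length in bp for the recorded
#'   F_ROH. Tract-length thresholds are genetic lengths: under population
#'   rescaling the per-bp recombination rate grows by 1/lambda, so a 0.1 Mb
#'   threshold on the full map corresponds to `1e5 * lambda` bp on the
#'   rescaled map.
#' @return a `sim_timeseries` data.frame; attribute `extinct` maps
#'   population labels to extinction years (years BP) if any went extinct.
#' @export
continue_scenario <- function(state, sc, seed = NULL, sample_size = 30L,
                              sample_interval = 10L, replicate = 1L,
                              froh_min_len = 1e5) {
  stopifnot(inherits(state, "sim_state"), inherits(sc, "fs_scenario"))
  if (!isTRUE(all.equal(sc$mainland_capacity, state$capacity)))
    stop("scenario mainland capacity (", sc$mainland_capacity,
         ") does not match the burnt-in state (", state$capacity, ")")
  if (!is.null(seed)) set.seed(seed)
  ptr <- .sim_clone(state$ptr)
  ev_time <- vapply(sc$events, `[[`, numeric(1), "time")
  t_start <- max(ev_time)
  rows <- vector("list", floor(t_start / sample_interval) + 2L)
  nrow <- 0L
  extinct <- c()
  for (yr in seq(t_start, 0)) {
    .sim_set_year(ptr, yr)
    .sim_reproduce(ptr)
    .sim_survive(ptr)
    for (ev in sc$events[ev_time == yr]) {
      if (ev$kind == "found_from_mainland") {
        .sim_found(ptr, state$label, ev$population,
                   as.integer(round(ev$capacity)), ev$capacity)
      } else {
        .sim_set_capacity(ptr, ev$population, ev$capacity)
      }
    }
    if (yr %% state$compact_interval == 0L) .sim_compact(ptr)
    if (yr %% sample_interval == 0L) {
      cen <- .sim_census(ptr)
      for (i in seq_along(cen$population)) {
        pop <- cen$population[i]
        if (cen$N[i] == 0L) {
          if (!pop %in% names(extinct)) extinct[pop] <- yr
          row <- .na_row(pop, yr)
        } else {
          row <- .summary_row(ptr, pop, sample_size, yr, froh_min_len)
          row$N <- cen$N[i]
          row$mean_fitness <- cen$mean_fitness[i]
        }
        nrow <- nrow + 1L
        rows[[nrow]] <- row
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nrow)])
  out <- cbind(replicate = as.integer(replicate), out)
  structure(out, class = c("sim_timeseries", "data.frame"),
            label = sc$label, extinct = extinct)
}

#' Run a demographic scenario
#'
#' High-level driver: applies the scaling policy, then for each replicate r
#' seeds the RNG with `base_seed + r`, builds a mainland at mutation-drift
#' equilibrium, runs the burn-in and the scenario timeline, and records the
#' per-decade summary statistics (heterozygosity per kb, F_ROH over tracts
#' longer than 0.1 Mb, realized and masked load, and per-category deleterious
#' allele counts) from samples of `sample_size` individuals per population.
#'
#' @param sc a [scenario()] (unscaled).
#' @param arch,dfe,lh genome architecture, DFE and life history (unscaled).
#' @param policy a [scaling_policy()].
#' @param replicates number of replicates.
#' @param base_seed base seed; replicate r uses seed `base_seed + r`.
#' @param sample_size individuals sampled per record (default 30).
#' @param sample_interval years between records; default 10 scaled by
#'   `policy$lambda` (at least 1).
#' @param burnin_years override the scaled burn-in length (scaled years).
#' @param verbose print per-replicate progress.
#' @return a `sim_timeseries` data.frame with one row per
#'   (replicate, sampled year, population); attributes `label`, `lambda`,
#'   `seeds`, `extinct`.
#' @export
run_scenario <- function(sc, arch = genome_architecture(), dfe = dfe_spec(),
                         lh = life_history(), policy = scaling_policy(),
                         replicates = 1L, base_seed = 1L, sample_size = 30L,
                         sample_interval = NULL, burnin_years = NULL,
                         verbose = FALSE) {
  scaled <- apply_scaling(sc, arch, dfe, policy)
  if (is.null(sample_interval))
    sample_interval <- max(1L, as.integer(round(10 * policy$lambda)))
  if (is.null(burnin_years)) burnin_years <- scaled$scenario$burnin_years
  out <- vector("list", replicates)
  extinct <- list()
  seeds <- base_seed + seq_len(replicates)
  for (r in seq_len(replicates)) {
    if (verbose) message("replicate ", r, " (seed ", seeds[r], ")")
    st <- init_mainland(scaled$arch, scaled$dfe, lh,
                        scaled$scenario$mainland_capacity, burnin_years,
                        seed = seeds[r])
    ts <- continue_scenario(st, scaled$scenario, sample_size = sample_size,
                            sample_interval = sample_interval, replicate = r,
                            froh_min_len = 1e5 * policy$lambda)
    ex <- attr(ts, "extinct")
    if (length(ex)) extinct[[as.character(r)]] <- ex
    out[[r]] <- as.data.frame(ts)
  }
  res <- do.call(rbind, out)
  res$year_bp_full <- if (policy$lambda < 1 && isTRUE(policy$rescale_times))
    res$year_bp / policy$lambda else res$year_bp
  structure(res, class = c("sim_timeseries", "data.frame"),
            label = sc$label, lambda = policy$lambda, seeds = seeds,
            extinct = extinct)
}

#' @export
print.sim_timeseries <- function(x, ...) {
  cat("<sim_timeseries>", attr(x, "label") %||% "", "—",
      length(unique(x$replicate)), "replicate(s),",
      length(unique(x$year_bp)), "sampled year(s)\n")
  ex <- attr(x, "extinct")
  if (length(ex)) cat("  extinct replicates:", length(ex), "\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.sim_timeseries <- function(object, ...) {
  df <- as.data.frame(object)
  num <- c("N", "het_per_kb", "f_roh_100kb", "realized_load", "masked_load",
           "n_weak", "n_moderate", "n_strong", "n_very_strong")
  agg <- stats::aggregate(df[num], by = df[c("year_bp", "population")],
                   FUN = function(v) mean(v, na.rm = TRUE))
  agg[order(-agg$year_bp, agg$population), ]
}

#' Plot a simulated time series
#'
#' Base-graphics panels of population size, heterozygosity, F_ROH, realized
#' and masked load against time, replicate means per population.
#'
#' @param x a `sim_timeseries`.
#' @param ... unused.
#' @export
plot.sim_timeseries <- function(x, ...) {
  agg <- summary(x)
  pops <- unique(agg$population)
  vars <- c(N = "N", `het / kb` = "het_per_kb", `F_ROH` = "f_roh_100kb",
            `realized load` = "realized_load", `masked load` = "masked_load")
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(2.2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_along(vars)) {
    v <- vars[i]
    graphics::plot(NA, xlim = rev(range(agg$year_bp)),
                   ylim = range(agg[[v]], na.rm = TRUE),
                   xlab = "years BP", ylab = names(vars)[i])
    for (j in seq_along(pops)) {
      d <- agg[agg$population == pops[j], ]
      graphics::lines(d$year_bp, d[[v]], col = j)
    }
    if (i == 1) graphics::legend("topright", legend = pops,
                                 col = seq_along(pops), lty = 1, bty = "n")
  }
  invisible(x)
}
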