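#' Population-rescaling policy
#'
#' Full-size scenarios (mainland K = 50,000, 500,000-year burn-in) are not
#' desk-runnable; standard population rescaling by a factor `lambda` in
#' (0, 1] shrinks them while preserving the population-scaled compound
#' parameters (N*mu, N*r, N*s) that control drift, diversity and selection:
#'
#' * carrying capacities are multiplied by `lambda` (rounded; results below
#'   2 are raised to 2 with a warning),
#' * the per-site mutation rate and the inter-gene crossover probability are
#'   divided by `lambda`,
#' * selection coefficients are divided by `lambda` and clamped at -1
#'   (categorisation and dominance stay on the unscaled scale),
#' * event times and the burn-in are multiplied by `lambda` (rounded).
#'
#' Time compression is what keeps total drift over the scenario window
#' invariant: with `lambda * K` individuals, per-generation drift is
#' `1/lambda` times stronger, so the window must contain `lambda` times
#' fewer generations. Life history and age structure remain in calendar
#' years; this makes generations span relatively more of the (compressed)
#' scenario, the usual and accepted distortion of rescaled
#' overlapping-generation models.
#'
#' @param lambda scaling factor in (0, 1]; 1 leaves everything unchanged.
#' @param burnin_override burn-in duration in *scaled* years, replacing the
#'   scenario's scaled burn-in (optional).
#' @param rescale_times logical; multiply event times and burn-in by
#'   `lambda` (default TRUE).
#' @param min_capacity floor applied to rescaled carrying capacities
#'   (default 2). Rescaling a small founder capacity to a handful of
#'   individuals makes the scaled population demographically non-viable in a
#'   way the full-size population is not (a two-individual deme under
#'   density-dependent survival and stochastic sex ratios goes extinct
#'   almost surely): for scenarios whose smallest capacity matters, raise
#'   the floor to the smallest demographically viable deme for the life
#'   history in use (about 10 for the default reindeer-like life history —
#'   a few breeding females plus males).
#' @return a `scaling_policy`.
#' @export
scaling_policy <- function(lambda = 1, burnin_override = NULL,
                           rescale_times = TRUE, min_capacity = 2) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda <= 0 || lambda > 1)
    stop("lambda must be a single number in (0, 1]")
  if (min_capacity < 2) stop("min_capacity must be at least 2")
  structure(list(lambda = as.numeric(lambda),
                 burnin_override = burnin_override,
                 rescale_times = isTRUE(rescale_times),
                 min_capacity = as.numeric(min_capacity)),
            class = "scaling_policy")
}

.scale_capacity <- function(K, lambda, floor_k = 2) {
  k <- round(K * lambda)
  if (any(k < floor_k)) {
    warning("rescaled carrying capacity below ", floor_k,
            "; raised to the minimum of ", floor_k)
    k <- pmax(k, floor_k)
  }
  k
}

#' Apply a scaling policy to a scenario, architecture and DFE
#'
#' @param sc an [scenario()] object.
#' @param arch a [genome_architecture()].
#' @param dfe a [dfe_spec()].
#' @param policy a [scaling_policy()].
#' @return list with elements `scenario`, `arch`, `dfe`, `lambda`.
#' @export
apply_scaling <- function(sc, arch, dfe, policy = scaling_policy()) {
  stopifnot(inherits(sc, "fs_scenario"), inherits(arch, "genome_architecture"),
            inherits(dfe, "dfe_spec"), inherits(policy, "scaling_policy"))
  lam <- policy$lambda
  if (lam == 1 && is.null(policy$burnin_override))
    return(list(scenario = sc, arch = arch, dfe = dfe, lambda = 1))
  floor_k <- policy$min_capacity %||% 2
  sc2 <- sc
  sc2$mainland_capacity <- .scale_capacity(sc$mainland_capacity, lam, floor_k)
  sc2$events <- lapply(sc$events, function(ev) {
    ev$capacity <- .scale_capacity(ev$capacity, lam, floor_k)
    if (policy$rescale_times) ev$time <- as.integer(round(ev$time * lam))
    ev
  })
  times <- vapply(sc2$events, `[[`, numeric(1), "time")
  if (any(diff(times) >= 0))
    stop("event times collide after rescaling; use a larger lambda")
  sc2$burnin_years <- if (!is.null(policy$burnin_override))
    policy$burnin_override
  else if (policy$rescale_times) max(1, round(sc$burnin_years * lam))
  else sc$burnin_years
  validate_scenario(sc2)

  arch2 <- arch
  arch2$mutation_rate <- min(1, arch$mutation_rate / lam)
  arch2$intergene_recomb <- arch$intergene_recomb / lam
  if (arch2$intergene_recomb > 0.5) {
    warning("rescaled inter-gene recombination exceeds 0.5; capped at 0.5 ",
            "(free recombination)")
    arch2$intergene_recomb <- 0.5
  }

  dfe2 <- dfe
  dfe2$s_scale <- dfe$s_scale / lam

  list(scenario = sc2, arch = arch2, dfe = dfe2, lambda = lam)
}
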