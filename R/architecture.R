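#' Genome architecture for the forward simulator
#'
#' The simulated genome is a set of chromosomes, each a contiguous array of
#' equally long genes. Gene `g` (0-based) occupies the half-open bp interval
#' `[g * gene_length, (g + 1) * gene_length)` on its chromosome. There is no
#' recombination within genes, a fixed crossover probability at each gene
#' boundary, and free recombination between chromosomes.
#'
#' Defaults follow the reindeer-genome-informed setup: 6 chromosomes of 500
#' genes x 1750 bp, a mutation rate of 1.76e-9 per site per year (one
#' simulator cycle is one calendar year, mutations are applied at each
#' meiosis), and an inter-gene crossover probability of 1e-3.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length gene length in bp.
#' @param mutation_rate per-site mutation rate applied per meiosis.
#' @param intergene_recomb crossover probability per gene boundary per meiosis.
#' @return an object of class `genome_architecture`.
#' @seealso [mutation_rate_per_year()] for the per-generation conversion.
#' @export
genome_architecture <- function(n_chromosomes = 6L,
                                genes_per_chromosome = 500L,
                                gene_length = 1750L,
                                mutation_rate = 1.76e-9,
                                intergene_recomb = 1e-3) {
  arch <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_length = as.integer(gene_length),
    mutation_rate = as.numeric(mutation_rate),
    intergene_recomb = as.numeric(intergene_recomb)
  )
  stopifnot(arch$n_chromosomes >= 1, arch$genes_per_chromosome >= 1,
            arch$gene_length >= 1)
  if (arch$mutation_rate < 0 || arch$mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (arch$intergene_recomb < 0 || arch$intergene_recomb > 1)
    stop("intergene_recomb must be in [0, 1]")
  arch$chrom_bp <- as.numeric(arch$genes_per_chromosome) * arch$gene_length
  arch$genome_bp <- arch$chrom_bp * arch$n_chromosomes
  class(arch) <- "genome_architecture"
  arch
}

#' Convert a per-generation mutation rate to a per-year rate
#'
#' @param per_generation mutation rate per site per generation
#'   (default 1.06e-8).
#' @param generation_time generation time in years (default 6).
#' @return mutation rate per site per year.
#' @export
mutation_rate_per_year <- function(per_generation = 1.06e-8,
                                   generation_time = 6) {
  per_generation / generation_time
}

#' Distribution of fitness effects of new mutations
#'
#' New coding mutations are deleterious (non-synonymous) with probability
#' `ns_to_syn_ratio / (1 + ns_to_syn_ratio)` and neutral (synonymous)
#' otherwise. Deleterious selection coefficients are `s = -X` with
#' `X ~ Gamma(shape, mean = |gamma_mean_s|)`, clamped at -1. The dominance
#' coefficient is a step function of `s` (inverse h-s relationship):
#' `h = 0` for `s < -0.1`, `0.01` for `-0.1 <= s < -0.01`, `0.1` for
#' `-0.01 <= s < -0.001` and `0.4` for weaker mutations.
#'
#' Under population rescaling (see [apply_scaling()]) selection coefficients
#' are multiplied by `s_scale` *after* categorisation and dominance
#' assignment, so the category bins always refer to the unscaled effect.
#'
#' @param ns_to_syn_ratio ratio of deleterious to neutral mutations (2.31).
#' @param gamma_mean_s mean selection coefficient of deleterious mutations
#'   (negative).
#' @param gamma_shape gamma shape parameter.
#' @param s_scale multiplier applied to drawn selection coefficients
#'   (population rescaling); 1 leaves them unchanged.
#' @param p_lethal optional extra point mass of lethal mutations (s = -1)
#'   within the deleterious class; default 0 (off).
#' @return an object of class `dfe_spec`.
#' @export
dfe_spec <- function(ns_to_syn_ratio = 2.31,
                     gamma_mean_s = -0.01314833,
                     gamma_shape = 0.186,
                     s_scale = 1,
                     p_lethal = 0) {
  stopifnot(ns_to_syn_ratio >= 0, gamma_mean_s < 0, gamma_shape > 0,
            s_scale >= 1, p_lethal >= 0, p_lethal <= 1)
  structure(list(
    ns_to_syn_ratio = ns_to_syn_ratio,
    p_deleterious = ns_to_syn_ratio / (1 + ns_to_syn_ratio),
    gamma_mean_s = gamma_mean_s,
    gamma_shape = gamma_shape,
    s_scale = s_scale,
    p_lethal = p_lethal
  ), class = "dfe_spec")
}

#' Dominance coefficient implied by a selection coefficient
#'
#' @param s selection coefficient(s), on the unscaled (per-generation) scale.
#' @return dominance coefficient(s): 0, 0.01, 0.1 or 0.4 by bin.
#' @export
dominance_coefficient <- function(s) {
  h <- rep(0.4, length(s))
  h[s < -0.001] <- 0.1
  h[s < -0.01] <- 0.01
  h[s < -0.1] <- 0
  h
}

#' Selection-strength category of a mutation
#'
#' @param s selection coefficient(s) on the unscaled scale.
#' @return factor with levels neutral, weak, moderate, strong, very_strong.
#' @export
dfe_category <- function(s) {
  lab <- rep("neutral", length(s))
  lab[s < 0] <- "weak"
  lab[s < -0.001] <- "moderate"
  lab[s < -0.01] <- "strong"
  lab[s < -0.1] <- "very_strong"
  factor(lab, levels = .category_levels)
}

#' Draw new mutations from the DFE
#'
#' Draws `n` mutations: site uniform over the gene map, selection coefficient
#' from the mixture described in [dfe_spec()], dominance from
#' [dominance_coefficient()]. Positions are 0-based within the chromosome.
#'
#' @param n number of mutations.
#' @param arch a [genome_architecture()].
#' @param dfe a [dfe_spec()].
#' @return data.frame with columns chrom, pos, s, h, category.
#' @export
sample_mutation <- function(n = 1, arch = genome_architecture(),
                            dfe = dfe_spec()) {
  n <- as.integer(n)
  u <- floor(runif(n) * arch$genome_bp)
  chrom <- as.integer(u %/% arch$chrom_bp) + 1L
  pos <- as.integer(u %% arch$chrom_bp)
  del <- runif(n) < dfe$p_deleterious
  s_raw <- numeric(n)
  nd <- sum(del)
  if (nd > 0) {
    draw <- -rgamma(nd, shape = dfe$gamma_shape,
                    scale = abs(dfe$gamma_mean_s) / dfe$gamma_shape)
    if (dfe$p_lethal > 0)
      draw[runif(nd) < dfe$p_lethal] <- -1
    s_raw[del] <- draw
  }
  h <- dominance_coefficient(s_raw)
  h[!del] <- 0.5
  category <- dfe_category(s_raw)
  s <- pmax(s_raw * dfe$s_scale, -1)
  data.frame(chrom = chrom, pos = pos, s = s, h = h, category = category)
}
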