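# Builders for small, fully specified simulator states used across tests.

toy_arch <- function(n_chromosomes = 2, genes_per_chromosome = 10,
                     gene_length = 1000, mutation_rate = 0,
                     intergene_recomb = 0) {
  genome_architecture(n_chromosomes, genes_per_chromosome, gene_length,
                      mutation_rate, intergene_recomb)
}

# life history with no accidental deaths below the longevity cap
immortal_lh <- function(max_longevity = 16, male_breeding_fraction = 1) {
  life_history(male_breeding_fraction = male_breeding_fraction,
               max_repro_age = min(13L, max_longevity - 1L),
               max_longevity = max_longevity,
               age_mortality = c(rep(0, max_longevity), 1))
}

toy_sim <- function(arch = toy_arch(), dfe = dfe_spec(), lh = life_history()) {
  cfg <- foundersim:::.sim_lists(arch, dfe, lh)
  foundersim:::.sim_new(cfg$arch, cfg$dfe, cfg$lh)
}

# add a population of explicitly constructed individuals
# inds: list of list(sex = 0/1, age, h1 = ids, h2 = ids)
toy_pop <- function(ptr, label, K, inds) {
  foundersim:::.sim_add_population(ptr, label, K, 0L, 0L)
  for (d in inds)
    foundersim:::.sim_add_individual(ptr, label, d$sex, d$age,
                                     as.integer(d$h1), as.integer(d$h2))
  ptr
}

toy_mut <- function(ptr, chrom, pos, s = 0, h = 0.5, cat = 0) {
  foundersim:::.sim_new_mutation(ptr, as.integer(chrom), as.integer(pos),
                                 s, h, as.integer(cat))
}

sample_all <- function(ptr, label, n = 1000L) {
  foundersim:::.as_sim_sample(foundersim:::.sim_sample_state(ptr, label,
                                                             as.integer(n)))
}

# minimal sim_sample built directly from matrices (no C++ state)
toy_sample <- function(geno, pos, chrom = 1L, s = 0, h = 0.5,
                       category = "neutral", fixed = NULL,
                       chrom_len = 875000, n_chrom = 6) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  site <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                     s = rep_len(s, n), h = rep_len(h, n),
                     category = factor(rep_len(category, n),
                                       levels = foundersim:::.category_levels))
  sim_sample(geno, site, fixed, chrom_len = chrom_len, n_chrom = n_chrom)
}

toy_fixed <- function(chrom, pos, s, h, category) {
  data.frame(chrom = chrom, pos = pos, s = s, h = h,
             category = factor(category,
                               levels = foundersim:::.category_levels))
}

# small annotated variant table with two populations
toy_vt <- function(geno, category, pos = NULL, chrom = NULL,
                   populations = NULL, ...) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(chrom)) chrom <- rep(1L, ns)
  if (is.null(populations))
    populations <- rep(c("popA", "popB"), each = ncol(geno) / 2)
  variant_table(chrom, pos, category, geno, populations, ...)
}
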