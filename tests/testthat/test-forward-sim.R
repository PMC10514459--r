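# Forward simulator semantics: fitness arithmetic, gamete formation,
# reproduction and survival rules, founding bookkeeping, determinism and
# population regulation.

test_that("individual fitness is multiplicative over genotypes", {
  ptr <- toy_sim()
  foundersim:::.sim_add_population(ptr, "p", 10, 0L, 0L)
  clean <- toy_mut(ptr, 1, 10) # neutral
  strong <- toy_mut(ptr, 1, 500, s = -0.1, h = 0.01, cat = 3)
  mod <- toy_mut(ptr, 2, 700, s = -0.2, h = 0, cat = 4)
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, integer(), integer())
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(strong), integer())
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(strong), c(strong))
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L,
                                   c(clean, strong, mod), c(strong, mod))
  w <- foundersim:::.sim_individuals(ptr, "p")$fitness
  expect_equal(w[1], 1.0)                  # mutation-free: empty product
  expect_equal(w[2], 1 - 0.1 * 0.01)       # het: 1 + h s
  expect_equal(w[3], 0.9)                  # hom: 1 + s
  expect_equal(w[4], 0.9 * 0.8)            # hom strong x hom recessive
})

test_that("gametes copy whole chromosomes when recombination is off", {
  set.seed(5)
  ptr <- toy_sim(toy_arch(intergene_recomb = 0, mutation_rate = 0))
  foundersim:::.sim_add_population(ptr, "p", 10, 0L, 0L)
  a1 <- toy_mut(ptr, 1, 100); a2 <- toy_mut(ptr, 1, 5000)
  b1 <- toy_mut(ptr, 2, 100); b2 <- toy_mut(ptr, 2, 7000)
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(a1, b1), c(a2, b2))
  for (i in 1:50) {
    g <- foundersim:::.sim_make_gamete(ptr, "p", 1L, FALSE)
    c1 <- intersect(g, c(a1, a2))
    c2 <- intersect(g, c(b1, b2))
    expect_true(identical(c1, a1) || identical(c1, a2))
    expect_true(identical(c2, b1) || identical(c2, b2))
  }
})

test_that("boundary switching frequency matches the recombination rate", {
  set.seed(6)
  # two genes, one boundary, r = 0.5: marker configurations (both, one, none)
  arch <- toy_arch(n_chromosomes = 1, genes_per_chromosome = 2,
                   intergene_recomb = 0.5)
  ptr <- toy_sim(arch)
  foundersim:::.sim_add_population(ptr, "p", 10, 0L, 0L)
  m1 <- toy_mut(ptr, 1, 100)    # gene 1 on h1
  m2 <- toy_mut(ptr, 1, 1500)   # gene 2 on h1
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(m1, m2), integer())
  n <- 4000
  switched <- logical(n)
  for (i in seq_len(n)) {
    g <- foundersim:::.sim_make_gamete(ptr, "p", 1L, FALSE)
    switched[i] <- length(g) == 1 # exactly one marker = crossover happened
  }
  expect_lt(abs(mean(switched) - 0.5), 4 * sqrt(0.25 / n))
})

test_that("mutations within one gene always co-segregate", {
  set.seed(7)
  arch <- toy_arch(n_chromosomes = 1, genes_per_chromosome = 4,
                   intergene_recomb = 0.5)
  ptr <- toy_sim(arch)
  foundersim:::.sim_add_population(ptr, "p", 10, 0L, 0L)
  m1 <- toy_mut(ptr, 1, 2000) # both in gene 3 ([2000, 3000))
  m2 <- toy_mut(ptr, 1, 2999)
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(m1, m2), integer())
  for (i in 1:3000) {
    g <- foundersim:::.sim_make_gamete(ptr, "p", 1L, FALSE)
    expect_true(length(intersect(g, c(m1, m2))) %in% c(0L, 2L))
  }
})

test_that("new mutations appear only in gametes, alleles are conserved", {
  set.seed(8)
  arch <- toy_arch(mutation_rate = 1e-4) # high rate: ~2 new per gamete
  ptr <- toy_sim(arch)
  foundersim:::.sim_add_population(ptr, "p", 10, 0L, 0L)
  m1 <- toy_mut(ptr, 1, 100); m2 <- toy_mut(ptr, 2, 300)
  foundersim:::.sim_add_individual(ptr, "p", 0L, 3L, c(m1), c(m2))
  n_before <- foundersim:::.sim_n_mutations(ptr)
  saw_new <- FALSE
  for (i in 1:200) {
    g <- foundersim:::.sim_make_gamete(ptr, "p", 1L, TRUE)
    inherited <- g[g < n_before]
    expect_true(all(inherited %in% c(m1, m2)))
    if (any(g >= n_before)) saw_new <- TRUE
  }
  expect_true(saw_new)
})

test_that("reproduction requires eligible sires and dams", {
  lh <- immortal_lh()
  # only females
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 100, replicate(10, list(sex = 0, age = 5, h1 = NULL,
                                            h2 = NULL), simplify = FALSE))
  foundersim:::.sim_reproduce(ptr)
  expect_equal(foundersim:::.sim_census(ptr)$N, 10L)
  # females all age 0 (below first reproduction age)
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 100, c(replicate(10, list(sex = 0, age = 0, h1 = NULL,
                                              h2 = NULL), simplify = FALSE),
                           list(list(sex = 1, age = 5, h1 = NULL, h2 = NULL))))
  foundersim:::.sim_reproduce(ptr)
  expect_equal(foundersim:::.sim_census(ptr)$N, 11L)
  # females beyond the maximum reproductive age
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 100, list(list(sex = 0, age = 14, h1 = NULL, h2 = NULL),
                              list(sex = 1, age = 5, h1 = NULL, h2 = NULL)))
  foundersim:::.sim_reproduce(ptr)
  expect_equal(foundersim:::.sim_census(ptr)$N, 2L)
})

test_that("calves per eligible female match the litter distribution", {
  set.seed(9)
  lh <- immortal_lh()
  nf <- 4000
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 1e6,
          c(replicate(nf, list(sex = 0, age = 5, h1 = NULL, h2 = NULL),
                      simplify = FALSE),
            replicate(50, list(sex = 1, age = 5, h1 = NULL, h2 = NULL),
                      simplify = FALSE)))
  foundersim:::.sim_reproduce(ptr)
  calves <- foundersim:::.sim_census(ptr)$N - nf - 50
  mu <- mean_litter_size(lh)
  sigma <- sqrt(sum((1:8)^2 * lh$litter_probs) - mu^2)
  expect_lt(abs(calves / nf - mu), 4 * sigma / sqrt(nf))
})

test_that("survival composes fitness, age mortality and density dependence", {
  set.seed(10)
  lh <- life_history()
  # age 16 dies with certainty
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 100, replicate(20, list(sex = 0, age = 16, h1 = NULL,
                                            h2 = NULL), simplify = FALSE))
  foundersim:::.sim_survive(ptr)
  expect_equal(foundersim:::.sim_census(ptr)$N, 0L)

  # mutation-free calf with N <= K survives with probability 0.8
  n <- 4000
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", 1e6, replicate(n, list(sex = 0, age = 0, h1 = NULL,
                                           h2 = NULL), simplify = FALSE))
  foundersim:::.sim_survive(ptr)
  surv <- foundersim:::.sim_census(ptr)$N / n
  expect_lt(abs(surv - 0.8), 4 * sqrt(0.8 * 0.2 / n))

  # N = 2K: mutation-free adult aged 5 survives with 0.95 * 0.5
  ptr <- toy_sim(lh = lh)
  toy_pop(ptr, "p", n / 2, replicate(n, list(sex = 0, age = 5, h1 = NULL,
                                             h2 = NULL), simplify = FALSE))
  foundersim:::.sim_survive(ptr)
  surv <- foundersim:::.sim_census(ptr)$N / n
  expect_lt(abs(surv - 0.475), 4 * sqrt(0.475 * 0.525 / n))
})

test_that("survivors age and no one outlives the maximum longevity", {
  set.seed(12)
  ptr <- toy_sim(lh = immortal_lh(max_longevity = 4))
  toy_pop(ptr, "p", 100, replicate(10, list(sex = 0, age = 0, h1 = NULL,
                                            h2 = NULL), simplify = FALSE))
  for (i in 1:6) foundersim:::.sim_survive(ptr)
  ind <- foundersim:::.sim_individuals(ptr, "p")
  expect_equal(nrow(ind), 0L) # all reached age > 4 and were removed
})

test_that("founding copies exact founder genotypes into the island", {
  set.seed(13)
  ptr <- toy_sim(lh = immortal_lh())
  foundersim:::.sim_add_population(ptr, "mainland", 100, 0L, 0L)
  muts <- vapply(1:6, function(i) toy_mut(ptr, 1, i * 137, s = 0), integer(1))
  for (i in 1:10)
    foundersim:::.sim_add_individual(ptr, "mainland", i %% 2, 4L,
                                     sample(muts, 2), sample(muts, 2))
  # founding with k = N copies the whole population: frequencies match exactly
  foundersim:::.sim_found(ptr, "mainland", "island", 10L, 25)
  main <- sample_all(ptr, "mainland", 10L)
  isl <- sample_all(ptr, "island", 10L)
  key <- function(s) paste(s$site$chrom, s$site$pos, sep = ":")
  expect_setequal(key(main), key(isl))
  expect_equal(rowSums(main$geno)[order(key(main))],
               rowSums(isl$geno)[order(key(isl))])
  # island inherits capacity and size
  cen <- foundersim:::.sim_census(ptr)
  expect_equal(cen$N[cen$population == "island"], 10L)
  expect_equal(cen$K[cen$population == "island"], 25)
  # cannot draw more founders than the source holds
  expect_error(foundersim:::.sim_found(ptr, "mainland", "i2", 1000L, 10),
               "cannot draw")
})

test_that("a two-individual founding yields exactly two island founders", {
  set.seed(14)
  ptr <- toy_sim(lh = immortal_lh())
  foundersim:::.sim_add_population(ptr, "mainland", 50, 50L, 5L)
  foundersim:::.sim_found(ptr, "mainland", "island", 2L, 2)
  cen <- foundersim:::.sim_census(ptr)
  expect_equal(cen$N[cen$population == "island"], 2L)
})

test_that("identical seeds give bit-identical time series", {
  sc <- scenario("micro", list(
    demographic_event(30, "found_from_mainland", "island", 10),
    demographic_event(15, "set_capacity", "island", 30)),
    mainland_capacity = 60, burnin_years = 20)
  arch <- genome_architecture(n_chromosomes = 1, genes_per_chromosome = 50,
                              mutation_rate = 1e-6, intergene_recomb = 1e-2)
  run <- function() run_scenario(sc, arch, dfe_spec(), life_history(),
                                 replicates = 2, base_seed = 99,
                                 sample_interval = 10)
  a <- run()
  b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sort(unique(a$population)), c("island", "mainland"))
  # pooled row count: replicates x sampled years x populations (island
  # appears once founded)
  expect_equal(nrow(a), 2 * (4 + 4))
})

test_that("N fluctuates around K and fitness stays in bounds", {
  set.seed(15)
  arch <- toy_arch(mutation_rate = 0)
  ptr <- toy_sim(arch, lh = life_history())
  foundersim:::.sim_add_population(ptr, "p", 300, 300L, 10L)
  Ns <- integer(120)
  for (i in seq_along(Ns)) {
    foundersim:::.sim_reproduce(ptr)
    foundersim:::.sim_survive(ptr)
    cen <- foundersim:::.sim_census(ptr)
    Ns[i] <- cen$N
    expect_equal(cen$mean_fitness, 1) # neutral: fitness exactly 1
  }
  expect_lt(abs(mean(Ns[21:120]) - 300) / 300, 0.15)
})

test_that("deleterious mutation keeps mean fitness in (0, 1]", {
  set.seed(16)
  arch <- toy_arch(mutation_rate = 1e-5)
  ptr <- toy_sim(arch, dfe_spec(), life_history())
  foundersim:::.sim_add_population(ptr, "p", 150, 150L, 10L)
  for (i in 1:40) {
    foundersim:::.sim_reproduce(ptr)
    foundersim:::.sim_survive(ptr)
  }
  w <- foundersim:::.sim_census(ptr)$mean_fitness
  expect_true(w > 0 && w <= 1)
  expect_lt(w, 1) # load has accumulated at this mutation rate
})

test_that("fixation compaction leaves summaries unchanged", {
  set.seed(17)
  ptr <- toy_sim(toy_arch())
  foundersim:::.sim_add_population(ptr, "p", 50, 0L, 0L)
  fix <- toy_mut(ptr, 1, 100, s = -0.05, h = 0.01, cat = 3)
  seg <- toy_mut(ptr, 1, 900, s = -0.2, h = 0, cat = 4)
  for (i in 1:6)
    foundersim:::.sim_add_individual(ptr, "p", i %% 2, 4L,
                                     c(fix, if (i <= 3) seg), c(fix))
  before <- sample_all(ptr, "p")
  stats_before <- c(realized_load(before), masked_load(before),
                    sim_heterozygosity(before), category_counts(before))
  foundersim:::.sim_compact(ptr)
  after <- sample_all(ptr, "p")
  expect_equal(nrow(after$fixed), 1L) # 'fix' moved to the fixed list
  stats_after <- c(realized_load(after), masked_load(after),
                   sim_heterozygosity(after), category_counts(after))
  expect_equal(stats_after, stats_before)
  # fitness of later-built individuals includes the fixed product
  foundersim:::.sim_add_individual(ptr, "p", 0L, 4L, integer(), integer())
  ind <- foundersim:::.sim_individuals(ptr, "p")
  expect_equal(ind$fitness[nrow(ind)], 1 - 0.05)
})
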