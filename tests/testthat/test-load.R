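# Load accounting: per-individual counts, deleterious:synonymous ratios,
# R_xy with intergenic standardisation, and hard variant filters.

test_that("count_load follows the counting rule", {
  geno <- rbind(c(2L, 0L, 1L, 2L), # HIGH
                c(1L, 1L, 0L, 2L), # HIGH
                c(0L, 2L, 2L, 2L), # HIGH
                c(NA, 1L, 1L, 0L), # HIGH
                c(1L, 0L, 0L, 1L)) # SYNONYMOUS
  vt <- toy_vt(geno, c(rep("HIGH", 4), "SYNONYMOUS"))
  out <- count_load(vt, "popA", "HIGH")
  # individual 1: genotypes {2, 1, 0, NA} -> hom 1, het 1, total 2, alleles 3
  expect_equal(out$n_hom[1], 1)
  expect_equal(out$n_het[1], 1)
  expect_equal(out$n_total_variants[1], 2)
  expect_equal(out$n_alleles[1], 3)
  expect_error(count_load(vt, "nosuch", "HIGH"), "unknown population")
})

test_that("drop_fixed removes sites fixed across all populations", {
  geno <- rbind(c(2L, 2L, 2L, 2L),   # fixed everywhere
                c(2L, 2L, NA, 2L),   # fixed among non-missing
                c(2L, 2L, 1L, 2L))   # still segregating
  vt <- toy_vt(geno, rep("HIGH", 3))
  kept <- count_load(vt, "popA", "HIGH", drop_fixed = TRUE)
  expect_equal(kept$n_total_variants, c(1, 1)) # only the third site remains
  all_sites <- count_load(vt, "popA", "HIGH")
  expect_equal(all_sites$n_total_variants, c(3, 3))
})

test_that("count_load matches brute force and is additive over site subsets", {
  set.seed(41)
  geno <- matrix(sample(c(0:2, NA), 10 * 6, TRUE, prob = c(.4, .3, .2, .1)),
                 10, 6)
  geno[rowSums(!is.na(geno)) == 0, 1] <- 0L
  cats <- sample(c("HIGH", "SYNONYMOUS"), 10, TRUE)
  vt <- toy_vt(geno, cats, populations = rep(c("popA", "popB"), each = 3))
  out <- count_load(vt, "popB", "HIGH")
  for (j in 1:3) {
    ref <- load_brute(geno[cats == "HIGH", 3 + j])
    expect_equal(out$n_hom[j], unname(ref["n_hom"]))
    expect_equal(out$n_het[j], unname(ref["n_het"]))
    expect_equal(out$n_alleles[j], unname(ref["n_alleles"]))
  }
  # additivity: HIGH + SYNONYMOUS totals = totals over all sites
  tot <- count_load(vt, "popB", "HIGH")$n_total_variants +
    count_load(vt, "popB", "SYNONYMOUS")$n_total_variants
  ref_tot <- vapply(4:6, function(j) unname(load_brute(geno[, j])["n_total"]),
                    numeric(1))
  expect_equal(tot, ref_tot)
})

test_that("load ratios normalise by the synonymous count", {
  # 5 HIGH and 50 SYNONYMOUS variants -> 0.1
  geno <- matrix(0L, 55, 2)
  geno[1:55, 1] <- 1L
  vt <- toy_vt(geno, c(rep("HIGH", 5), rep("SYNONYMOUS", 50)),
               populations = c("popA", "popB"))
  r <- load_ratio(vt, "popA", "HIGH")
  expect_equal(r$ratio, 0.1)
  # equal counts -> 1; zero synonymous -> NA with warning
  expect_warning(r2 <- load_ratio(vt, "popB", "HIGH"), "zero synonymous")
  expect_true(is.na(r2$ratio))
  # 3-individual toy vs hand computation
  g3 <- rbind(c(1L, 2L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(2L, 2L, 1L))
  vt3 <- variant_table(rep(1L, 4), 1:4 * 10,
                       c("MODERATE", "MODERATE", "SYNONYMOUS", "SYNONYMOUS"),
                       g3, rep("p1", 3))
  r3 <- load_ratio(vt3, "p1", "MODERATE")
  # ind 1: 2 moderate (het, het) over 1 synonymous (0/0, hom alt) -> 2, etc.
  expect_equal(r3$ratio, c(2, 1 / 2, 1 / 2))
})

test_that("R_xy identities: self-comparison, reciprocity, hand oracle", {
  set.seed(42)
  ns <- 400
  geno_half <- matrix(rbinom(ns * 8, 2, 0.3), ns, 8)
  geno <- cbind(geno_half, geno_half) # two populations, identical genotypes
  cats <- sample(c("HIGH", "INTERGENIC"), ns, TRUE, prob = c(0.3, 0.7))
  vt <- toy_vt(geno, cats)
  r <- rxy(vt, "popA", "popB", "HIGH", seed = 1)
  expect_equal(r$point_estimate, 1.0)

  # reciprocity with the same standardisation seed is exact
  set.seed(43)
  geno2 <- matrix(rbinom(ns * 16, 2, runif(ns)), ns, 16)
  vt2 <- toy_vt(geno2, cats)
  rxy_ab <- rxy(vt2, "popA", "popB", "HIGH", seed = 7)
  rxy_ba <- rxy(vt2, "popB", "popA", "HIGH", seed = 7)
  expect_equal(rxy_ab$point_estimate * rxy_ba$point_estimate, 1.0)

  # 4-site toy evaluated by hand from the L sums
  mk <- function(f, n = 10) { # exact derived counts for n diploids
    cnt <- as.integer(round(f * 2 * n))
    vapply(seq_len(n), function(i) min(2L, max(0L, cnt - 2L * (i - 1L))),
           integer(1))
  }
  fx <- c(0.8, 0.2); fy <- c(0.2, 0.8); fn <- c(0.5, 0.5)
  gx <- rbind(mk(fx[1]), mk(fx[2]), mk(fn[1]), mk(fn[2]))
  gy <- rbind(mk(fy[1]), mk(fy[2]), mk(fn[1]), mk(fn[2]))
  vt4 <- toy_vt(cbind(gx, gy), c("HIGH", "HIGH", "INTERGENIC", "INTERGENIC"),
                populations = rep(c("popA", "popB"), each = 10))
  r4 <- suppressWarnings(rxy(vt4, "popA", "popB", "HIGH", n_blocks = 2,
                             seed = 1)) # 4-site toy: some blocks degenerate
  lxy <- sum(fx * (1 - fy)); lyx <- sum(fy * (1 - fx))
  lnxy <- sum(fn * (1 - fn)); lnyx <- lnxy
  expect_equal(r4$point_estimate, (lxy / lnxy) / (lyx / lnyx))
})

test_that("R_xy is invariant to site order and refuses thin standardisation", {
  set.seed(44)
  ns <- 300
  geno <- matrix(rbinom(ns * 10, 2, 0.3), ns, 10)
  cats <- c(rep("HIGH", 100), rep("INTERGENIC", 200))
  pos <- sort(sample.int(1e6, ns))
  vt <- variant_table(rep(1L, ns), pos, cats, geno,
                      rep(c("popA", "popB"), each = 5))
  perm <- sample.int(ns)
  vtp <- variant_table(rep(1L, ns), pos[perm], cats[perm],
                       geno[perm, , drop = FALSE],
                       rep(c("popA", "popB"), each = 5))
  a <- rxy(vt, "popA", "popB", "HIGH", seed = 3)
  b <- rxy(vtp, "popA", "popB", "HIGH", seed = 3)
  expect_equal(a$point_estimate, b$point_estimate)

  vt_thin <- toy_vt(matrix(rbinom(40, 2, .5), 10, 4),
                    c(rep("HIGH", 8), "INTERGENIC", "INTERGENIC"))
  expect_error(rxy(vt_thin, "popA", "popB", "HIGH"), "refused")
})

test_that("R_xy detects planted frequency deficits with jackknife support", {
  spec0 <- synth_spec(sites_per_category = c(HIGH = 300, MODERATE = 300,
                                             SYNONYMOUS = 300,
                                             INTERGENIC = 2500),
                      samples_per_pop = 15, rxy_deficit = 1, seed = 101)
  null_tab <- generate_table(spec0)$table
  r0 <- rxy(null_tab, "pop1", "pop2", "HIGH", seed = 5)
  expect_lt(abs(r0$point_estimate - 1), 3 * r0$jackknife_se)
  expect_gt(r0$jackknife_se, 0)

  # changing the standardisation seed moves R_xy by less than 3 SEs
  r0b <- rxy(null_tab, "pop1", "pop2", "HIGH", seed = 77)
  expect_lt(abs(r0b$point_estimate - r0$point_estimate),
            3 * r0$jackknife_se)

  # directional power: deficit in pop1 pushes R_xy below 1
  for (sd in c(201, 202, 203)) {
    spec1 <- synth_spec(sites_per_category = c(HIGH = 300, MODERATE = 300,
                                               SYNONYMOUS = 300,
                                               INTERGENIC = 2500),
                        samples_per_pop = 15, rxy_deficit = 0.4,
                        deficit_categories = "HIGH", seed = sd)
    tab1 <- generate_table(spec1)$table
    r1 <- rxy(tab1, "pop1", "pop2", "HIGH", seed = 5)
    expect_lt(r1$point_estimate, 1)
  }
})

test_that("hard filters follow the depth, quality, balance and indel rules", {
  # 12-record fixture audited rule by rule; two samples, mean depth 20
  geno <- matrix(c(1L, 1L,  # site 1: balance fail for sample 1
                   1L, 0L,  # site 2: depth too low for sample 1
                   0L, 2L,  # site 3: indel
                   1L, 1L,  # site 4: SNP 3 bp from the indel
                   0L, 1L,  # site 5: low qual
                   1L, 2L,  # site 6: clean
                   2L, 0L,  # site 7: depth too high for sample 2
                   1L, 1L,  # site 8: balance fail both -> dropped entirely
                   0L, 0L,  # site 9: clean
                   1L, 0L,  # site 10: clean het balance 0.5
                   2L, 2L,  # site 11: clean
                   0L, 1L), # site 12: SNP 6 bp from indel -> kept
                 nrow = 12, byrow = TRUE)
  pos <- c(100, 200, 300, 303, 400, 500, 600, 700, 800, 900, 1000, 306)
  dp <- matrix(20, 12, 2)
  dp[2, 1] <- 5       # < 20/3
  dp[7, 2] <- 45      # > 2 * 20
  ad <- matrix(10, 12, 2)
  ad[geno == 0L] <- 20
  ad[geno == 2L] <- 0
  ad[1, 1] <- 2       # balance 0.1
  ad[8, ] <- c(19, 19) # balance 0.95 at a het in both samples
  qual <- rep(60, 12); qual[5] <- 20
  is_indel <- rep(FALSE, 12); is_indel[3] <- TRUE
  vt <- variant_table(rep(1L, 12), pos, rep("SYNONYMOUS", 12), geno,
                      c("popA", "popB"), qual = qual, is_indel = is_indel,
                      dp = dp, ad_ref = ad)
  out <- filter_variants(vt, mean_depth = c(20, 20))
  # dropped sites: 3 (indel), 4 (within 5 bp), 5 (qual), 8 (no calls left)
  expect_setequal(out$site$pos, c(100, 200, 500, 600, 800, 900, 1000, 306))
  # genotype-level removals became missing
  expect_true(is.na(out$geno[out$site$pos == 100, 1]))
  expect_true(is.na(out$geno[out$site$pos == 200, 1]))
  expect_true(is.na(out$geno[out$site$pos == 600, 2]))
  # untouched genotypes survive
  expect_equal(out$geno[out$site$pos == 900, ], c(popA_s1 = 1L, popB_s1 = 0L),
               ignore_attr = TRUE)
  # complete-cases drops any site with a missing genotype
  cc <- filter_variants(vt, mean_depth = c(20, 20), complete_cases = TRUE)
  expect_setequal(cc$site$pos, c(500, 800, 900, 1000, 306))
  # missing auxiliary fields are reported by name
  vt$dp <- NULL
  expect_error(filter_variants(vt), "'dp'")
})
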