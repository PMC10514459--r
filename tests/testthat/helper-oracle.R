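# Independent oracles used by the tests. These deliberately re-derive results
# with the most naive algorithms available (explicit loops, genotype-matrix
# bookkeeping) and stay independent of the package's implementation paths.

# --- brute-force diploid Wright-Fisher simulator (neutral) -------------------
# N diploids with separate sexes, discrete generations; each offspring draws
# a mother and a father uniformly; one gamete per parent with free
# recombination between genes and Poisson(mu * L) new mutations. Returns the
# mean per-individual heterozygous site count over the recorded window.
wf_brute_heterozygosity <- function(N, n_genes, gene_len, mu, generations,
                                    record_from) {
  L <- n_genes * gene_len
  # haplotypes: matrix sites x 2N (grown as mutations arise)
  hap <- matrix(0L, nrow = 0, ncol = 2 * N)
  gene_of <- integer(0)
  sex <- sample(rep(c(0L, 1L), length.out = N))
  het_rec <- numeric(0)
  for (gen in seq_len(generations)) {
    moms <- which(sex == 0)
    dads <- which(sex == 1)
    newhap <- matrix(0L, nrow = nrow(hap), ncol = 2 * N)
    new_rows <- list()
    for (i in seq_len(N)) {
      for (p in 1:2) {
        par <- if (p == 1) moms[sample.int(length(moms), 1)]
               else dads[sample.int(length(dads), 1)]
        cols <- c(2 * par - 1, 2 * par)
        gam <- integer(nrow(hap))
        if (nrow(hap) > 0) {
          pick <- sample(1:2, n_genes, replace = TRUE) # free recombination
          use <- cols[pick[gene_of]]
          gam <- hap[cbind(seq_len(nrow(hap)), use)]
        }
        nm <- rpois(1, mu * L)
        if (nm > 0)
          new_rows[[length(new_rows) + 1]] <-
            list(col = 2 * i - 2 + p, gene = sample.int(n_genes, nm,
                                                        replace = TRUE))
        newhap[, 2 * i - 2 + p] <- gam
      }
    }
    if (length(new_rows)) {
      extra_n <- sum(vapply(new_rows, function(r) length(r$gene), integer(1)))
      add <- matrix(0L, nrow = extra_n, ncol = 2 * N)
      genes <- integer(extra_n)
      k <- 0
      for (r in new_rows) {
        for (g in r$gene) {
          k <- k + 1
          add[k, r$col] <- 1L
          genes[k] <- g
        }
      }
      newhap <- rbind(newhap, add)
      gene_of <- c(gene_of, genes)
    }
    hap <- newhap
    keep <- rowSums(hap) > 0 & rowSums(hap) < 2 * N
    hap <- hap[keep, , drop = FALSE]
    gene_of <- gene_of[keep]
    sex <- sample(rep(c(0L, 1L), length.out = N))
    if (gen >= record_from) {
      het <- vapply(seq_len(N), function(i)
        sum(hap[, 2 * i - 1] != hap[, 2 * i]), numeric(1))
      het_rec <- c(het_rec, mean(het))
    }
  }
  mean(het_rec)
}

# --- regularized-incomplete-gamma masses of the deleterious bins -------------
gamma_bin_masses <- function(dfe, cuts = c(0.1, 0.01, 0.001)) {
  shape <- dfe$gamma_shape
  scale <- abs(dfe$gamma_mean_s) / shape
  p <- pgamma(cuts, shape = shape, scale = scale)
  c(very_strong = 1 - p[1], strong = p[1] - p[2],
    moderate = p[2] - p[3], weak = p[3])
}

# --- naive sliding-window ROH evaluator --------------------------------------
# direct loop translation of the window rules, O(n * W); no cumulative sums.
roh_brute <- function(genotypes, positions, p) {
  n <- length(genotypes)
  W <- p$window_snp
  if (n < W) return(NULL)
  het <- ifelse(is.na(genotypes), 0L, as.integer(genotypes == 1L))
  win_hom <- logical(n - W + 1)
  for (j in seq_len(n - W + 1))
    win_hom[j] <- sum(het[j:(j + W - 1)]) <= p$window_het_max
  qual <- logical(n)
  for (i in seq_len(n)) {
    js <- max(1, i - W + 1):min(i, n - W + 1)
    qual[i] <- mean(win_hom[js]) >= p$window_threshold
  }
  segs <- list()
  i <- 1
  while (i <= n) {
    if (!qual[i]) { i <- i + 1; next }
    j <- i
    while (j < n && qual[j + 1] &&
           positions[j + 1] - positions[j] <= p$gap_kb * 1000) j <- j + 1
    len <- positions[j] - positions[i] + 1
    nh <- sum(het[i:j])
    ok <- (j - i + 1) >= p$min_snp && len >= p$min_kb * 1000 &&
      len / 1000 / (j - i + 1) <= p$density_kb_per_snp &&
      nh <= p$segment_het_max
    if (ok)
      segs[[length(segs) + 1]] <- data.frame(start = positions[i],
                                             end = positions[j],
                                             n_snps = j - i + 1, n_het = nh,
                                             length = len)
    i <- j + 1
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

# --- brute-force load counting ----------------------------------------------
load_brute <- function(geno_col) {
  g <- geno_col[!is.na(geno_col)]
  c(n_hom = sum(g == 2), n_het = sum(g == 1),
    n_total = sum(g == 2) + sum(g == 1),
    n_alleles = 2 * sum(g == 2) + sum(g == 1))
}

# --- brute-force fitness / load on enumerated genotypes ----------------------
fitness_brute <- function(g, s, h) {
  w <- 1
  for (i in seq_along(g)) {
    if (g[i] == 2) w <- w * (1 + s[i])
    else if (g[i] == 1) w <- w * (1 + h[i] * s[i])
  }
  max(w, 0)
}

# per-bp Jaccard between detected and planted tracts on one chromosome
jaccard_bp <- function(det_start, det_end, tr_start, tr_end, chrom_bp) {
  x <- logical(chrom_bp)
  y <- logical(chrom_bp)
  for (i in seq_along(det_start)) x[det_start[i]:det_end[i]] <- TRUE
  y[tr_start:tr_end] <- TRUE
  sum(x & y) / sum(x | y)
}
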