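# Per-sample summary statistics computed on sampled simulator states:
# heterozygosity, F_ROH over the gene map, realized and masked load, and
# per-category deleterious allele counts.

#' Sampled simulator state
#'
#' A `sim_sample` holds the diploid genotypes of a sample of individuals at
#' the union of mutations they carry, plus the population's fixed
#' (monomorphic derived) mutations. `geno` is an integer matrix, sites in
#' rows (0/1/2 derived copies), individuals in columns. `site` and `fixed`
#' are data.frames with columns `chrom`, `pos` (0-based bp within the
#' chromosome), `s`, `h` and `category` (one of neutral, weak, moderate,
#' strong, very_strong).
#'
#' @param geno integer matrix of derived-allele dosages, sites x individuals.
#' @param site data.frame describing the rows of `geno`.
#' @param fixed data.frame of fixed mutations (zero-row default).
#' @param chrom_len chromosome length in bp.
#' @param n_chrom number of chromosomes.
#' @return an object of class `sim_sample`.
#' @export
sim_sample <- function(geno, site, fixed = NULL, chrom_len, n_chrom) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(site))
    stop("geno and site must have one row per mutation")
  if (is.null(fixed))
    fixed <- data.frame(chrom = integer(), pos = integer(), s = numeric(),
                        h = numeric(), category = factor(character(),
                                                         levels = .category_levels))
  for (d in list(site, fixed))
    stopifnot(all(c("chrom", "pos", "s", "h", "category") %in% names(d)))
  structure(list(geno = geno, site = site, fixed = fixed,
                 n = ncol(geno), chrom_len = as.numeric(chrom_len),
                 n_chrom = as.integer(n_chrom),
                 genome_bp = as.numeric(chrom_len) * n_chrom),
            class = "sim_sample")
}

# convert the raw C++ list into a sim_sample
.as_sim_sample <- function(raw) {
  mk <- function(l) data.frame(chrom = l$chrom, pos = l$pos, s = l$s,
                               h = l$h,
                               category = factor(.category_levels[l$category + 1L],
                                                 levels = .category_levels))
  out <- sim_sample(raw$geno, mk(raw$site), mk(raw$fixed),
                    chrom_len = raw$chrom_len, n_chrom = raw$n_chrom)
  out$age <- raw$age
  out$sex <- raw$sex
  out
}

#' Draw a sampled state from a live simulation
#'
#' @param state a `sim_state` from [init_mainland()].
#' @param population population label.
#' @param n sample size (whole population if N < n).
#' @return a [sim_sample()].
#' @export
sample_population <- function(state, population, n = 30L) {
  stopifnot(inherits(state, "sim_state"))
  .as_sim_sample(.sim_sample_state(state$ptr, population, as.integer(n)))
}

#' @export
print.sim_sample <- function(x, ...) {
  cat("<sim_sample>", x$n, "individuals,", nrow(x$geno),
      "segregating records,", nrow(x$fixed), "fixed,",
      format(x$genome_bp, big.mark = ","), "bp\n")
  invisible(x)
}

# rows of the genotype matrix that segregate within the sample
.segregating <- function(sample) {
  g <- sample$geno
  !(rowSums(g == 0L) == ncol(g) | rowSums(g == 2L) == ncol(g))
}

#' Mean heterozygosity of a sampled state, per 1,000 bp
#'
#' Mean over individuals of the number of heterozygous sites divided by the
#' total simulated sequence length, times 1,000.
#'
#' @param sample a [sim_sample()].
#' @return heterozygous sites per kb (scalar).
#' @export
sim_heterozygosity <- function(sample) {
  stopifnot(inherits(sample, "sim_sample"))
  if (sample$n == 0) stop("empty sample")
  mean(colSums(sample$geno == 1L)) / sample$genome_bp * 1000
}

#' Mean F_ROH of a sampled state
#'
#' Runs of homozygosity are defined against the sites segregating within the
#' sample (monomorphic stretches carry no information, mirroring what
#' SNP-based empirical F_ROH can see): for one individual, a run is a
#' maximal stretch of the physical map containing no heterozygous
#' segregating site. A run is bounded by the individual's flanking
#' heterozygous sites (exclusive) or by the chromosome ends, and its length
#' is the enclosed bp. F_ROH is the summed length of runs of at least
#' `min_len` bp divided by the genome length; the sample mean is returned.
#'
#' @param sample a [sim_sample()].
#' @param min_len minimum tract length in bp (default 0.1 Mb).
#' @return mean F_ROH (scalar).
#' @export
sim_froh <- function(sample, min_len = 1e5) {
  stopifnot(inherits(sample, "sim_sample"))
  seg <- .segregating(sample)
  g <- sample$geno[seg, , drop = FALSE]
  chrom <- sample$site$chrom[seg]
  pos <- sample$site$pos[seg]
  vapply(seq_len(sample$n), function(j) {
    tot <- 0
    for (c in seq_len(sample$n_chrom)) {
      idx <- chrom == c
      het <- pos[idx][g[idx, j] == 1L]
      bounds <- c(-1, sort(het), sample$chrom_len)
      runs <- diff(bounds) - 1
      tot <- tot + sum(runs[runs >= min_len])
    }
    tot / sample$genome_bp
  }, numeric(1)) |> mean()
}

#' Fitness of diploid genotypes
#'
#' Multiplicative fitness over sites:
#' `W = prod (1 + s)^{hom} * (1 + h s)^{het}`, floored at 0.
#'
#' @param g integer vector of derived dosages (0/1/2) across sites.
#' @param s,h selection and dominance coefficients per site.
#' @return fitness in `[0, 1]` (for non-positive `s`).
#' @export
genotype_fitness <- function(g, s, h) {
  w <- prod((1 + s)[g == 2L]) * prod((1 + h * s)[g == 1L])
  max(w, 0)
}

#' Mean realized genetic load of a sampled state
#'
#' One minus the sample mean of individual fitness, with fixed deleterious
#' mutations included in the fitness product: the fitness reduction due to
#' segregating and fixed deleterious variation.
#'
#' @param sample a [sim_sample()].
#' @return realized load (scalar).
#' @export
realized_load <- function(sample) {
  stopifnot(inherits(sample, "sim_sample"))
  wfix <- prod(1 + sample$fixed$s)
  w <- vapply(seq_len(sample$n), function(j)
    genotype_fitness(sample$geno[, j], sample$site$s, sample$site$h) * wfix,
    numeric(1))
  1 - mean(pmax(pmin(w, 1), 0))
}

#' Mean masked genetic load of a sampled state
#'
#' The additional fitness loss that would be expressed if every heterozygous
#' deleterious site were made homozygous: per individual
#' `W_masked = prod over het deleterious sites (1 + s) / (1 + h s)`, and the
#' masked load is `1 - mean(W_masked)` — the recessive deleterious variation
#' currently concealed in heterozygotes.
#'
#' @param sample a [sim_sample()].
#' @return masked load (scalar).
#' @export
masked_load <- function(sample) {
  stopifnot(inherits(sample, "sim_sample"))
  s <- sample$site$s
  h <- sample$site$h
  w <- vapply(seq_len(sample$n), function(j) {
    het <- sample$geno[, j] == 1L & s < 0
    prod((1 + s[het]) / (1 + h[het] * s[het]))
  }, numeric(1))
  1 - mean(w)
}

#' Mean derived-allele count per individual by selection category
#'
#' Allele counting: homozygous sites contribute 2, heterozygous sites 1;
#' fixed mutations contribute 2 per individual. Returns the sample mean per
#' deleterious category.
#'
#' @param sample a [sim_sample()].
#' @return named numeric vector (weak, moderate, strong, very_strong).
#' @export
category_counts <- function(sample) {
  stopifnot(inherits(sample, "sim_sample"))
  bins <- setdiff(.category_levels, "neutral")
  alleles <- (sample$geno == 2L) * 2L + (sample$geno == 1L)
  out <- vapply(bins, function(b) {
    rows <- sample$site$category == b
    mean(colSums(alleles[rows, , drop = FALSE])) +
      2 * sum(sample$fixed$category == b)
  }, numeric(1))
  setNames(out, bins)
}
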