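# Genetic-load accounting on annotated variant tables: per-individual
# impact-category counts, deleterious:synonymous ratios, the R_xy statistic
# with intergenic standardisation and block-jackknife variance, and the
# hard genotype filters.

#' Annotated multi-population variant table
#'
#' Sites x samples derived-allele dosages with one impact category per site
#' (HIGH, MODERATE, SYNONYMOUS or INTERGENIC; the ALT allele is the derived
#' allele, polarised upstream) and one population label per sample.
#' Optional per-genotype auxiliary matrices (`dp`, `ad_ref`) and per-site
#' fields (`qual`, `is_indel`) support [filter_variants()].
#'
#' @param chrom,pos site coordinates (pos 1-based).
#' @param category impact category per site.
#' @param geno integer dosage matrix (0/1/2, NA = missing), sites x samples.
#' @param populations population label per sample.
#' @param samples sample names (default from `geno` columns).
#' @param qual per-site base quality (optional).
#' @param is_indel per-site indel flag (optional).
#' @param dp,ad_ref per-genotype depth and reference-allele depth matrices
#'   (optional).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, category, geno, populations,
                          samples = NULL, qual = NULL, is_indel = NULL,
                          dp = NULL, ad_ref = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ns <- nrow(geno)
  if (length(chrom) != ns || length(pos) != ns || length(category) != ns)
    stop("chrom, pos and category must have one entry per site")
  category <- factor(as.character(category), levels = .impact_levels)
  if (anyNA(category))
    stop("impact categories must be one of ",
         paste(.impact_levels, collapse = ", "))
  if (length(populations) != ncol(geno))
    stop("populations must have one entry per sample")
  if (is.null(samples))
    samples <- colnames(geno) %||% sprintf("sample%02d", seq_len(ncol(geno)))
  colnames(geno) <- samples
  ok <- geno %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(rowSums(!is.na(geno)) == 0))
    stop("each site must have at least one non-missing genotype")
  vt <- list(site = data.frame(chrom = chrom, pos = pos, category = category),
             geno = geno, samples = samples,
             populations = as.character(populations),
             qual = qual, is_indel = is_indel, dp = dp, ad_ref = ad_ref)
  class(vt) <- "variant_table"
  vt
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table>", nrow(x$geno), "sites x", ncol(x$geno), "samples;",
      "populations:", paste(unique(x$populations), collapse = ", "), "\n")
  print(table(x$site$category))
  invisible(x)
}

.check_pop <- function(vt, pop) {
  if (!pop %in% vt$populations)
    stop("unknown population '", pop, "'")
  which(vt$populations == pop)
}

# sites where every non-missing genotype across ALL populations is hom-derived
.fixed_sites <- function(vt) {
  rowSums(vt$geno != 2L, na.rm = TRUE) == 0
}

#' Per-individual load counts for one impact category
#'
#' For every individual of a population: the number of homozygous-derived
#' sites (`n_hom`), heterozygous sites (`n_het`), their sum
#' (`n_total_variants`) and the derived allele count
#' (`n_alleles = 2 n_hom + n_het`), over sites of the requested category.
#' With `drop_fixed`, sites fixed (homozygous derived in every non-missing
#' individual of every population) are excluded first.
#'
#' @param vt a [variant_table()].
#' @param pop population label.
#' @param category impact category.
#' @param drop_fixed exclude sites fixed across all populations.
#' @return data.frame with one row per individual.
#' @export
count_load <- function(vt, pop, category = c("HIGH", "MODERATE",
                                             "SYNONYMOUS", "INTERGENIC"),
                       drop_fixed = FALSE) {
  category <- match.arg(category)
  cols <- .check_pop(vt, pop)
  rows <- vt$site$category == category
  if (drop_fixed) rows <- rows & !.fixed_sites(vt)
  g <- vt$geno[rows, cols, drop = FALSE]
  n_hom <- colSums(g == 2L, na.rm = TRUE)
  n_het <- colSums(g == 1L, na.rm = TRUE)
  data.frame(sample = vt$samples[cols], population = pop,
             category = category, n_hom = n_hom, n_het = n_het,
             n_total_variants = n_hom + n_het,
             n_alleles = 2L * n_hom + n_het, row.names = NULL)
}

#' Deleterious-to-synonymous load ratio per individual
#'
#' The per-individual count of HIGH (or MODERATE) impact variants divided by
#' the synonymous count — the ratio normalisation that controls mapping and
#' reference-distance batch effects.
#'
#' @param vt a [variant_table()].
#' @param pop population label.
#' @param category `"HIGH"` or `"MODERATE"`.
#' @param drop_fixed exclude sites fixed across all populations.
#' @return data.frame with per-individual counts and `ratio` (NA with a
#'   warning for individuals without synonymous variants).
#' @export
load_ratio <- function(vt, pop, category = c("HIGH", "MODERATE"),
                       drop_fixed = FALSE) {
  category <- match.arg(category)
  num <- count_load(vt, pop, category, drop_fixed)
  den <- count_load(vt, pop, "SYNONYMOUS", drop_fixed)
  ratio <- num$n_total_variants / den$n_total_variants
  bad <- den$n_total_variants == 0
  if (any(bad)) {
    warning(sum(bad), " individual(s) with zero synonymous variants; ",
            "ratio undefined (NA)")
    ratio[bad] <- NA_real_
  }
  data.frame(sample = num$sample, population = pop, category = category,
             n_category = num$n_total_variants,
             n_synonymous = den$n_total_variants, ratio = ratio)
}

# derived-allele frequency per site from non-missing genotypes of given columns
.daf <- function(geno, cols) {
  g <- geno[, cols, drop = FALSE]
  rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
}

#' R_xy: relative derived-allele-frequency burden of a variant category
#'
#' For site set S, `L_xy(S) = sum_i f_i^x (1 - f_i^y)` accumulates derived
#' alleles present in population x weighted by their absence in y. R_xy for
#' category C is the double ratio
#' `(L_xy(C) / L_xy(N)) / (L_yx(C) / L_yx(N))`, where N is a random set of
#' intergenic sites of the same size as C — the intergenic standardisation
#' that absorbs sampling and substructure effects. R_xy < 1 means a frequency
#' deficit of category-C derived alleles in x relative to y.
#'
#' The variance is a delete-one block jackknife over `n_blocks` contiguous
#' genomic blocks of equal site count (C and N jointly), which respects
#' linkage. Jackknife replicates with a zero L term are dropped with a
#' warning.
#'
#' @param vt a [variant_table()].
#' @param pop_x,pop_y population labels.
#' @param category impact category to test (`"HIGH"` or `"MODERATE"`).
#' @param n_blocks jackknife blocks (default 50).
#' @param seed seed for the intergenic standardisation draw (the same seed
#'   gives the same standardisation set for both orientations, making
#'   `R_yx = 1 / R_xy` exact).
#' @param drop_fixed exclude sites fixed across all populations.
#' @return an `rxy_result`: list with `point_estimate`, `jackknife_se`,
#'   `blocks`, `category`, `pop_x`, `pop_y`.
#' @export
rxy <- function(vt, pop_x, pop_y, category = c("HIGH", "MODERATE"),
                n_blocks = 50L, seed = NULL, drop_fixed = FALSE) {
  category <- match.arg(category)
  cx <- .check_pop(vt, pop_x)
  cy <- .check_pop(vt, pop_y)
  keep <- !logical(nrow(vt$geno))
  if (drop_fixed) keep <- !.fixed_sites(vt)
  C <- which(vt$site$category == category & keep)
  I <- which(vt$site$category == "INTERGENIC" & keep)
  # genomic order makes the standardisation draw invariant to row order
  C <- C[order(vt$site$chrom[C], vt$site$pos[C])]
  I <- I[order(vt$site$chrom[I], vt$site$pos[I])]
  if (length(I) < length(C))
    stop("fewer intergenic sites (", length(I), ") than ", category,
         " sites (", length(C), "); R_xy without intergenic ",
         "standardisation is refused")
  N <- with_seed(seed, sort(sample(I, length(C))))
  fx <- .daf(vt$geno, cx)
  fy <- .daf(vt$geno, cy)
  lterms <- function(sites) {
    c(xy = sum(fx[sites] * (1 - fy[sites])),
      yx = sum(fy[sites] * (1 - fx[sites])))
  }
  ratio <- function(lc, ln) (lc[["xy"]] / ln[["xy"]]) / (lc[["yx"]] / ln[["yx"]])
  point <- ratio(lterms(C), lterms(N))

  # contiguous equal-site-count blocks along the genome, C and N jointly
  all_sites <- c(C, N)
  memb <- c(rep(1L, length(C)), rep(2L, length(N)))
  ord <- order(vt$site$chrom[all_sites], vt$site$pos[all_sites])
  all_sites <- all_sites[ord]
  memb <- memb[ord]
  n_blocks <- min(as.integer(n_blocks), length(all_sites))
  block <- ceiling(seq_along(all_sites) / (length(all_sites) / n_blocks))
  reps <- numeric(0)
  dropped <- 0L
  for (b in seq_len(n_blocks)) {
    inb <- block == b
    Cb <- setdiff(C, all_sites[inb & memb == 1L])
    Nb <- setdiff(N, all_sites[inb & memb == 2L])
    lc <- lterms(Cb)
    ln <- lterms(Nb)
    if (any(c(lc, ln) == 0)) { dropped <- dropped + 1L; next }
    reps <- c(reps, ratio(lc, ln))
  }
  if (dropped > 0)
    warning(dropped, " jackknife replicate(s) dropped (zero L term)")
  B <- length(reps)
  se <- if (B > 1) sqrt((B - 1) / B * sum((reps - mean(reps))^2)) else NA_real_
  structure(list(category = category, pop_x = pop_x, pop_y = pop_y,
                 point_estimate = point, jackknife_se = se, blocks = B,
                 n_sites = length(C)),
            class = "rxy_result")
}

#' @export
print.rxy_result <- function(x, ...) {
  cat(sprintf("R_xy[%s] (%s vs %s) = %.4f  (jackknife SE %.4f, %d blocks, %d sites)\n",
              x$category, x$pop_x, x$pop_y, x$point_estimate,
              x$jackknife_se, x$blocks, x$n_sites))
  invisible(x)
}

#' Hard genotype and site filters for called variants
#'
#' Applies the standard hard-call filtering rules: per-genotype depth must
#' lie within `[mean_depth / 3, 2 * mean_depth]` of the sample's mean depth;
#' sites need base quality of at least 30; heterozygous genotypes must have
#' a reference-allele balance (reference reads / depth) within
#' `[0.2, 0.8]`; indels and SNPs within 5 bp of an indel are removed.
#' Failing genotypes are set missing; with `complete_cases`, sites with any
#' missing genotype are dropped; sites losing all genotypes are dropped.
#'
#' @param vt a [variant_table()] carrying `dp`, `ad_ref`, `qual` and
#'   `is_indel` fields.
#' @param mean_depth per-sample mean depth; computed from `dp` if omitted.
#' @param min_qual minimum site base quality (default 30).
#' @param indel_window bp around an indel within which SNPs are removed
#'   (default 5).
#' @param balance allowed reference-allele balance range for heterozygotes.
#' @param complete_cases drop sites with any missing genotype after
#'   filtering.
#' @return a filtered `variant_table`.
#' @export
filter_variants <- function(vt, mean_depth = NULL, min_qual = 30,
                            indel_window = 5, balance = c(0.2, 0.8),
                            complete_cases = FALSE) {
  for (f in c("dp", "ad_ref", "qual", "is_indel"))
    if (is.null(vt[[f]]))
      stop("filter_variants requires the '", f, "' field")
  geno <- vt$geno
  dp <- vt$dp
  if (is.null(mean_depth)) mean_depth <- colMeans(dp, na.rm = TRUE)
  lo <- matrix(mean_depth / 3, nrow(geno), ncol(geno), byrow = TRUE)
  hi <- matrix(2 * mean_depth, nrow(geno), ncol(geno), byrow = TRUE)
  geno[!is.na(dp) & (dp < lo | dp > hi)] <- NA_integer_
  bal <- vt$ad_ref / dp
  bad_bal <- !is.na(geno) & geno == 1L & !is.na(bal) &
    (bal < balance[1] | bal > balance[2])
  geno[bad_bal] <- NA_integer_
  keep <- !vt$is_indel & vt$qual >= min_qual
  near <- rep(FALSE, nrow(geno))
  ind <- which(vt$is_indel)
  for (i in ind) {
    same <- vt$site$chrom == vt$site$chrom[i] & !vt$is_indel
    near <- near | (same & abs(vt$site$pos - vt$site$pos[i]) <= indel_window)
  }
  keep <- keep & !near
  if (complete_cases) keep <- keep & rowSums(is.na(geno)) == 0
  keep <- keep & rowSums(!is.na(geno)) > 0
  variant_table(vt$site$chrom[keep], vt$site$pos[keep],
                vt$site$category[keep], geno[keep, , drop = FALSE],
                vt$populations, vt$samples,
                qual = vt$qual[keep], is_indel = vt$is_indel[keep],
                dp = dp[keep, , drop = FALSE],
                ad_ref = vt$ad_ref[keep, , drop = FALSE])
}

#' Read a variant table from VCF plus annotation and population map
#'
#' @param vcf path to a VCF (v4.2, plain or gzipped) with GT and optionally
#'   DP/AD genotype fields.
#' @param annotation path to a TSV with columns chrom, pos, category.
#' @param popmap path to a TSV with columns sample, population.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(vcf, annotation, popmap) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  ad_ref <- if (!is.null(ad))
    matrix(as.numeric(vapply(strsplit(ad, ","), `[`, character(1), 1)),
           nrow(ad), ncol(ad), dimnames = dimnames(ad))
  else NULL
  qual <- suppressWarnings(as.numeric(vcfR::getQUAL(v)))
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  is_indel <- nchar(ref) != 1L | nchar(alt) != 1L
  ann <- utils::read.table(annotation, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  key <- paste(chrom, pos)
  akey <- paste(ann$chrom, ann$pos)
  m <- match(key, akey)
  if (anyNA(m)) stop(sum(is.na(m)), " VCF site(s) missing from annotation")
  pm <- utils::read.table(popmap, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pops <- pm$population[match(colnames(geno), pm$sample)]
  if (anyNA(pops)) stop("popmap missing sample(s): ",
                        paste(colnames(geno)[is.na(pops)], collapse = ", "))
  variant_table(chrom, pos, ann$category[m], geno, pops,
                samples = colnames(geno), qual = qual, is_indel = is_indel,
                dp = dp, ad_ref = ad_ref)
}
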