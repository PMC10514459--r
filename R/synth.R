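# Synthetic annotated multi-population genotype data: category-labelled
# sites with controlled per-population derived-allele-frequency
# differentials, planted homozygous tracts, and depth/allele-balance fields
# for filter testing. Everything downstream of variant calling can be
# exercised from these fixtures alone.

#' Specification for synthetic variant data
#'
#' Sites are placed uniformly per chromosome at the requested per-category
#' counts. Each site's derived-allele frequency is drawn per population from
#' a Beta distribution (one (a, b) pair per category); `rxy_deficit`
#' multiplies the frequencies of selected categories in `deficit_pop`,
#' emulating a population-specific loss of that category. Genotypes are
#' Hardy-Weinberg draws at the population frequency, except inside planted
#' tracts (`roh_plan`) where the target sample is forced homozygous at every
#' site. Per-genotype depths are negative binomial and heterozygote
#' reference-allele balances Beta-distributed.
#'
#' @param n_pops number of populations (2-5).
#' @param samples_per_pop samples per population.
#' @param n_chromosomes,chromosome_bp genome layout.
#' @param sites_per_category named counts for HIGH, MODERATE, SYNONYMOUS,
#'   INTERGENIC.
#' @param beta_a,beta_b Beta parameters per category (recycled).
#' @param rxy_deficit multiplicative frequency factor (1 = none).
#' @param deficit_categories categories the deficit applies to.
#' @param deficit_pop population index it applies to (default 1).
#' @param roh_plan data.frame(sample, chrom, start, end, state) of tracts
#'   forced homozygous; state is "ancestral" (0) or "derived" (2).
#' @param missing_rate genotype missingness probability.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param ab_shape1,ab_shape2 Beta parameters of heterozygote reference
#'   allele balance.
#' @param qual per-site base quality written to fixtures.
#' @param seed RNG seed used by [generate_table()].
#' @return a `synth_spec`.
#' @export
synth_spec <- function(n_pops = 2L, samples_per_pop = 20L,
                       n_chromosomes = 2L, chromosome_bp = 5e6,
                       sites_per_category = c(HIGH = 200L, MODERATE = 1000L,
                                              SYNONYMOUS = 2000L,
                                              INTERGENIC = 4000L),
                       beta_a = 0.5, beta_b = 2,
                       rxy_deficit = 1, deficit_categories = "HIGH",
                       deficit_pop = 1L, roh_plan = NULL,
                       missing_rate = 0, depth_mean = 20, depth_size = 10,
                       ab_shape1 = 200, ab_shape2 = 200, qual = 60,
                       seed = 1L) {
  stopifnot(n_pops >= 2, n_pops <= 5, samples_per_pop >= 1)
  if (!all(.impact_levels %in% names(sites_per_category)))
    stop("sites_per_category must name all of ",
         paste(.impact_levels, collapse = ", "))
  sites_per_category <- sites_per_category[.impact_levels]
  if (sum(sites_per_category) > n_chromosomes * chromosome_bp)
    stop("more sites requested than base pairs available")
  beta_a <- rep_len(beta_a, 4)
  beta_b <- rep_len(beta_b, 4)
  if (rxy_deficit < 0 || rxy_deficit > 1)
    stop("rxy_deficit must be in [0, 1]")
  spec <- list(n_pops = as.integer(n_pops),
               samples_per_pop = as.integer(samples_per_pop),
               n_chromosomes = as.integer(n_chromosomes),
               chromosome_bp = as.numeric(chromosome_bp),
               sites_per_category = sites_per_category,
               beta_a = setNames(beta_a, .impact_levels),
               beta_b = setNames(beta_b, .impact_levels),
               rxy_deficit = rxy_deficit,
               deficit_categories = deficit_categories,
               deficit_pop = as.integer(deficit_pop),
               roh_plan = roh_plan,
               missing_rate = missing_rate, depth_mean = depth_mean,
               depth_size = depth_size, ab_shape1 = ab_shape1,
               ab_shape2 = ab_shape2, qual = qual, seed = as.integer(seed))
  if (!is.null(roh_plan)) {
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(roh_plan)))
    if (is.null(roh_plan$state)) spec$roh_plan$state <- "ancestral"
    if (any(roh_plan$start < 1 | roh_plan$end > chromosome_bp |
            roh_plan$start >= roh_plan$end))
      stop("roh_plan tracts must lie within chromosome bounds")
  }
  class(spec) <- "synth_spec"
  spec
}

#' Generate a synthetic annotated variant table
#'
#' @param spec a [synth_spec()].
#' @return list with `table` (a [variant_table()]) and `truth` (per-site
#'   per-population frequencies, tract coordinates and the spec) — the
#'   ground truth downstream tests compare against.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    ns <- sum(spec$sites_per_category)
    per_chrom <- table(factor(sample(spec$n_chromosomes, ns, replace = TRUE),
                              levels = seq_len(spec$n_chromosomes)))
    chrom <- integer(0); pos <- integer(0)
    for (c in seq_len(spec$n_chromosomes)) {
      p <- sort(sample.int(spec$chromosome_bp, per_chrom[[c]]))
      chrom <- c(chrom, rep(c, length(p)))
      pos <- c(pos, p)
    }
    category <- sample(rep(.impact_levels, spec$sites_per_category))
    pops <- rep(sprintf("pop%d", seq_len(spec$n_pops)),
                each = spec$samples_per_pop)
    samples <- sprintf("%s_s%02d", pops,
                       rep(seq_len(spec$samples_per_pop), spec$n_pops))
    freq <- matrix(0, ns, spec$n_pops)
    for (k in seq_len(spec$n_pops))
      freq[, k] <- rbeta(ns, spec$beta_a[category], spec$beta_b[category])
    if (spec$rxy_deficit < 1) {
      rows <- category %in% spec$deficit_categories
      freq[rows, spec$deficit_pop] <- freq[rows, spec$deficit_pop] *
        spec$rxy_deficit
    }
    geno <- matrix(0L, ns, length(samples))
    for (k in seq_len(spec$n_pops)) {
      cols <- which(pops == sprintf("pop%d", k))
      for (j in cols)
        geno[, j] <- rbinom(ns, 2L, freq[, k])
    }
    # planted homozygous tracts override the HWE draws
    if (!is.null(spec$roh_plan)) {
      for (i in seq_len(nrow(spec$roh_plan))) {
        tr <- spec$roh_plan[i, ]
        j <- match(tr$sample, samples)
        if (is.na(j)) stop("roh_plan sample not found: ", tr$sample)
        rows <- chrom == tr$chrom & pos >= tr$start & pos <= tr$end
        geno[rows, j] <- if (identical(tr$state, "derived")) 2L else 0L
      }
    }
    if (spec$missing_rate > 0)
      geno[runif(length(geno)) < spec$missing_rate] <- NA_integer_
    # guarantee at least one called genotype per site
    allna <- rowSums(!is.na(geno)) == 0
    geno[allna, 1] <- 0L
    dp <- matrix(rnbinom(length(geno), mu = spec$depth_mean,
                         size = spec$depth_size),
                 ns, length(samples))
    dp[dp < 1] <- 1L
    ab <- matrix(rbeta(length(geno), spec$ab_shape1, spec$ab_shape2),
                 ns, length(samples))
    ad_ref <- matrix(0L, ns, length(samples))
    hom_ref <- which(!is.na(geno) & geno == 0L)
    ad_ref[hom_ref] <- dp[hom_ref]
    het <- which(!is.na(geno) & geno == 1L)
    ad_ref[het] <- round(dp[het] * ab[het])
    vt <- variant_table(chrom, pos, category, geno, pops, samples,
                        qual = rep(spec$qual, ns),
                        is_indel = rep(FALSE, ns),
                        dp = dp, ad_ref = ad_ref)
    truth <- list(freq = freq, category = category, chrom = chrom, pos = pos,
                  roh_plan = spec$roh_plan, spec = spec)
    list(table = vt, truth = truth)
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits a plain-text VCF v4.2 (GT:DP:AD genotypes), an annotation TSV
#' (chrom, pos, category), a population map TSV (sample, population) and a
#' truth JSON. The files round-trip through [read_variant_table()].
#'
#' @param table a [variant_table()].
#' @param truth truth record from [generate_table()] (optional).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(table, truth = NULL, dir, prefix = "synth") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  ns <- nrow(table$geno)
  gt_chr <- matrix("./.", ns, ncol(table$geno))
  gt_chr[table$geno == 0L] <- "0/0"
  gt_chr[table$geno == 1L] <- "0/1"
  gt_chr[table$geno == 2L] <- "1/1"
  dp <- table$dp
  if (is.null(dp)) dp <- matrix(20L, ns, ncol(table$geno))
  ad_ref <- table$ad_ref
  if (is.null(ad_ref)) ad_ref <- round(dp * (2 - table$geno) / 2)
  ad_alt <- dp - ad_ref
  body <- matrix(paste0(gt_chr, ":", dp, ":", ad_ref, ",", ad_alt),
                 ns, ncol(table$geno))
  colnames(body) <- table$samples
  fix <- cbind(CHROM = paste0("chr", table$site$chrom),
               POS = as.character(table$site$pos),
               ID = rep(".", ns), REF = rep("A", ns), ALT = rep("T", ns),
               QUAL = as.character(table$qual %||% rep(60, ns)),
               FILTER = rep("PASS", ns), INFO = rep(".", ns))
  meta <- c("##fileformat=VCFv4.2",
            "##source=foundersim_synth",
            paste0("##contig=<ID=chr", seq_len(max(table$site$chrom)), ">"),
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  con <- file(vcf_path, "w")
  writeLines(meta, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", table$samples), collapse = "\t"), con)
  writeLines(apply(cbind(fix, FORMAT = "GT:DP:AD", body), 1, paste,
                   collapse = "\t"), con)
  close(con)
  ann_path <- file.path(dir, paste0(prefix, "_annotation.tsv"))
  utils::write.table(data.frame(chrom = paste0("chr", table$site$chrom),
                                pos = table$site$pos,
                                category = table$site$category),
                     ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pop_path <- file.path(dir, paste0(prefix, "_popmap.tsv"))
  utils::write.table(data.frame(sample = table$samples,
                                population = table$populations),
                     pop_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf_path, annotation = ann_path, popmap = pop_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
    tr <- truth
    tr$spec$roh_plan <- NULL
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths["truth"] <- truth_path
  }
  paths
}
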