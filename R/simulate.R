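#' Configuration for the diploid genome simulator
#'
#' Describes a synthetic diploid genome with the statistical structure the
#' analysis modules assume: polymorphic sites placed at `snp_density` per bp,
#' a per-site heterozygosity chosen so the genome-wide het rate matches
#' `background_het_rate` (the target theta; whale-scale defaults are a few
#' 1e-4), optional planted autozygous tracts covering a fraction of the
#' genome with exponential lengths (zero heterozygosity inside, emulating
#' recent inbreeding), genotyping error that flips heterozygotes to
#' homozygotes, and independent missingness.
#'
#' @param scaffold_lengths numeric vector of scaffold lengths in bp.
#' @param background_het_rate target per-bp heterozygosity outside tracts.
#' @param planted_tract_fraction fraction of each scaffold inside autozygous
#'   tracts (F*).
#' @param tract_length_mean mean tract length in bp (exponential).
#' @param snp_density per-bp probability of a polymorphic site; must satisfy
#'   `background_het_rate <= snp_density`.
#' @param missing_rate per-call missingness probability.
#' @param het_to_hom_error_rate probability a true heterozygote is scored
#'   homozygous.
#' @param rng_seed integer seed.
#' @return An object of class `diploid_sim_config`.
#' @export
diploid_sim_config <- function(scaffold_lengths = 1e7,
                               background_het_rate = 6.7e-4,
                               planted_tract_fraction = 0,
                               tract_length_mean = 2e5,
                               snp_density = 1.5e-3,
                               missing_rate = 0.002,
                               het_to_hom_error_rate = 0,
                               rng_seed = 1L) {
  probs <- c(background_het_rate, planted_tract_fraction, snp_density,
             missing_rate, het_to_hom_error_rate)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (planted_tract_fraction >= 1) stop("tract fraction must be < 1")
  if (background_het_rate > snp_density)
    stop("background_het_rate cannot exceed snp_density")
  if (planted_tract_fraction > 0 &&
      planted_tract_fraction * sum(scaffold_lengths) < tract_length_mean)
    stop("infeasible config: tract budget smaller than one mean tract")
  structure(list(scaffold_lengths = scaffold_lengths,
                 background_het_rate = background_het_rate,
                 planted_tract_fraction = planted_tract_fraction,
                 tract_length_mean = tract_length_mean,
                 snp_density = snp_density, missing_rate = missing_rate,
                 het_to_hom_error_rate = het_to_hom_error_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "diploid_sim_config")
}

# Non-overlapping exponential-length tracts covering ~ frac * L of [1, L],
# placed with broken-stick gaps. Returns data.frame(start_bp, end_bp).
plant_tracts <- function(L, frac, mean_len) {
  target <- frac * L
  if (target <= 0) return(data.frame(start_bp = numeric(), end_bp = numeric()))
  lens <- numeric(0)
  while (sum(lens) < target)
    lens <- c(lens, ceiling(stats::rexp(1, 1 / mean_len)))
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - round(target))
  lens <- lens[lens >= 1]
  k <- length(lens)
  gap_total <- L - sum(lens)
  if (gap_total < 0) stop("tracts exceed scaffold length")
  cuts <- sort(stats::runif(k, 0, 1))
  gaps <- diff(c(0, cuts, 1)) * gap_total
  starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, lens[-k])) + 1
  data.frame(start_bp = floor(starts), end_bp = floor(starts) + lens - 1)
}

#' Simulate a diploid genotype table with planted autozygous tracts
#'
#' Generates, per individual, genotypes on a shared polymorphic-site grid:
#' heterozygous with probability `background_het_rate / snp_density` outside
#' tracts and 0 inside, then het-to-hom error and missingness. All scaffolds
#' are fully callable for every individual. Pure function of (config, seed).
#'
#' @param config a [diploid_sim_config].
#' @param n_individuals number of individuals (default 1), named `ind1`,
#'   `ind2`, ...
#' @return List with `table` (a [genotype_table]), `mask` (a
#'   [callable_mask]), and `truth` (list: `tracts` data.frame with `sample`,
#'   `scaffold`, `start_bp`, `end_bp`; `realized_theta` named vector;
#'   `f_star`).
#' @export
simulate_diploid_table <- function(config, n_individuals = 1) {
  stopifnot(inherits(config, "diploid_sim_config"))
  samples <- paste0("ind", seq_len(n_individuals))
  with_seed(config$rng_seed, {
    scafs <- data.frame(scaffold = paste0("scaf", seq_along(config$scaffold_lengths)),
                        length = config$scaffold_lengths)
    h <- config$background_het_rate / config$snp_density
    site_rows <- list()
    geno <- list()
    tracts <- list()
    for (si in seq_len(nrow(scafs))) {
      L <- scafs$length[si]
      n_sites <- stats::rbinom(1, L, config$snp_density)
      pos <- sort(sample.int(L, n_sites))
      alle <- matrix(sample(c("A", "C", "G", "T"), 2 * n_sites,
                            replace = TRUE), ncol = 2)
      same <- alle[, 1] == alle[, 2]
      alle[same, 2] <- chartr("ACGT", "CGTA", alle[same, 1])
      site_rows[[si]] <- data.frame(scaffold = scafs$scaffold[si], pos = pos,
                                    ref = alle[, 1], alt = alle[, 2])
      g <- matrix(NA_integer_, n_sites, n_individuals,
                  dimnames = list(NULL, samples))
      for (ind in samples) {
        tr <- plant_tracts(L, config$planted_tract_fraction,
                           config$tract_length_mean)
        if (nrow(tr) > 0)
          tracts[[length(tracts) + 1L]] <-
            cbind(sample = ind, scaffold = scafs$scaffold[si], tr)
        in_tract <- if (nrow(tr) > 0)
          IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                               IRanges::IRanges(tr$start_bp, tr$end_bp))
        else rep(FALSE, n_sites)
        p_het <- ifelse(in_tract, 0, h)
        is_het <- stats::runif(n_sites) < p_het
        flip <- is_het & stats::runif(n_sites) < config$het_to_hom_error_rate
        gi <- ifelse(is_het & !flip, 1L,
                     ifelse(stats::runif(n_sites) < 0.3, 2L, 0L))
        gi[stats::runif(n_sites) < config$missing_rate] <- NA_integer_
        g[, ind] <- gi
      }
      geno[[si]] <- g
    }
    sites <- do.call(rbind, site_rows)
    g_all <- do.call(rbind, geno)
    depth <- matrix(30L, nrow(sites), n_individuals,
                    dimnames = list(NULL, samples))
    table <- genotype_table(scafs, sites, g_all, depth)
    mask <- callable_mask(
      do.call(rbind, lapply(samples, function(ind)
        data.frame(sample = ind, scaffold = scafs$scaffold, start = 0,
                   end = scafs$length))))
    realized <- vapply(samples, function(ind) {
      gi <- g_all[, ind]
      sum(!is.na(gi) & gi == 1L) / sum(scafs$length)
    }, numeric(1))
    tr_all <- if (length(tracts)) do.call(rbind, tracts) else
      data.frame(sample = character(), scaffold = character(),
                 start_bp = numeric(), end_bp = numeric())
    rownames(tr_all) <- NULL
    list(table = table, mask = mask,
         truth = list(tracts = tr_all, realized_theta = realized,
                      f_star = config$planted_tract_fraction))
  })
}

#' Simulate a pair of diploids under Hardy-Weinberg
#'
#' Per site, draws an allele frequency from `maf_law` and genotypes: for
#' `"unrelated"`, two independent Hardy-Weinberg diploids; for `"full_sib"`,
#' two children of one simulated parental pair (each child receives one
#' uniformly chosen allele from each parent). Sites are spaced `spacing_bp`
#' apart (split over several scaffolds to keep positions in integer range),
#' so the identity-by-state spacing filter retains every informative site at
#' its default.
#'
#' @param n_sites number of unlinked sites (> 0).
#' @param maf_law function of n returning alternate-allele frequencies;
#'   default Uniform(0.05, 0.5).
#' @param relationship `"unrelated"` or `"full_sib"`.
#' @param rng_seed integer seed.
#' @param spacing_bp distance between consecutive sites (default 500 kb).
#' @return List with `table` (a two-sample [genotype_table], samples `ind1`,
#'   `ind2`) and `freq` (per-site alternate-allele frequency).
#' @export
simulate_hwe_pair <- function(n_sites,
                              maf_law = function(n) stats::runif(n, 0.05, 0.5),
                              relationship = c("unrelated", "full_sib"),
                              rng_seed = 1L, spacing_bp = 5e5) {
  relationship <- match.arg(relationship)
  if (n_sites <= 0) stop("n_sites must be > 0")
  with_seed(rng_seed, {
    q <- maf_law(n_sites)
    if (relationship == "unrelated") {
      g1 <- stats::rbinom(n_sites, 1, q) + stats::rbinom(n_sites, 1, q)
      g2 <- stats::rbinom(n_sites, 1, q) + stats::rbinom(n_sites, 1, q)
    } else {
      m <- cbind(stats::rbinom(n_sites, 1, q), stats::rbinom(n_sites, 1, q))
      f <- cbind(stats::rbinom(n_sites, 1, q), stats::rbinom(n_sites, 1, q))
      pick <- function(par) par[cbind(seq_len(n_sites),
                                      sample(2, n_sites, replace = TRUE))]
      g1 <- pick(m) + pick(f)
      g2 <- pick(m) + pick(f)
    }
    # keep positions within integer range by splitting across scaffolds
    per_scaf <- max(1, floor(2e9 / spacing_bp))
    scaf_of <- (seq_len(n_sites) - 1) %/% per_scaf
    within <- (seq_len(n_sites) - 1) %% per_scaf
    pos <- within * spacing_bp + 1
    scaf_ids <- paste0("sim", seq_len(max(scaf_of) + 1))
    scafs <- data.frame(scaffold = scaf_ids,
                        length = per_scaf * spacing_bp)
    sites <- data.frame(scaffold = scaf_ids[scaf_of + 1], pos = pos,
                        ref = "A", alt = "C")
    geno <- cbind(ind1 = as.integer(g1), ind2 = as.integer(g2))
    depth <- matrix(30L, n_sites, 2, dimnames = list(NULL, c("ind1", "ind2")))
    list(table = genotype_table(scafs, sites, geno, depth), freq = q)
  })
}

#' Simulate ABBA/BABA pattern counts in genomic blocks
#'
#' Per block, a multinomial draw of (ABBA, BABA, other) site counts with
#' probabilities (p_abba + admixture_excess, p_baba, remainder). With zero
#' excess and equal rates this is the incomplete-lineage-sorting null under
#' which D is expected to be 0; a positive excess emulates gene flow into P2.
#'
#' @param n_blocks number of blocks.
#' @param sites_per_block sites evaluated per block.
#' @param p_abba,p_baba per-site pattern probabilities.
#' @param admixture_excess added to `p_abba` (0 under the null).
#' @param rng_seed integer seed.
#' @return A `pattern_blocks` data.frame compatible with
#'   [d_with_jackknife].
#' @export
simulate_pattern_blocks <- function(n_blocks, sites_per_block,
                                    p_abba = 0.01, p_baba = 0.01,
                                    admixture_excess = 0, rng_seed = 1L) {
  pa <- p_abba + admixture_excess
  if (min(pa, p_baba, admixture_excess) < 0 || pa + p_baba > 1)
    stop("invalid pattern probabilities")
  with_seed(rng_seed, {
    draws <- stats::rmultinom(n_blocks, sites_per_block,
                              c(pa, p_baba, 1 - pa - p_baba))
    new_pattern_blocks(data.frame(
      scaffold = "sim", block = seq_len(n_blocks) - 1L,
      n_abba = draws[1, ], n_baba = draws[2, ], n_concordant = 0L,
      n_sites_evaluated = sites_per_block))
  })
}
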