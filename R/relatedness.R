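#' Identity-by-state comparison configuration
#'
#' Site selection for pairwise IBS relatedness: a minor-allele-frequency
#' floor (computed from all samples in the table pooled together) and a
#' minimum spacing between retained informative SNPs to limit linkage
#' disequilibrium. Defaults: MAF 0.01 and 500 kb spacing.
#'
#' @param maf_min minimum minor allele frequency in [0, 0.5).
#' @param min_spacing_bp minimum distance between consecutive retained
#'   informative sites within a scaffold.
#' @return An object of class `ibs_config`.
#' @export
ibs_config <- function(maf_min = 0.01, min_spacing_bp = 5e5) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  if (min_spacing_bp < 0) stop("min_spacing_bp must be >= 0")
  structure(list(maf_min = maf_min, min_spacing_bp = min_spacing_bp),
            class = "ibs_config")
}

#' Informative IBS site counts for a pair of individuals
#'
#' Considers biallelic sites where both genotypes are called and the pooled
#' minor allele frequency is at least `maf_min`. Informative sites are the
#' two IBS extremes: both heterozygous (IBS = 2, "HetHet") and discordant
#' homozygotes (IBS = 0, "HomHom"). Informative sites are thinned greedily
#' left-to-right so that consecutive retained informative sites are at least
#' `min_spacing_bp` apart within a scaffold; counts are tallied on the
#' retained sites.
#'
#' @param table a [genotype_table].
#' @param pair character vector of two sample ids.
#' @param config an [ibs_config].
#' @return List of class `ibs_counts`: `n_hethet`, `n_homhom_discordant`,
#'   `n_sites_used` (sites passing the MAF/call filters).
#' @export
ibs_counts <- function(table, pair, config = ibs_config()) {
  absent <- setdiff(pair, table$samples)
  if (length(absent) > 0)
    stop("pair member(s) not in table: ", paste(absent, collapse = ", "))
  if (length(pair) != 2) stop("pair must name exactly two individuals")
  g <- table$geno
  alt <- rowSums(g, na.rm = TRUE)
  called <- rowSums(!is.na(g))
  p_alt <- ifelse(called > 0, alt / (2 * called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  g1 <- g[, pair[1]]
  g2 <- g[, pair[2]]
  usable <- !is.na(g1) & !is.na(g2) & !is.na(maf) & maf >= config$maf_min &
    !grepl(",", table$sites$alt)
  hethet <- usable & g1 == 1L & g2 == 1L
  discord <- usable & ((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  informative <- which(hethet | discord)
  keep <- logical(length(informative))
  if (length(informative) > 0) {
    sc <- table$sites$scaffold[informative]
    pos <- table$sites$pos[informative]
    for (s in unique(sc)) {
      ii <- which(sc == s)
      last <- -Inf
      for (k in ii) {
        if (pos[k] - last >= config$min_spacing_bp || !is.finite(last)) {
          keep[k] <- TRUE
          last <- pos[k]
        }
      }
    }
  }
  kept <- informative[keep]
  structure(list(n_hethet = sum(hethet[kept]),
                 n_homhom_discordant = sum(discord[kept]),
                 n_sites_used = sum(usable)),
            class = "ibs_counts")
}

#' HetHet : HomHom sharing ratio
#'
#' Ratio of both-heterozygous to discordant-homozygote site counts. Under
#' random mating within one population the expectation is 2 (per-site
#' densities 4 p^2 q^2 vs 2 p^2 q^2); a ratio above 2 suggests the pair is
#' more related than expected by chance, below 2 that the two individuals
#' draw recent ancestry from different mating pools.
#'
#' @param counts an [ibs_counts] result (or any list with `n_hethet` and
#'   `n_homhom_discordant`).
#' @return The ratio (numeric).
#' @export
hethet_homhom_ratio <- function(counts) {
  if (counts$n_homhom_discordant == 0)
    stop("no discordant homozygote sites")
  counts$n_hethet / counts$n_homhom_discordant
}

#' Pairwise population concordance (PPC) test
#'
#' Exact one-sided binomial test of the informative-site composition against
#' the random-mating null. Conditional on a site being informative, the null
#' probability that it is HetHet is 2/3 (HetHet:HomHom = 2:1); the
#' alternative is a deficit of HetHet sites (success probability < 2/3),
#' i.e. the pair draws ancestry from different mating pools. Small p rejects
#' common ancestry; related pairs give p near 1.
#'
#' @param counts an [ibs_counts] result.
#' @return The one-sided p-value.
#' @export
ppc_test <- function(counts) {
  n <- counts$n_hethet + counts$n_homhom_discordant
  if (n == 0) stop("no informative sites")
  stats::binom.test(counts$n_hethet, n, p = 2 / 3,
                    alternative = "less")$p.value
}
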