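#' Mutation-rate configuration for time and Ne scaling
#'
#' The substitution rate and generation time that convert scaled genetic
#' quantities into calendar years and diploid effective sizes. Defaults are
#' the baleen-whale values used throughout the package: an autosomal
#' substitution rate of 4.8e-10 per bp per year (credibility interval
#' 1.5e-10 to 10e-10) and a generation time of 18.9 years (midpoint of the
#' 15.5-22.3 year range).
#'
#' @param substitution_rate_per_year point rate, per bp per year.
#' @param rate_ci length-2 numeric, lower and upper rate bounds.
#' @param generation_time_years generation time in years.
#' @return An object of class `rate_config` with the inputs plus
#'   `mu_per_generation`, the per-generation per-bp mutation rate.
#' @export
rate_config <- function(substitution_rate_per_year = 4.8e-10,
                        rate_ci = c(1.5e-10, 10e-10),
                        generation_time_years = 18.9) {
  if (substitution_rate_per_year <= 0 || generation_time_years <= 0 ||
      any(rate_ci <= 0))
    stop("rates and generation time must be > 0")
  if (rate_ci[1] > substitution_rate_per_year ||
      rate_ci[2] < substitution_rate_per_year)
    stop("rate_ci must bracket the point rate")
  structure(list(substitution_rate_per_year = substitution_rate_per_year,
                 rate_ci = rate_ci,
                 generation_time_years = generation_time_years,
                 mu_per_generation = substitution_rate_per_year *
                   generation_time_years),
            class = "rate_config")
}

#' Genome-wide heterozygosity for one individual
#'
#' theta_genome = heterozygous sites / total callable sites. The numerator
#' counts heterozygous, non-missing calls lying inside the individual's
#' callable mask; the denominator is the mask's total callable bp, so callable
#' monomorphic positions count even when the VCF holds variant records only.
#'
#' @param table a [genotype_table].
#' @param mask a [callable_mask] covering the individual.
#' @param individual sample id.
#' @return A list of class `diversity_result`: `theta_genome`, `n_het`,
#'   `n_callable`.
#' @export
theta_genome <- function(table, mask, individual) {
  if (!individual %in% table$samples) stop("unknown individual: ", individual)
  n_callable <- mask_total(mask, individual)
  if (n_callable == 0) stop("no callable sites for ", individual)
  g <- table$geno[, individual]
  het <- !is.na(g) & g == 1L
  n_het <- 0
  for (sc in unique(table$sites$scaffold[het])) {
    idx <- het & table$sites$scaffold == sc
    n_het <- n_het + sum(mask_contains(mask, individual, sc,
                                       table$sites$pos[idx]))
  }
  structure(list(theta_genome = n_het / n_callable,
                 n_het = n_het, n_callable = n_callable),
            class = "diversity_result")
}

#' Heterozygosity outside runs of homozygosity
#'
#' theta_noROH contrasts with [theta_genome] to quantify how much autozygosity
#' depresses overall variation: heterozygous sites outside all ROHs divided by
#' callable bp outside all ROHs.
#'
#' @param table a [genotype_table].
#' @param mask a [callable_mask].
#' @param rohs ROH data.frame from [scan_roh] for the same individual.
#' @param individual sample id.
#' @return Numeric theta_noROH.
#' @export
theta_no_roh <- function(table, mask, rohs, individual) {
  if (!individual %in% table$samples) stop("unknown individual: ", individual)
  res <- theta_genome(table, mask, individual)
  if (nrow(rohs) == 0) return(res$theta_genome)
  roh_bp <- mask_overlap_bp(mask, individual,
                            data.frame(scaffold = rohs$scaffold,
                                       start_bp = rohs$start_bp,
                                       end_bp = rohs$end_bp))
  denom <- res$n_callable - roh_bp
  if (denom <= 0) stop("no callable sites outside ROHs")
  g <- table$geno[, individual]
  het <- !is.na(g) & g == 1L
  n_het_in <- 0
  for (sc in unique(rohs$scaffold)) {
    idx <- which(het & table$sites$scaffold == sc)
    if (length(idx) == 0) next
    pos <- table$sites$pos[idx]
    r <- rohs[rohs$scaffold == sc, , drop = FALSE]
    in_roh <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos, end = pos),
      IRanges::IRanges(start = r$start_bp, end = r$end_bp))
    inside_mask <- mask_contains(mask, individual, sc, pos)
    n_het_in <- n_het_in + sum(in_roh & inside_mask)
  }
  (res$n_het - n_het_in) / denom
}

#' Equilibrium effective population size from heterozygosity
#'
#' Inverts theta = 4 Ne mu with mu per generation derived from the yearly
#' substitution rate and generation time. An interval is reported from the
#' substitution-rate credibility bounds (a higher rate implies a smaller Ne).
#'
#' @param theta per-site heterozygosity (>= 0).
#' @param rates a [rate_config].
#' @return List with `ne` (diploid individuals), `ne_low`, `ne_high` (from the
#'   upper and lower rate bound respectively), and `mu_per_generation`.
#' @export
ne_from_theta <- function(theta, rates = rate_config()) {
  if (theta < 0) stop("theta must be >= 0")
  mu <- rates$mu_per_generation
  mu_bounds <- rates$rate_ci * rates$generation_time_years
  list(ne = theta / (4 * mu),
       ne_low = theta / (4 * mu_bounds[2]),
       ne_high = theta / (4 * mu_bounds[1]),
       mu_per_generation = mu)
}
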