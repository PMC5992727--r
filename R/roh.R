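#' Run-of-homozygosity scan configuration
#'
#' Window rules for calling autozygous tracts: a sliding window of
#' `window_snps` consecutive sites is eligible when it holds at most
#' `max_het_per_run` heterozygous and `max_missing_per_run` missing calls;
#' maximal unions of overlapping eligible windows become candidate runs.
#' Within each candidate, the emitted run is the maximal-site-count
#' subinterval (leftmost on ties) that still respects the het/missing caps,
#' contains at least `window_snps` homozygous sites and spans at least
#' `min_length_bp`; the remainders on either side are processed the same way,
#' and a candidate that satisfies the caps as a whole is emitted unchanged.
#' Defaults: 20-SNP windows allowing 1 heterozygous and 1 missing call, 1 kb
#' lower length bound.
#'
#' @param window_snps sites per window (>= 2).
#' @param max_het_per_run heterozygous calls tolerated per window and per run.
#' @param max_missing_per_run missing calls tolerated per window and per run.
#' @param min_length_bp minimum run extent in bp (first to last member SNP).
#' @return An object of class `roh_config`.
#' @export
roh_config <- function(window_snps = 20, max_het_per_run = 1,
                       max_missing_per_run = 1, min_length_bp = 1000) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (max_het_per_run >= window_snps) stop("max_het_per_run must be < window_snps")
  if (max_het_per_run < 0 || max_missing_per_run < 0 || min_length_bp < 0)
    stop("negative ROH parameter")
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_run = as.integer(max_het_per_run),
                 max_missing_per_run = as.integer(max_missing_per_run),
                 min_length_bp = as.numeric(min_length_bp)),
            class = "roh_config")
}

# Within sites [i, j], find the maximal-site-count subinterval (leftmost on
# ties) satisfying all run-level invariants; emit it and recurse on the
# remainders. `ch`/`cm` are 0-prefixed cumulative het/missing counts.
emit_runs <- function(pos, ch, cm, i, j, config, acc) {
  w <- config$window_snps
  if (j - i + 1L < w) return(acc)
  best_len <- 0L
  best <- NULL
  a <- i
  for (b in i:j) {
    # smallest a keeping the caps satisfied up to b (two-pointer)
    while (ch[b + 1L] - ch[a] > config$max_het_per_run ||
           cm[b + 1L] - cm[a] > config$max_missing_per_run)
      a <- a + 1L
    n_sites <- b - a + 1L
    n_het <- ch[b + 1L] - ch[a]
    n_mis <- cm[b + 1L] - cm[a]
    if (n_sites - n_het - n_mis >= w &&
        pos[b] - pos[a] + 1 >= config$min_length_bp &&
        n_sites > best_len) {
      best_len <- n_sites
      best <- c(a, b)
    }
  }
  if (is.null(best)) return(acc)
  a <- best[1]; b <- best[2]
  acc <- emit_runs(pos, ch, cm, i, a - 1L, config, acc)
  acc[[length(acc) + 1L]] <- data.frame(
    start_bp = pos[a], end_bp = pos[b], n_sites = b - a + 1L,
    n_het = ch[b + 1L] - ch[a], n_missing = cm[b + 1L] - cm[a],
    length_bp = pos[b] - pos[a] + 1)
  emit_runs(pos, ch, cm, b + 1L, j, config, acc)
}

# Windowed ROH scan over one scaffold's genotype codes and positions.
scan_roh_scaffold <- function(pos, g, config) {
  n <- length(pos)
  w <- config$window_snps
  empty <- data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_sites = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric())
  if (n < w) return(empty)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  starts <- seq_len(n - w + 1L)
  het_w <- ch[starts + w] - ch[starts]
  mis_w <- cm[starts + w] - cm[starts]
  ok <- het_w <= config$max_het_per_run & mis_w <= config$max_missing_per_run
  if (!any(ok)) return(empty)
  idx <- starts[ok]
  # windows i and j overlap iff |i - j| <= w - 1; chain overlapping windows
  brk <- c(0L, which(diff(idx) > w - 1L), length(idx))
  out <- list()
  for (k in seq_len(length(brk) - 1L)) {
    i <- idx[brk[k] + 1L]
    j <- idx[brk[k + 1L]] + w - 1L
    out <- emit_runs(pos, ch, cm, i, j, config, out)
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Detect runs of homozygosity for one individual
#'
#' Slides `window_snps`-site windows along each scaffold, merges overlapping
#' eligible windows into candidate runs and emits, per candidate, the
#' maximal subintervals satisfying the run-level invariants (see
#' [roh_config]). Runs never span scaffold boundaries, never merge across a
#' disqualifying site, and coordinates span the first to last member SNP
#' (1-based inclusive).
#'
#' @param table a [genotype_table].
#' @param individual sample id.
#' @param config a [roh_config].
#' @return data.frame of class `roh_set`, sorted by (scaffold, start), with
#'   columns `scaffold`, `start_bp`, `end_bp`, `n_sites`, `n_het`,
#'   `n_missing`, `length_bp`.
#' @export
scan_roh <- function(table, individual, config = roh_config()) {
  if (!individual %in% table$samples) stop("unknown individual: ", individual)
  g_all <- table$geno[, individual]
  out <- list()
  for (sc in unique(table$sites$scaffold)) {
    sel <- table$sites$scaffold == sc
    runs <- scan_roh_scaffold(table$sites$pos[sel], g_all[sel], config)
    if (nrow(runs) > 0)
      out[[length(out) + 1L]] <- cbind(scaffold = sc, runs)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(), start_bp = numeric(),
               end_bp = numeric(), n_sites = integer(), n_het = integer(),
               n_missing = integer(), length_bp = numeric())
  res <- res[order(res$scaffold, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Summarize a set of runs of homozygosity
#'
#' Computes the four standard ROH parameters: N_ROH (count), L_ROH (mean
#' length, with n-1 sd), T_ROH (summed length), and the inbreeding
#' coefficient F_ROH = T_ROH / genome size.
#'
#' @param rohs ROH data.frame from [scan_roh].
#' @param genome_size_bp genome size used as the F_ROH denominator
#'   (default 2.4e9 bp).
#' @return List with `n_roh`, `mean_length_bp`, `sd_length_bp`,
#'   `total_length_bp`, `f_roh`, `genome_size_bp`.
#' @export
summarize_roh <- function(rohs, genome_size_bp = 2.4e9) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0")
  n <- nrow(rohs)
  if (n == 0)
    return(list(n_roh = 0L, mean_length_bp = 0, sd_length_bp = NA_real_,
                total_length_bp = 0, f_roh = 0,
                genome_size_bp = genome_size_bp))
  len <- rohs$length_bp
  list(n_roh = n, mean_length_bp = mean(len),
       sd_length_bp = if (n > 1) stats::sd(len) else NA_real_,
       total_length_bp = sum(len), f_roh = sum(len) / genome_size_bp,
       genome_size_bp = genome_size_bp)
}

#' Welch t-test on mean ROH length between two individuals
#'
#' Unequal-variance two-sample t on raw run lengths, two-sided.
#'
#' @param rohsA,rohsB ROH data.frames from [scan_roh] (>= 2 runs each).
#' @return List with `t`, `df`, `p_value`.
#' @export
compare_mean_length <- function(rohsA, rohsB) {
  if (nrow(rohsA) < 2 || nrow(rohsB) < 2)
    stop("need >= 2 runs in each set for the Welch test")
  tt <- stats::t.test(rohsA$length_bp, rohsB$length_bp, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Kolmogorov-Smirnov test on ROH length distributions
#'
#' Two-sample KS statistic on run lengths with the asymptotic two-sided
#' p-value.
#'
#' @param rohsA,rohsB non-empty ROH data.frames from [scan_roh].
#' @return List with `d_ks`, `p_value`.
#' @export
compare_length_distributions <- function(rohsA, rohsB) {
  if (nrow(rohsA) == 0 || nrow(rohsB) == 0)
    stop("need non-empty run sets for the KS test")
  ks <- suppressWarnings(stats::ks.test(rohsA$length_bp, rohsB$length_bp,
                                        exact = FALSE))
  list(d_ks = unname(ks$statistic), p_value = ks$p.value)
}

#' Write runs of homozygosity as BED
#'
#' 0-based half-open intervals with site/het/missing counts in columns 4-6.
#'
#' @param rohs ROH data.frame from [scan_roh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(rohs, path) {
  bed <- data.frame(rohs$scaffold, format(rohs$start_bp - 1, scientific = FALSE,
                                          trim = TRUE),
                    format(rohs$end_bp, scientific = FALSE, trim = TRUE),
                    rohs$n_sites, rohs$n_het, rohs$n_missing)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
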