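#' ABBA-BABA test configuration
#'
#' @param block_size_bp jackknife block size along a scaffold (default 10 Mb,
#'   chosen to exceed linkage disequilibrium).
#' @param min_scaffold_bp scaffolds shorter than this are excluded
#'   (default 10 Mb).
#' @param z_critical |Z| threshold for rejecting a topology (default 3).
#' @param rng_seed seed for the per-site allele sampling.
#' @param weighted use the weighted delete-one block jackknife with
#'   informative-site weights (default `TRUE`); `FALSE` gives the ordinary
#'   unweighted delete-one jackknife.
#' @return An object of class `dstat_config`.
#' @export
dstat_config <- function(block_size_bp = 10e6, min_scaffold_bp = 10e6,
                         z_critical = 3, rng_seed = 1L, weighted = TRUE) {
  if (block_size_bp <= 0) stop("block_size_bp must be > 0")
  if (z_critical <= 0) stop("z_critical must be > 0")
  structure(list(block_size_bp = block_size_bp,
                 min_scaffold_bp = min_scaffold_bp,
                 z_critical = z_critical, rng_seed = as.integer(rng_seed),
                 weighted = isTRUE(weighted)),
            class = "dstat_config")
}

new_pattern_blocks <- function(df) {
  class(df) <- c("pattern_blocks", "data.frame")
  df
}

#' Count ABBA/BABA site patterns in genomic blocks
#'
#' For each site where all four genotypes are called and the outgroup is
#' homozygous, one allele is sampled uniformly at random (seeded) from each
#' ingroup individual; the outgroup allele defines the ancestral state A and
#' the derived state B is any non-outgroup allele. Sites are classified ABBA
#' (P1 ancestral, P2 and P3 derived), BABA (P2 ancestral, P1 and P3 derived)
#' or tree-concordant (P1 and P2 derived, P3 ancestral), and counts are
#' accumulated in non-overlapping blocks of `block_size_bp` aligned to
#' scaffold starts; the terminal partial block is kept. Allele draws are
#' keyed to the individual (not the topology slot), so exchanging P1 and P2
#' under the same seed mirrors every site exactly.
#'
#' @param table a [genotype_table].
#' @param topology character vector `(P1, P2, P3, outgroup)` of sample ids.
#' @param config a [dstat_config].
#' @return A `pattern_blocks` data.frame: `scaffold`, `block`, `n_abba`,
#'   `n_baba`, `n_concordant`, `n_sites_evaluated`.
#' @export
count_patterns <- function(table, topology, config = dstat_config()) {
  if (length(topology) != 4 || anyDuplicated(topology))
    stop("topology must be four distinct sample ids (P1, P2, P3, outgroup)")
  absent <- setdiff(topology, table$samples)
  if (length(absent) > 0)
    stop("topology member(s) not in table: ", paste(absent, collapse = ", "))
  keep_scaf <- table$scaffolds$scaffold[
    table$scaffolds$length >= config$min_scaffold_bp]
  sel <- table$sites$scaffold %in% keep_scaf
  sites <- table$sites[sel, , drop = FALSE]
  if (nrow(sites) == 0)
    return(new_pattern_blocks(data.frame(
      scaffold = character(), block = integer(), n_abba = integer(),
      n_baba = integer(), n_concordant = integer(),
      n_sites_evaluated = integer())))
  g <- table$geno[sel, topology, drop = FALSE]
  go <- g[, 4]
  evaluable <- rowSums(is.na(g)) == 0 & (go == 0L | go == 2L)

  # seeded uniform draws, one column per ingroup individual ordered by the
  # individual's position in the table (for P1/P2 exchange symmetry)
  ingroup <- topology[1:3]
  ord <- order(match(ingroup, table$samples))
  u <- with_seed(config$rng_seed,
                 matrix(stats::runif(nrow(sites) * 3), ncol = 3))
  colnames(u) <- ingroup[ord]
  allele <- matrix(NA, nrow(sites), 3, dimnames = list(NULL, ingroup))
  for (id in ingroup) {
    gi <- g[, match(id, topology)]
    allele[, id] <- ifelse(gi == 2L, 1L,
                           ifelse(gi == 0L, 0L,
                                  as.integer(u[, id] < 0.5)))
  }
  anc <- ifelse(go == 2L, 1L, 0L)
  b <- allele != anc   # derived indicator per ingroup individual
  abba <- evaluable & !b[, 1] & b[, 2] & b[, 3]
  baba <- evaluable & b[, 1] & !b[, 2] & b[, 3]
  conc <- evaluable & b[, 1] & b[, 2] & !b[, 3]

  block <- (sites$pos - 1) %/% config$block_size_bp
  key <- factor(paste(sites$scaffold, block, sep = "\r"))
  agg <- function(x) as.vector(tapply(as.integer(x), key, sum))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    scaffold = vapply(parts, `[`, "", 1),
    block = as.integer(vapply(parts, `[`, "", 2)),
    n_abba = agg(abba), n_baba = agg(baba), n_concordant = agg(conc),
    n_sites_evaluated = agg(evaluable))
  out <- out[order(out$scaffold, out$block), , drop = FALSE]
  rownames(out) <- NULL
  new_pattern_blocks(out)
}

#' D-statistic with weighted block-jackknife standard error
#'
#' D = (nABBA - nBABA) / (nABBA + nBABA) from the pooled counts; the standard
#' error comes from the delete-one block jackknife with block weights
#' proportional to each block's informative-site count (ABBA + BABA), and
#' Z = D / SE. Blocks without informative sites carry no information and are
#' dropped from the jackknife.
#'
#' @param blocks a `pattern_blocks` data.frame ([count_patterns] or
#'   [simulate_pattern_blocks]).
#' @param weighted use informative-site weights (default `TRUE`).
#' @return List of class `dstat_result`: `d`, `se`, `z`, `n_blocks`,
#'   `n_abba`, `n_baba`.
#' @export
d_with_jackknife <- function(blocks, weighted = TRUE) {
  m <- blocks$n_abba + blocks$n_baba
  tot <- sum(m)
  if (tot == 0) stop("no informative (ABBA or BABA) sites")
  use <- m > 0
  if (sum(use) < 2) stop("jackknife undefined: informative sites in < 2 blocks")
  a <- blocks$n_abba[use]
  b <- blocks$n_baba[use]
  m <- m[use]
  g <- length(m)
  A <- sum(a); B <- sum(b)
  d_hat <- (A - B) / (A + B)
  d_loo <- ((A - a) - (B - b)) / ((A - a) + (B - b))
  if (weighted) {
    n <- sum(m)
    h <- n / m
    d_jack <- g * d_hat - sum((1 - m / n) * d_loo)
    tau <- h * d_hat - (h - 1) * d_loo
    var_j <- sum((tau - d_jack)^2 / (h - 1)) / g
  } else {
    var_j <- (g - 1) / g * sum((d_loo - mean(d_loo))^2)
  }
  se <- sqrt(var_j)
  structure(list(d = d_hat, se = se, z = if (se > 0) d_hat / se else NA_real_,
                 n_blocks = g, n_abba = A, n_baba = B),
            class = "dstat_result")
}

#' ABBA-BABA tests over all ingroup topologies
#'
#' Evaluates the three distinct ways of arranging three ingroup individuals
#' as ((P1, P2), P3) with a fixed outgroup, returning a D-statistic, SE and
#' Z for each. A topology is rejected when |Z| exceeds `config$z_critical`.
#'
#' @param table a [genotype_table].
#' @param labels character vector `(A, B, C, outgroup)`.
#' @param config a [dstat_config].
#' @return data.frame with one row per rotation: `p1`, `p2`, `p3`,
#'   `outgroup`, `n_abba`, `n_baba`, `d`, `se`, `z`, `significant`.
#' @export
run_topology_tests <- function(table, labels, config = dstat_config()) {
  if (length(labels) != 4 || anyDuplicated(labels))
    stop("labels must be four distinct sample ids")
  rot <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  rows <- lapply(rot, function(r) {
    topo <- c(labels[r], labels[4])
    res <- d_with_jackknife(count_patterns(table, topo, config),
                            weighted = config$weighted)
    data.frame(p1 = topo[1], p2 = topo[2], p3 = topo[3], outgroup = topo[4],
               n_abba = res$n_abba, n_baba = res$n_baba, d = res$d,
               se = res$se, z = res$z,
               significant = abs(res$z) > config$z_critical)
  })
  do.call(rbind, rows)
}
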