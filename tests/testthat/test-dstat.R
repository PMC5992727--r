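# Four-taxon table with all-homozygous genotypes drawn from pattern
# probabilities (no allele-sampling ambiguity): outgroup always 0.
pattern_table <- function(n_sites, p_abba, p_baba, p_conc,
                          scaffold_len = 2e7) {
  pat <- sample(c("ABBA", "BABA", "BBAA", "AAAA"), n_sites, replace = TRUE,
                prob = c(p_abba, p_baba, p_conc, 1 - p_abba - p_baba - p_conc))
  g <- matrix(0L, n_sites, 4, dimnames = list(NULL, c("p1", "p2", "p3", "o")))
  g[pat == "ABBA", 2:3] <- 2L
  g[pat == "BABA", c(1, 3)] <- 2L
  g[pat == "BBAA", 1:2] <- 2L
  pos <- sort(sample.int(scaffold_len, n_sites))
  list(table = make_table(g, pos = pos, scaffold = "s1",
                          scaffold_len = scaffold_len),
       pattern = pat, pos = pos)
}

test_that("homozygous site patterns classify deterministically", {
  cfg <- dstat_config(block_size_bp = 1e6, min_scaffold_bp = 0, rng_seed = 4)
  one <- function(g1, g2, g3, go) {
    tab <- make_table(matrix(c(g1, g2, g3, go), 1, 4,
                             dimnames = list(NULL, c("p1", "p2", "p3", "o"))),
                      pos = 500L)
    count_patterns(tab, c("p1", "p2", "p3", "o"), cfg)
  }
  abba <- one(0L, 2L, 2L, 0L)
  expect_equal(abba$n_abba, 1)
  expect_equal(abba$n_baba, 0)
  baba <- one(2L, 0L, 2L, 0L)
  expect_equal(baba$n_baba, 1)
  conc <- one(2L, 2L, 0L, 0L)
  expect_equal(conc$n_concordant, 1)
  # heterozygous outgroup is excluded entirely
  het_o <- one(0L, 2L, 2L, 1L)
  expect_equal(het_o$n_sites_evaluated, 0)
  # derived state is "not the outgroup allele": works from an ALT outgroup
  alt_o <- one(2L, 0L, 0L, 2L)
  expect_equal(alt_o$n_abba, 1)

  expect_error(count_patterns(abba, c("p1", "p1", "p3", "o"), cfg),
               "distinct")
})

test_that("block counts equal a site-wise reclassification oracle", {
  withr::local_seed(88)
  n <- 1000
  g <- matrix(sample(c(0L, 1L, 2L, NA), 4 * n, TRUE,
                     prob = c(.4, .25, .25, .1)),
              ncol = 4, dimnames = list(NULL, c("p1", "p2", "p3", "o")))
  pos <- sort(sample.int(5e6, n))
  tab <- make_table(g, pos = pos, scaffold_len = 5e6)
  cfg <- dstat_config(block_size_bp = 1e6, min_scaffold_bp = 0, rng_seed = 11)
  got <- count_patterns(tab, c("p1", "p2", "p3", "o"), cfg)

  # oracle: reproduce the seeded per-individual draws, then classify each
  # site independently and tally per block in a plain loop
  set.seed(11)
  u <- matrix(runif(n * 3), ncol = 3)  # columns follow table sample order
  colnames(u) <- c("p1", "p2", "p3")
  tally <- list()
  for (i in seq_len(n)) {
    if (anyNA(g[i, ])) next
    go <- g[i, "o"]
    if (go == 1L) next
    anc <- if (go == 2L) 1L else 0L
    al <- vapply(c("p1", "p2", "p3"), function(id) {
      gi <- g[i, id]
      if (gi == 0L) 0L else if (gi == 2L) 1L
      else as.integer(u[i, id] < 0.5)
    }, integer(1))
    b <- al != anc
    cls <- if (!b[1] && b[2] && b[3]) "abba"
    else if (b[1] && !b[2] && b[3]) "baba"
    else if (b[1] && b[2] && !b[3]) "conc" else "none"
    blk <- as.character((pos[i] - 1) %/% 1e6)
    if (is.null(tally[[blk]])) tally[[blk]] <- c(abba = 0, baba = 0,
                                                 conc = 0, eval = 0)
    tally[[blk]]["eval"] <- tally[[blk]]["eval"] + 1
    if (cls != "none") tally[[blk]][substr(cls, 1, 4)] <-
        tally[[blk]][substr(cls, 1, 4)] + 1
  }
  for (r in seq_len(nrow(got))) {
    tb <- tally[[as.character(got$block[r])]]
    expect_equal(got$n_abba[r], unname(tb["abba"]))
    expect_equal(got$n_baba[r], unname(tb["baba"]))
    expect_equal(got$n_concordant[r], unname(tb["conc"]))
    expect_equal(got$n_sites_evaluated[r], unname(tb["eval"]))
  }
})

test_that("D is antisymmetric in P1/P2 and invariant to block size", {
  withr::local_seed(3)
  pt <- pattern_table(5000, 0.04, 0.02, 0.1)
  # add heterozygous sites so allele sampling is exercised
  pt$table$geno[sample(5000, 500), 1:3] <- 1L
  cfg <- dstat_config(block_size_bp = 2e6, min_scaffold_bp = 0, rng_seed = 9)
  r12 <- d_with_jackknife(count_patterns(pt$table, c("p1", "p2", "p3", "o"),
                                         cfg))
  r21 <- d_with_jackknife(count_patterns(pt$table, c("p2", "p1", "p3", "o"),
                                         cfg))
  expect_equal(r12$d, -r21$d, tolerance = 1e-12)
  expect_equal(r12$n_abba, r21$n_baba)

  cfg2 <- dstat_config(block_size_bp = 5e6, min_scaffold_bp = 0, rng_seed = 9)
  r_big <- d_with_jackknife(count_patterns(pt$table,
                                           c("p1", "p2", "p3", "o"), cfg2))
  expect_equal(r_big$d, r12$d, tolerance = 1e-12)  # pooled D unchanged
  expect_equal(r_big$n_abba + r_big$n_baba, r12$n_abba + r12$n_baba)
})

test_that("pooled D arithmetic hits the boundary cases", {
  mkblocks <- function(a, b) {
    k <- length(a)
    structure(data.frame(scaffold = "s", block = seq_len(k) - 1,
                         n_abba = a, n_baba = b, n_concordant = 0,
                         n_sites_evaluated = a + b + 10),
              class = c("pattern_blocks", "data.frame"))
  }
  expect_equal(d_with_jackknife(mkblocks(c(5, 5), c(5, 5)))$d, 0)
  expect_equal(d_with_jackknife(mkblocks(c(6, 4), c(0, 0)))$d, 1)
  expect_equal(d_with_jackknife(mkblocks(c(20, 10), c(4, 6)))$d, 0.5)
  expect_error(d_with_jackknife(mkblocks(c(10, 0), c(5, 0))),
               "jackknife undefined")
  expect_error(d_with_jackknife(mkblocks(c(0, 0), c(0, 0))), "no informative")
})

test_that("jackknife SE tracks the replicate spread under the null", {
  reps <- 100
  ds <- numeric(reps)
  ses <- numeric(reps)
  for (i in seq_len(reps)) {
    blk <- simulate_pattern_blocks(50, 2000, 0.02, 0.02, 0,
                                   rng_seed = 7000 + i)
    r <- d_with_jackknife(blk)
    ds[i] <- r$d
    ses[i] <- r$se
  }
  expect_lt(abs(sd(ds) - mean(ses)) / mean(ses), 0.30)
})

test_that("topology rotations flag admixture only when planted", {
  withr::local_seed(21)
  # concordant-dominated table, equal ABBA/BABA: true topology not rejected
  null_sig <- vapply(1:10, function(i) {
    pt <- pattern_table(20000, 0.01, 0.01, 0.08)
    res <- run_topology_tests(pt$table, c("p1", "p2", "p3", "o"),
                              dstat_config(block_size_bp = 2e6,
                                           min_scaffold_bp = 0,
                                           rng_seed = i))
    expect_equal(nrow(res), 3)
    res$significant[res$p1 == "p1" & res$p2 == "p2"]
  }, logical(1))
  expect_lte(mean(null_sig), 0.2)

  # strong P3 -> P2 excess: the true topology shows D > 0, |Z| > 3
  adm_hits <- vapply(1:10, function(i) {
    pt <- pattern_table(20000, 0.03, 0.01, 0.08)
    res <- run_topology_tests(pt$table, c("p1", "p2", "p3", "o"),
                              dstat_config(block_size_bp = 2e6,
                                           min_scaffold_bp = 0,
                                           rng_seed = 50 + i))
    row <- res[res$p1 == "p1" & res$p2 == "p2", ]
    row$d > 0 && row$significant
  }, logical(1))
  expect_gte(mean(adm_hits), 0.9)
})

test_that("short scaffolds are excluded from pattern counting", {
  g <- matrix(c(0L, 2L, 2L, 0L), 1, 4,
              dimnames = list(NULL, c("p1", "p2", "p3", "o")))
  tab <- make_table(g, pos = 500L, scaffold_len = 5e6)
  cfg <- dstat_config(min_scaffold_bp = 1e7, rng_seed = 2)
  expect_error(d_with_jackknife(count_patterns(tab, c("p1", "p2", "p3", "o"),
                                               cfg)),
               "no informative")
})
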