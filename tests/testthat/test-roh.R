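test_that("window rules force the expected runs on constructed strings", {
  cfg <- roh_config()  # 20 SNP window, 1 het, 1 missing, 1 kb

  # 30 homozygous sites spanning 2,000 bp -> exactly one run of 2,000 bp
  pos <- round(seq(1, 2000, length.out = 30))
  tab <- make_table(cbind(ind1 = rep(0L, 30)), pos = pos)
  runs <- scan_roh(tab, "ind1", cfg)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$length_bp, 2000)
  expect_equal(runs$n_het, 0)

  # 19 homozygous sites: fewer than the 20-site window -> nothing
  tab19 <- make_table(cbind(ind1 = rep(0L, 19)),
                      pos = round(seq(1, 5000, length.out = 19)))
  expect_equal(nrow(scan_roh(tab19, "ind1", cfg)), 0)

  # 25 homozygous sites with one het in the middle -> one run containing it
  g <- rep(0L, 26); g[13] <- 1L
  tab25 <- make_table(cbind(ind1 = g),
                      pos = round(seq(1, 1500, length.out = 26)))
  runs25 <- scan_roh(tab25, "ind1", cfg)
  expect_equal(nrow(runs25), 1)
  expect_equal(runs25$n_het, 1)
  expect_equal(runs25$length_bp, 1500)

  expect_error(scan_roh(tab, "nobody", cfg), "nobody")
})

test_that("scanner equals the exhaustive-interval oracle on random strings", {
  withr::local_seed(31)
  configs <- list(roh_config(window_snps = 5, min_length_bp = 50),
                  roh_config(window_snps = 20, min_length_bp = 1000))
  for (i in 1:20) {
    cfg <- configs[[(i %% 2) + 1]]
    s <- random_geno_string(sample(30:200, 1),
                            p_het = runif(1, 0.02, 0.3),
                            p_miss = runif(1, 0, 0.15))
    got <- scan_roh(make_table(cbind(ind1 = s$g), pos = s$pos), "ind1", cfg)
    want <- oracle_scan_roh(s$pos, s$g, cfg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_het, want$n_het)
      expect_equal(got$n_missing, want$n_missing)
    }
  }
})

test_that("runs are disjoint, scaffold-local, and respond monotonically", {
  withr::local_seed(57)
  for (i in 1:6) {
    s <- random_geno_string(200, p_het = 0.08, p_miss = 0.05)
    tab <- make_table(cbind(ind1 = s$g), pos = s$pos)
    cfg <- roh_config(window_snps = 8, min_length_bp = 200)
    runs <- scan_roh(tab, "ind1", cfg)
    if (nrow(runs) > 1)
      expect_true(all(runs$start_bp[-1] > runs$end_bp[-nrow(runs)]))
    expect_true(all(runs$n_het <= cfg$max_het_per_run))
    expect_true(all(runs$n_missing <= cfg$max_missing_per_run))
    expect_true(all(runs$n_sites - runs$n_het - runs$n_missing >=
                      cfg$window_snps))
    expect_true(all(runs$length_bp >= cfg$min_length_bp))

    # invariant to prepending a different scaffold
    other <- make_table(cbind(ind1 = rep(0L, 30)), scaffold = "s0")
    both <- genotype_table(
      scaffolds = rbind(other$scaffolds, tab$scaffolds),
      sites = rbind(other$sites, tab$sites),
      geno = rbind(other$geno, tab$geno),
      depth = rbind(other$depth, tab$depth))
    runs_b <- scan_roh(both, "ind1", cfg)
    expect_equal(runs_b[runs_b$scaffold == "s1", -1, drop = FALSE],
                 runs[, -1, drop = FALSE], ignore_attr = TRUE)

    # relaxing min_length never loses runs; tightening het cap never adds bp
    relaxed <- scan_roh(tab, "ind1", roh_config(window_snps = 8,
                                                min_length_bp = 0))
    expect_gte(nrow(relaxed), nrow(runs))
    strict <- scan_roh(tab, "ind1", roh_config(window_snps = 8,
                                               max_het_per_run = 0,
                                               min_length_bp = 200))
    expect_lte(sum(strict$length_bp), sum(runs$length_bp))
  }
})

test_that("summaries aggregate the four ROH parameters exactly", {
  s <- summarize_roh(roh_df(c(1e3, 2e3, 3e3)), genome_size_bp = 2.4e9)
  expect_equal(s$n_roh, 3)
  expect_equal(s$mean_length_bp, 2e3)
  expect_equal(s$total_length_bp, 6e3)
  expect_equal(s$f_roh, 2.5e-6)
  expect_equal(s$sd_length_bp, sd(c(1e3, 2e3, 3e3)))

  # a run set totalling 0.088 of a 2.4 Gb genome gives F_ROH = 0.088
  lens <- rep(0.088 * 2.4e9 / 1000, 1000)
  expect_equal(summarize_roh(roh_df(lens))$f_roh, 0.088)

  z <- summarize_roh(roh_df(numeric(0)))
  expect_equal(z$n_roh, 0)
  expect_equal(z$total_length_bp, 0)
  expect_equal(z$f_roh, 0)
  expect_equal(z$mean_length_bp, 0)
})

test_that("Welch comparison matches the textbook statistic and calibrates", {
  same <- roh_df(c(1, 2, 3, 4, 5) * 1e3)
  res0 <- compare_mean_length(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)

  a <- c(1, 2, 3, 4, 5) * 1e3
  b <- c(10, 20, 30, 40, 50) * 1e3
  got <- compare_mean_length(roh_df(a), roh_df(b))
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)

  expect_error(compare_mean_length(roh_df(1e3), roh_df(a)), ">= 2 runs")

  # p-values uniform under the null
  withr::local_seed(77)
  pvals <- replicate(1000, {
    compare_mean_length(roh_df(rexp(500, 1e-4)),
                        roh_df(rexp(500, 1e-4)))$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("KS comparison matches the brute-force CDF-gap oracle", {
  same <- roh_df(c(1, 5, 9) * 1e3)
  res <- compare_length_distributions(same, same)
  expect_equal(res$d_ks, 0)
  expect_equal(res$p_value, 1)

  disjoint <- compare_length_distributions(roh_df(1:5), roh_df(101:105))
  expect_equal(disjoint$d_ks, 1)

  withr::local_seed(13)
  for (i in 1:15) {
    x <- rexp(sample(3:20, 1), 1e-4)
    y <- rexp(sample(3:20, 1), 2e-4)
    got <- compare_length_distributions(roh_df(x), roh_df(y))
    expect_equal(got$d_ks, oracle_ks_stat(x, y), tolerance = 1e-12)
  }
  expect_error(compare_length_distributions(roh_df(numeric(0)), roh_df(1)),
               "non-empty")
})

test_that("planted autozygous fractions are recovered by F_ROH", {
  sim <- simulate_diploid_table(
    diploid_sim_config(scaffold_lengths = 1e7, planted_tract_fraction = 0.10,
                       rng_seed = 97), 1)
  runs <- scan_roh(sim$table, "ind1")
  f <- summarize_roh(runs, genome_size_bp = 1e7)$f_roh
  expect_lt(abs(f - 0.10), 0.02)
})

test_that("ROH BED export is 0-based half-open", {
  runs <- scan_roh(make_table(cbind(ind1 = rep(0L, 30)),
                              pos = round(seq(1, 2000, length.out = 30))),
                   "ind1")
  path <- tempfile(fileext = ".bed")
  write_roh_bed(runs, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, runs$start_bp - 1)
  expect_equal(bed$V3, runs$end_bp)
})
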