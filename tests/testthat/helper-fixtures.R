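# Shared builders and independent oracles for the test suite.

# Build a genotype_table from genotype codes (vector or matrix; NA = missing).
make_table <- function(codes, pos = NULL, scaffold = "s1",
                       scaffold_len = NULL, depth = 30L,
                       ref = "A", alt = "C") {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("ind", seq_len(ncol(codes)))
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(scaffold_len)) scaffold_len <- max(pos) + 1000
  genotype_table(
    scaffolds = data.frame(scaffold = scaffold, length = scaffold_len),
    sites = data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt),
    geno = codes,
    depth = matrix(depth, n, ncol(codes),
                   dimnames = list(NULL, colnames(codes))))
}

# Full-coverage mask for every sample over every scaffold of a table.
full_mask <- function(table) {
  callable_mask(do.call(rbind, lapply(table$samples, function(sm)
    data.frame(sample = sm, scaffold = table$scaffolds$scaffold,
               start = 0, end = table$scaffolds$length))))
}

# Handwritten VCF text for ingestion tests (3 samples unless overridden).
write_test_vcf <- function(path, records, samples = c("A", "B", "C"),
                           contigs = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             if (!is.null(contigs))
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

# --- brute-force run-of-homozygosity oracle -------------------------------
# Naive re-implementation of the scan semantics: eligibility by direct
# counting, window unions by explicit grouping, and per-candidate emission by
# exhaustive enumeration of every subinterval (max site count, leftmost on
# ties), recursing on the remainders.
oracle_scan_roh <- function(pos, g, config) {
  w <- config$window_snps
  n <- length(g)
  state <- ifelse(is.na(g), "M", ifelse(g == 1L, "H", "O"))
  out <- list()
  valid <- function(a, b) {
    s <- state[a:b]
    sum(s == "H") <= config$max_het_per_run &&
      sum(s == "M") <= config$max_missing_per_run &&
      sum(s == "O") >= w &&
      pos[b] - pos[a] + 1 >= config$min_length_bp
  }
  emit <- function(i, j) {
    if (j - i + 1 < w) return(invisible())
    best <- NULL
    for (a in i:j) for (b in a:j) {
      if ((is.null(best) || (b - a + 1) > (best[2] - best[1] + 1)) &&
          valid(a, b))
        best <- c(a, b)
    }
    if (is.null(best)) return(invisible())
    emit(i, best[1] - 1)
    out[[length(out) + 1]] <<- data.frame(
      start_bp = pos[best[1]], end_bp = pos[best[2]],
      n_sites = best[2] - best[1] + 1,
      n_het = sum(state[best[1]:best[2]] == "H"),
      n_missing = sum(state[best[1]:best[2]] == "M"),
      length_bp = pos[best[2]] - pos[best[1]] + 1)
    emit(best[2] + 1, j)
  }
  if (n >= w) {
    elig <- vapply(1:(n - w + 1), function(i) {
      s <- state[i:(i + w - 1)]
      sum(s == "H") <= config$max_het_per_run &&
        sum(s == "M") <= config$max_missing_per_run
    }, logical(1))
    starts <- which(elig)
    cur <- integer(0)
    flush <- function(cur) {
      if (length(cur) > 0) emit(cur[1], cur[length(cur)] + w - 1)
    }
    for (s in starts) {
      if (length(cur) == 0 || s - cur[length(cur)] <= w - 1) cur <- c(cur, s)
      else { flush(cur); cur <- s }
    }
    flush(cur)
  }
  if (length(out) == 0)
    data.frame(start_bp = numeric(), end_bp = numeric(), n_sites = integer(),
               n_het = integer(), n_missing = integer(),
               length_bp = numeric())
  else do.call(rbind, out)
}

# Random genotype string with adjustable composition, plus positions.
random_geno_string <- function(n, p_het, p_miss, max_gap = 300) {
  g <- sample(c(0L, 1L, NA_integer_), n, replace = TRUE,
              prob = c(1 - p_het - p_miss, p_het, p_miss))
  pos <- cumsum(sample.int(max_gap, n, replace = TRUE))
  list(pos = pos, g = g)
}

# --- brute-force two-sample KS statistic ----------------------------------
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  f1 <- vapply(pts, function(p) mean(x <= p), numeric(1))
  f2 <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(f1 - f2))
}

# --- textbook Welch statistic ---------------------------------------------
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p)
}

roh_df <- function(lengths) data.frame(length_bp = lengths)
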