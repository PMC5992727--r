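#' Diploid genotype table
#'
#' The central container for all analyses: per-site, per-individual diploid
#' genotype calls with read depth, on a shared site grid produced by joint
#' calling. Genotype states are coded `0` (homozygous reference), `1`
#' (heterozygous), `2` (homozygous alternate) and `NA` (missing). Positions
#' are 1-based and strictly increasing within a scaffold, with exactly one
#' record per (scaffold, position).
#'
#' @param scaffolds data.frame with columns `scaffold` (character) and
#'   `length` (bp).
#' @param sites data.frame with columns `scaffold`, `pos` (1-based integer),
#'   `ref`, `alt` (allele strings; a comma in `alt` marks a multi-allelic
#'   record).
#' @param geno integer matrix, sites x samples, coded 0/1/2/NA; column names
#'   are the sample identifiers.
#' @param depth integer matrix of per-call read depths, same shape as `geno`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(scaffolds, sites, geno, depth) {
  scaffolds <- data.frame(scaffold = as.character(scaffolds$scaffold),
                          length = as.numeric(scaffolds$length))
  sites <- data.frame(scaffold = as.character(sites$scaffold),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt))
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  storage.mode(geno) <- "integer"
  storage.mode(depth) <- "integer"
  if (is.null(colnames(geno))) stop("geno must have sample ids as column names")
  if (!identical(dim(geno), dim(depth)))
    stop("geno and depth must have identical dimensions")
  if (nrow(geno) != nrow(sites))
    stop("geno must have one row per site")
  if (anyNA(sites$pos) || any(sites$pos < 1))
    stop("positions must be positive integers")
  unknown <- setdiff(unique(sites$scaffold), scaffolds$scaffold)
  if (length(unknown) > 0)
    stop("sites reference undeclared scaffold(s): ",
         paste(unknown, collapse = ", "))
  if (any(!is.na(depth) & depth < 0)) stop("depths must be >= 0")
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == sc]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on scaffold ", sc)
  }
  structure(list(scaffolds = scaffolds, sites = sites, geno = geno,
                 depth = depth, samples = colnames(geno)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites,", length(x$samples),
      "samples,", nrow(x$scaffolds), "scaffolds\n")
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

gt_code <- function(gt) {
  # "0/0" -> 0, "0/1"/"1/0" -> 1, "1/1" -> 2, anything with "." -> NA
  out <- rep(NA_integer_, length(gt))
  gt <- gsub("\\|", "/", gt)
  out[gt %in% "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% "1/1"] <- 2L
  out
}

code_gt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Read a genotype table from a VCF file
#'
#' Ingests jointly called biallelic SNP genotypes (GT) and per-sample depths
#' (DP). Scaffold lengths are taken from `##contig` header lines when present,
#' otherwise from the largest observed position per scaffold.
#'
#' @param path path to a VCF file (plain text).
#' @param sample_ids samples to retain, in the requested order; `NULL` keeps
#'   all samples in header order. A requested sample absent from the header is
#'   an error naming the sample.
#' @param biallelic_only drop records whose ALT field holds more than one
#'   allele (default `TRUE`).
#' @return A [genotype_table].
#' @export
read_genotype_table <- function(path, sample_ids = NULL, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  if (is.null(sample_ids)) sample_ids <- have
  absent <- setdiff(sample_ids, have)
  if (length(absent) > 0)
    stop("sample(s) not present in VCF: ", paste(absent, collapse = ", "))

  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("malformed VCF record: non-numeric POS at data line ",
                       which(is.na(pos))[1])
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only)
    keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) & fix$ALT != "."

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gt <- gt[, sample_ids, drop = FALSE]
  dp <- dp[, sample_ids, drop = FALSE]
  geno <- apply(gt, 2, gt_code)
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = length(sample_ids))
  colnames(geno) <- sample_ids
  dp[is.na(dp)] <- 0
  depth <- matrix(as.integer(dp), ncol = length(sample_ids),
                  dimnames = list(NULL, sample_ids))

  # contig lengths from the header if declared
  meta <- v@meta
  contig <- meta[grepl("^##contig=", meta)]
  ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
  scafs <- unique(fix$CHROM)
  length_of <- stats::setNames(rep(NA_real_, length(scafs)), scafs)
  known <- intersect(scafs, ids[!is.na(lens)])
  length_of[known] <- lens[match(known, ids)]
  for (sc in scafs[is.na(length_of[scafs])])
    length_of[sc] <- max(pos[fix$CHROM == sc])

  genotype_table(
    scaffolds = data.frame(scaffold = scafs, length = as.numeric(length_of)),
    sites = data.frame(scaffold = fix$CHROM, pos = pos,
                       ref = fix$REF, alt = fix$ALT)[keep, , drop = FALSE],
    geno = geno[keep, , drop = FALSE],
    depth = depth[keep, , drop = FALSE]
  )
}

#' Write a genotype table as VCF text
#'
#' Emits a minimal VCFv4.2 file (GT:DP per sample, contig header lines) that
#' round-trips through [read_genotype_table] with states, positions and depths
#' preserved exactly.
#'
#' @param table a [genotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", table$scaffolds$scaffold,
                   as.integer(table$scaffolds$length)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", table$samples), collapse = "\t"))
  n <- nrow(table$sites)
  cells <- matrix("", n, length(table$samples))
  for (j in seq_along(table$samples))
    cells[, j] <- paste0(code_gt(table$geno[, j]), ":", table$depth[, j])
  body <- paste(table$sites$scaffold, table$sites$pos, ".", table$sites$ref,
                table$sites$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  if (n == 0) body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site filter configuration
#'
#' Site- and call-level filters applied before any statistic: calls below a
#' minimum read depth are treated as missing (the grid of sites stays aligned
#' across individuals), whole scaffolds can be excluded (e.g. X-linked
#' scaffolds that would bias autosomal statistics), and multi-allelic records
#' can be dropped.
#'
#' @param min_depth minimum per-call read depth; shallower calls become
#'   missing. Default 20 reads.
#' @param excluded_scaffolds character vector of scaffold ids to drop.
#' @param biallelic_only drop multi-allelic records (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 20, excluded_scaffolds = character(),
                          biallelic_only = TRUE) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  structure(list(min_depth = min_depth,
                 excluded_scaffolds = as.character(excluded_scaffolds),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_config")
}

#' Apply depth and scaffold filters to a genotype table
#'
#' Calls with depth below `config$min_depth` are set to missing for that
#' individual only; sites on excluded scaffolds are dropped entirely and the
#' scaffold list shrinks accordingly. Applying the same configuration twice is
#' a no-op.
#'
#' @param table a [genotype_table].
#' @param config a [filter_config].
#' @return The filtered [genotype_table].
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "genotype_table"), inherits(config, "filter_config"))
  geno <- table$geno
  geno[table$depth < config$min_depth] <- NA_integer_
  keep <- !(table$sites$scaffold %in% config$excluded_scaffolds)
  if (config$biallelic_only)
    keep <- keep & !grepl(",", table$sites$alt)
  scaf <- table$scaffolds[!(table$scaffolds$scaffold %in%
                              config$excluded_scaffolds), , drop = FALSE]
  genotype_table(scaffolds = scaf,
                 sites = table$sites[keep, , drop = FALSE],
                 geno = geno[keep, , drop = FALSE],
                 depth = table$depth[keep, , drop = FALSE])
}

#' Per-individual callable-site mask
#'
#' Holds, for each individual and scaffold, the merged set of 0-based
#' half-open intervals deemed callable (e.g. at or above the depth cutoff),
#' plus the total callable bp per individual. The mask is the denominator of
#' genome-wide heterozygosity; it is an independent input, not derived from
#' the variant records.
#'
#' @param intervals data.frame with columns `sample`, `scaffold`, `start`
#'   (0-based), `end` (exclusive). Overlapping or adjacent intervals are
#'   merged.
#' @return An object of class `callable_mask` with elements `intervals` and
#'   `callable_total` (named by sample).
#' @export
callable_mask <- function(intervals) {
  intervals <- data.frame(sample = as.character(intervals$sample),
                          scaffold = as.character(intervals$scaffold),
                          start = as.numeric(intervals$start),
                          end = as.numeric(intervals$end))
  if (any(intervals$end <= intervals$start))
    stop("mask interval with end <= start")
  merged <- list()
  for (sm in unique(intervals$sample)) {
    for (sc in unique(intervals$scaffold[intervals$sample == sm])) {
      iv <- intervals[intervals$sample == sm & intervals$scaffold == sc, ]
      r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1, end = iv$end))
      merged[[length(merged) + 1L]] <-
        data.frame(sample = sm, scaffold = sc,
                   start = IRanges::start(r) - 1, end = IRanges::end(r))
    }
  }
  merged <- if (length(merged)) do.call(rbind, merged) else
    data.frame(sample = character(), scaffold = character(),
               start = numeric(), end = numeric())
  totals <- tapply(merged$end - merged$start, merged$sample, sum)
  structure(list(intervals = merged,
                 callable_total = stats::setNames(as.numeric(totals),
                                                  names(totals))),
            class = "callable_mask")
}

#' Read callable masks from BED files
#'
#' One BED file per individual, 0-based half-open intervals. Intervals are
#' merged; `callable_total` is the summed length per individual.
#'
#' @param paths named character vector mapping sample id to BED path.
#' @param scaffolds optional character vector of known scaffold ids; an
#'   interval on any other scaffold is an error.
#' @return A [callable_mask].
#' @export
read_callable_mask <- function(paths, scaffolds = NULL) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by sample id")
  rows <- list()
  for (sm in names(paths)) {
    if (file.size(paths[[sm]]) == 0) next
    bed <- utils::read.table(paths[[sm]], sep = "\t",
                             col.names = c("scaffold", "start", "end"),
                             colClasses = c("character", "numeric", "numeric"))
    if (any(bed$end <= bed$start))
      stop("BED interval with end <= start in ", paths[[sm]])
    if (!is.null(scaffolds)) {
      bad <- setdiff(unique(bed$scaffold), scaffolds)
      if (length(bad) > 0)
        stop("unknown scaffold(s) in ", paths[[sm]], ": ",
             paste(bad, collapse = ", "))
    }
    rows[[sm]] <- data.frame(sample = sm, bed)
  }
  if (length(rows) == 0)
    return(structure(list(intervals = data.frame(sample = character(),
                                                 scaffold = character(),
                                                 start = numeric(),
                                                 end = numeric()),
                          callable_total = stats::setNames(
                            rep(0, length(paths)), names(paths))),
                     class = "callable_mask"))
  m <- callable_mask(do.call(rbind, rows))
  # individuals whose BED was empty still get a zero total
  missing <- setdiff(names(paths), names(m$callable_total))
  m$callable_total[missing] <- 0
  m
}

# Total callable bp for one individual (0 when absent from the mask).
mask_total <- function(mask, individual) {
  tot <- mask$callable_total[individual]
  if (is.na(tot)) 0 else as.numeric(tot)
}

# Logical vector: is each 1-based position inside the individual's mask on
# the given scaffold?
mask_contains <- function(mask, individual, scaffold, pos) {
  iv <- mask$intervals[mask$intervals$sample == individual &
                         mask$intervals$scaffold == scaffold, , drop = FALSE]
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(start = pos, end = pos)
  s <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
  IRanges::overlapsAny(q, s)
}

# bp of overlap between the individual's mask and a set of 1-based inclusive
# intervals given as data.frame(scaffold, start_bp, end_bp).
mask_overlap_bp <- function(mask, individual, regions) {
  if (nrow(regions) == 0) return(0)
  tot <- 0
  for (sc in unique(regions$scaffold)) {
    iv <- mask$intervals[mask$intervals$sample == individual &
                           mask$intervals$scaffold == sc, , drop = FALSE]
    if (nrow(iv) == 0) next
    r <- regions[regions$scaffold == sc, , drop = FALSE]
    ov <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(start = r$start_bp, end = r$end_bp)),
      IRanges::IRanges(start = iv$start + 1, end = iv$end))
    tot <- tot + sum(IRanges::width(ov))
  }
  tot
}
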