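#' Export heterozygous-site records for coalescent demographic inference
#'
#' Builds the per-individual input consumed by sequentially-Markovian
#' coalescent tools (PSMC'/MSMC family): one record per heterozygous site on
#' retained scaffolds, each carrying the number of callable sites since the
#' previous record (counted from the callable mask). Heterozygous sites
#' outside the mask are not callable and are skipped. Only scaffolds of at
#' least `min_scaffold_bp` are retained (default 30 Mb, long enough to
#' observe past recombination events).
#'
#' @param table a [genotype_table].
#' @param mask a [callable_mask].
#' @param individual sample id.
#' @param min_scaffold_bp scaffold length cutoff.
#' @return An object of class `hetsep_track`: data.frame with columns
#'   `scaffold`, `pos`, `n_since` (callable sites since previous record),
#'   `alleles` (unphased genotype pair, e.g. "AC"); scaffold lengths are kept
#'   in `attr(, "scaffold_lengths")`.
#' @export
export_hetsep <- function(table, mask, individual, min_scaffold_bp = 30e6) {
  if (!individual %in% table$samples) stop("unknown individual: ", individual)
  keep <- table$scaffolds[table$scaffolds$length >= min_scaffold_bp, ,
                          drop = FALSE]
  if (nrow(keep) == 0)
    stop("no scaffold passes the ", min_scaffold_bp, " bp length filter")
  g <- table$geno[, individual]
  rows <- list()
  for (sc in keep$scaffold) {
    iv <- mask$intervals[mask$intervals$sample == individual &
                           mask$intervals$scaffold == sc, , drop = FALSE]
    idx <- which(table$sites$scaffold == sc & !is.na(g) & g == 1L)
    if (length(idx) == 0 || nrow(iv) == 0) next
    pos <- table$sites$pos[idx]
    inside <- mask_contains(mask, individual, sc, pos)
    idx <- idx[inside]; pos <- pos[inside]
    if (length(idx) == 0) next
    # cumulative callable sites up to and including position p
    iv <- iv[order(iv$start), , drop = FALSE]
    cum_before <- cumsum(c(0, iv$end - iv$start))
    callable_upto <- function(p) {
      k <- findInterval(p, iv$start + 1)  # last interval starting at/below p
      ifelse(k == 0, 0, cum_before[k] + pmin(p, iv$end[k]) - iv$start[k])
    }
    cu <- callable_upto(pos)
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = sc, pos = pos, n_since = as.integer(diff(c(0, cu))),
      alleles = paste0(table$sites$ref[idx], table$sites$alt[idx]))
  }
  track <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), pos = integer(), n_since = integer(),
               alleles = character())
  rownames(track) <- NULL
  attr(track, "scaffold_lengths") <-
    stats::setNames(keep$length, keep$scaffold)
  class(track) <- c("hetsep_track", "data.frame")
  track
}

#' Write a heterozygous-site track in multihetsep format
#'
#' Tab-separated, no header: scaffold, position, callable-sites-since-last,
#' genotype pair.
#'
#' @param track a `hetsep_track` from [export_hetsep].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hetsep <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("scaffold", "pos", "n_since",
                                              "alleles")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a multihetsep text file
#'
#' @param path input path.
#' @param scaffold_lengths optional named numeric vector of scaffold lengths
#'   to attach to the track.
#' @return A `hetsep_track`.
#' @export
read_hetsep <- function(path, scaffold_lengths = NULL) {
  track <- utils::read.table(path, sep = "\t",
                             col.names = c("scaffold", "pos", "n_since",
                                           "alleles"),
                             colClasses = c("character", "integer", "integer",
                                            "character"))
  attr(track, "scaffold_lengths") <- scaffold_lengths
  class(track) <- c("hetsep_track", "data.frame")
  track
}

#' Bootstrap resampling of a heterozygous-site track
#'
#' For each replicate and each scaffold of length L, draws floor(L / chunk_bp)
#' chunk start offsets uniformly at random with replacement, extracts the
#' chunk windows, re-indexes positions onto a pseudo-scaffold and
#' concatenates, so each replicate's total length matches the original
#' retained length. Records keep their own callable-sites-since-last counts
#' (capped at the re-indexed positional gap); chunk-boundary counts are
#' therefore approximate, the usual convention for this resampling scheme.
#'
#' @param track a `hetsep_track` with scaffold lengths attached.
#' @param n_replicates number of bootstrap datasets (default 20).
#' @param chunk_bp chunk length (default 5 Mb).
#' @param rng_seed seed; identical seeds give byte-identical replicates.
#' @return List of `hetsep_track` objects of length `n_replicates`.
#' @export
bootstrap_datasets <- function(track, n_replicates = 20, chunk_bp = 5e6,
                               rng_seed = 1L) {
  lens <- attr(track, "scaffold_lengths")
  if (is.null(lens)) stop("track carries no scaffold lengths")
  short <- names(lens)[lens < chunk_bp]
  if (length(short) > 0)
    stop("chunk_bp exceeds scaffold length for: ",
         paste(short, collapse = ", "))
  with_seed(rng_seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      rows <- list()
      for (sc in names(lens)) {
        L <- lens[[sc]]
        k <- floor(L / chunk_bp)
        offs <- floor(stats::runif(k, 0, L - chunk_bp + 1))
        tsc <- track[track$scaffold == sc, , drop = FALSE]
        prev_pos <- 0
        for (c_i in seq_len(k)) {
          s <- offs[c_i]
          sel <- tsc$pos > s & tsc$pos <= s + chunk_bp
          if (!any(sel)) next
          chunk <- tsc[sel, , drop = FALSE]
          new_pos <- (c_i - 1) * chunk_bp + (chunk$pos - s)
          gaps <- diff(c(prev_pos, new_pos))
          chunk$n_since <- as.integer(pmin(chunk$n_since, gaps))
          chunk$pos <- as.integer(new_pos)
          prev_pos <- new_pos[length(new_pos)]
          rows[[length(rows) + 1L]] <- chunk
        }
      }
      out <- if (length(rows)) do.call(rbind, rows) else
        track[0, , drop = FALSE]
      rownames(out) <- NULL
      attr(out, "scaffold_lengths") <-
        stats::setNames(floor(lens / chunk_bp) * chunk_bp, names(lens))
      class(out) <- c("hetsep_track", "data.frame")
      out
    })
  })
}

#' Rescale coalescent-inference output to years and effective sizes
#'
#' Sequentially-Markovian coalescent tools report time boundaries in expected
#' mutations per site and coalescence rates lambda in the same scaled units.
#' This converts them with the convention: years = scaled_time /
#' substitution_rate_per_year, and diploid Ne = 1 / (2 * lambda *
#' mu_per_generation). Tracks at the substitution-rate credibility bounds are
#' emitted alongside the point track (higher rate means more recent times and
#' smaller Ne).
#'
#' @param segments data.frame with columns `left_time`, `right_time` (scaled,
#'   non-decreasing) and `lambda` (> 0).
#' @param rates a [rate_config].
#' @return List of class `demography_track` with `track` (data.frame:
#'   `start_years`, `end_years`, `ne`), `ci` (same shape at the lower/upper
#'   rate bound), and `rates`.
#' @export
scale_segments <- function(segments, rates = rate_config()) {
  if (any(segments$lambda <= 0)) stop("lambda must be > 0")
  if (is.unsorted(segments$left_time) ||
      any(segments$right_time < segments$left_time))
    stop("segment times must be non-decreasing")
  one <- function(rate_per_year) {
    mu_gen <- rate_per_year * rates$generation_time_years
    data.frame(start_years = segments$left_time / rate_per_year,
               end_years = segments$right_time / rate_per_year,
               ne = 1 / (2 * segments$lambda * mu_gen))
  }
  structure(list(track = one(rates$substitution_rate_per_year),
                 ci = list(low_rate = one(rates$rate_ci[1]),
                           high_rate = one(rates$rate_ci[2])),
                 rates = rates),
            class = "demography_track")
}
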