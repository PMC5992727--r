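#' Environmental tolerance envelope for one variable
#'
#' A trapezoid over the variable's axis: suitability 0 outside
#' `[absolute_min, absolute_max]`, 1 inside `[preferred_min, preferred_max]`,
#' linear on the two shoulders. Units are whatever the variable uses
#' (degrees C, metres, psu, ...).
#'
#' @param variable variable name (must match a layer name).
#' @param absolute_min,preferred_min,preferred_max,absolute_max envelope
#'   bounds, non-decreasing in that order.
#' @return An object of class `envelope`.
#' @export
envelope <- function(variable, absolute_min, preferred_min, preferred_max,
                     absolute_max) {
  b <- c(absolute_min, preferred_min, preferred_max, absolute_max)
  if (is.unsorted(b)) stop("envelope bounds must be non-decreasing")
  structure(list(variable = variable, absolute_min = absolute_min,
                 preferred_min = preferred_min, preferred_max = preferred_max,
                 absolute_max = absolute_max),
            class = "envelope")
}

#' Trapezoidal suitability of a value under an envelope
#'
#' Vectorized over `value`. At a degenerate shoulder (absolute bound equal to
#' the preferred bound) the closed preferred interval wins: the shared bound
#' scores 1.
#'
#' @param value numeric values in the envelope's units (NA passes through).
#' @param env an [envelope].
#' @return Suitability in [0, 1], same length as `value`.
#' @export
trapezoid_suitability <- function(value, env) {
  s <- numeric(length(value))
  s[value >= env$preferred_min & value <= env$preferred_max] <- 1
  left <- value > env$absolute_min & value < env$preferred_min
  s[left] <- (value[left] - env$absolute_min) /
    (env$preferred_min - env$absolute_min)
  right <- value > env$preferred_max & value < env$absolute_max
  s[right] <- (env$absolute_max - value[right]) /
    (env$absolute_max - env$preferred_max)
  s[is.na(value)] <- NA_real_
  s
}

#' Combine environmental layers into a habitat-suitability grid
#'
#' Scores each cell of each layer with its variable's trapezoid envelope and
#' combines across variables by the chosen rule. A cell missing (NA) in any
#' layer is missing in the output; a zero score under either rule
#' annihilates the cell.
#'
#' @param layers named list of numeric matrices sharing one lattice shape
#'   (NA marks land/no-data).
#' @param envelopes named list of [envelope]s, one per layer name.
#' @param combine `"product"` (default) or `"geometric_mean"`.
#' @return Matrix of suitabilities in [0, 1] with NA where any input is NA.
#' @export
grid_suitability <- function(layers, envelopes,
                             combine = c("product", "geometric_mean")) {
  combine <- match.arg(combine)
  if (length(layers) == 0) stop("no layers supplied")
  shp <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), shp))
      stop("layer shape mismatch: ", nm)
    if (is.null(envelopes[[nm]]))
      stop("missing envelope for layer: ", nm)
  }
  scored <- lapply(names(layers), function(nm) {
    m <- layers[[nm]]
    matrix(trapezoid_suitability(as.vector(m), envelopes[[nm]]),
           nrow = shp[1])
  })
  prod_grid <- Reduce(`*`, scored)
  if (combine == "product") prod_grid
  else prod_grid^(1 / length(scored))
}

#' Read a headered ASCII grid
#'
#' The plain-text GIS interchange format: six header lines (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by nrows rows of
#' ncols values, row 1 being the northernmost. NODATA cells become NA.
#'
#' @param path input path.
#' @return Numeric matrix with the header fields in `attr(, "header")`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  attr(m, "header") <- hdr
  m
}

#' Write a matrix as a headered ASCII grid
#'
#' @param m numeric matrix (NA written as the NODATA value).
#' @param path output path.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell size in coordinate units.
#' @param nodata_value sentinel for missing cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata_value = -9999) {
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata_value))
  m[is.na(m)] <- nodata_value
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
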