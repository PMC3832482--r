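#' Rectangular study region
#'
#' A planar rectangular window, in kilometres on a projected coordinate
#' system. All point patterns, rasters and quadrature schemes in ppmbias
#' live inside such a region; intensity is expressed per square kilometre.
#' Geographic (lon/lat) coordinates are not handled; projecting is the
#' user's responsibility.
#'
#' @param x_min,x_max,y_min,y_max region bounds in km; `x_max > x_min`,
#'   `y_max > y_min`.
#' @return An object of class `"region"`.
#' @export
region <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), is.numeric(y_min),
            is.numeric(y_max))
  if (!(x_max > x_min && y_max > y_min))
    stop("invalid region: need x_max > x_min and y_max > y_min")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "region")
}

#' Area of a region in square kilometres
#' @param r a [region()].
#' @return numeric scalar, km^2.
#' @export
region_area <- function(r) {
  stopifnot(inherits(r, "region"))
  (r$x_max - r$x_min) * (r$y_max - r$y_min)
}

inside_region <- function(r, x, y) {
  x >= r$x_min & x <= r$x_max & y >= r$y_min & y <= r$y_max
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region: [%g, %g] x [%g, %g] km, area %g km^2\n",
              x$x_min, x$x_max, x$y_min, x$y_max, region_area(x)))
  invisible(x)
}

#' Presence-only point pattern
#'
#' Planar presence locations with a species label per point, inside a
#' rectangular region. Points on the region boundary are inside.
#'
#' @param x,y numeric coordinates in km.
#' @param species character/factor label per point (recycled if length 1).
#' @param region a [region()]; defaults to the bounding box of the points.
#'   Required when the pattern is empty.
#' @return An object of class `"point_pattern"`.
#' @export
point_pattern <- function(x, y, species = "sp", region = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(species) == 1L) species <- rep(species, length(x))
  stopifnot(length(species) == length(x))
  if (is.null(region)) {
    if (length(x) == 0L)
      stop("an explicit region is required for an empty pattern")
    region <- region(min(x), max(max(x), min(x) + 1e-9),
                     min(y), max(max(y), min(y) + 1e-9))
  }
  bad <- which(!inside_region(region, x, y))
  if (length(bad))
    stop("points outside the region at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  structure(list(x = x, y = y, species = as.character(species),
                 region = region),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, %d species\n",
              length(x$x), length(unique(x$species))))
  print(x$region)
  invisible(x)
}

#' Number of points (optionally per species)
#' @param pattern a [point_pattern()].
#' @param by_species if `TRUE`, return a named per-species count table.
#' @return integer scalar or named integer vector.
#' @export
npoints <- function(pattern, by_species = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (by_species) table(pattern$species) else length(pattern$x)
}

#' Subset a point pattern by species
#' @param pattern a [point_pattern()].
#' @param species labels to keep (`keep = TRUE`) or drop (`keep = FALSE`).
#' @param keep keep or drop the named species.
#' @return a [point_pattern()] over the same region.
#' @export
subset_species <- function(pattern, species, keep = TRUE) {
  sel <- pattern$species %in% species
  if (!keep) sel <- !sel
  structure(list(x = pattern$x[sel], y = pattern$y[sel],
                 species = pattern$species[sel], region = pattern$region),
            class = "point_pattern")
}

#' Read presence points from CSV
#'
#' Expects a header row with columns `x`, `y`, `species` (extra columns are
#' ignored). Coordinates are planar km.
#'
#' @param path CSV file path.
#' @param region optional explicit [region()]; points outside it are an
#'   error. Without it the bounding box of the points is used (an empty file
#'   then errors, since no region can be inferred).
#' @return a [point_pattern()].
#' @export
read_points <- function(path, region = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "species")
  if (!all(need %in% names(df)))
    stop("points file must have columns x, y, species: ", path)
  if (nrow(df)) {
    badx <- which(!is.finite(suppressWarnings(as.numeric(df$x))))
    bady <- which(!is.finite(suppressWarnings(as.numeric(df$y))))
    bad <- sort(unique(c(badx, bady)))
    if (length(bad))
      stop("non-numeric coordinates at data line(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), " of ", path)
  }
  point_pattern(as.numeric(df$x), as.numeric(df$y),
                if (nrow(df)) df$species else character(0), region = region)
}

#' Presence/absence validation sites
#'
#' @param x,y site coordinates in km.
#' @param presence 0/1 outcome per site.
#' @param region optional [region()] (bounding box default).
#' @return an object of class `"pa_pattern"`.
#' @export
pa_pattern <- function(x, y, presence, region = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  presence <- as.integer(presence)
  stopifnot(length(x) == length(y), length(presence) == length(x))
  if (!all(presence %in% c(0L, 1L)))
    stop("presence outcomes must be 0 or 1")
  if (is.null(region)) {
    if (!length(x)) stop("an explicit region is required for empty PA data")
    region <- region(min(x), max(x), min(y), max(y))
  }
  bad <- which(!inside_region(region, x, y))
  if (length(bad))
    stop("PA sites outside the region at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  structure(list(x = x, y = y, presence = presence, region = region),
            class = "pa_pattern")
}

#' Read presence/absence sites from CSV (columns `x,y,presence`)
#' @inheritParams read_points
#' @return a [pa_pattern()].
#' @export
read_pa <- function(path, region = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "presence") %in% names(df)))
    stop("PA file must have columns x, y, presence: ", path)
  pa_pattern(df$x, df$y, df$presence, region = region)
}
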