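#' Aligned covariate raster stack
#'
#' A set of covariate layers on a shared regular grid, each tagged with a
#' role: `"environmental"` (enters the model linearly and quadratically) or
#' `"bias"` (observer-bias covariate, enters linearly and is conditioned out
#' at prediction time). Cell `(i, j)` (0-based col `i`, row `j`) covers the
#' half-open square `[x0 + i*d, x0 + (i+1)*d) x [y0 + j*d, y0 + (j+1)*d)`.
#' Layers are stored south-to-north (matrix row 1 is the southernmost row);
#' ESRI ASCII grids, which run north-to-south, are flipped on read/write.
#' The missing-value mask is shared: a cell masked in any layer is masked in
#' all.
#'
#' @param x0,y0 lower-left corner (km).
#' @param cellsize cell edge length (km).
#' @param layers named list of `nrows x ncols` numeric matrices (row 1 =
#'   south). `NA` entries are masked.
#' @param roles character vector, one of `"environmental"`/`"bias"` per
#'   layer; recycled if length 1.
#' @return An object of class `"raster_stack"`.
#' @export
raster_stack <- function(x0, y0, cellsize, layers, roles = "environmental") {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)))
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L)
    stop("alignment error: layers have differing dimensions")
  if (length(roles) == 1L) roles <- rep(roles, length(layers))
  stopifnot(length(roles) == length(layers))
  if (!all(roles %in% c("environmental", "bias")))
    stop("layer roles must be 'environmental' or 'bias'")
  names(roles) <- names(layers)
  layers <- lapply(layers, function(m) {m <- as.matrix(m); storage.mode(m) <- "double"; m})
  mask <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) {m[mask] <- NA_real_; m})
  nr <- nrow(layers[[1L]]); nc <- ncol(layers[[1L]])
  structure(list(x0 = x0, y0 = y0, cellsize = cellsize,
                 n_cols = nc, n_rows = nr,
                 layers = layers, roles = roles, mask = mask),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster stack: %d x %d cells of %g km, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cellsize, x$x0, x$y0))
  cat(sprintf("  layers: %s\n",
              paste(sprintf("%s (%s)", names(x$layers), x$roles),
                    collapse = ", ")))
  cat(sprintf("  masked cells: %d of %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Region covered by a raster stack
#' @param stack a [raster_stack()].
#' @return a [region()].
#' @export
stack_region <- function(stack) {
  region(stack$x0, stack$x0 + stack$n_cols * stack$cellsize,
         stack$y0, stack$y0 + stack$n_rows * stack$cellsize)
}

#' Layer names of a given role
#' @param stack a [raster_stack()].
#' @param role `"environmental"` or `"bias"`.
#' @return character vector of layer names.
#' @export
layer_names <- function(stack, role = c("environmental", "bias")) {
  role <- match.arg(role)
  names(stack$roles)[stack$roles == role]
}

# Map coordinates to 1-based (col, row); half-open cells, the far edges of
# the grid are clamped into the last cell. Points outside return NA.
cell_index <- function(stack, x, y) {
  d <- stack$cellsize
  col <- floor((x - stack$x0) / d) + 1
  row <- floor((y - stack$y0) / d) + 1
  xmax <- stack$x0 + stack$n_cols * d
  ymax <- stack$y0 + stack$n_rows * d
  col[x == xmax] <- stack$n_cols
  row[y == ymax] <- stack$n_rows
  out <- x < stack$x0 | x > xmax | y < stack$y0 | y > ymax
  col[out | col < 1 | col > stack$n_cols] <- NA_integer_
  row[out | row < 1 | row > stack$n_rows] <- NA_integer_
  cbind(col = as.integer(col), row = as.integer(row))
}

#' Nearest-cell covariate lookup
#'
#' Each point takes the value of the cell that contains it (half-open
#' convention, so a point on a shared edge belongs to the higher-index
#' cell); no interpolation. Points in masked cells get `NA` in every layer
#' and are flagged unusable.
#'
#' @param stack a [raster_stack()].
#' @param x,y point coordinates (km); or pass a [point_pattern()] as `x`.
#' @return data frame with one column per layer plus a logical attribute
#'   `"usable"` (FALSE for points in masked cells).
#' @export
extract_covariates <- function(stack, x, y = NULL) {
  if (inherits(x, "point_pattern")) { y <- x$y; x <- x$x }
  if (inherits(x, "pa_pattern")) { y <- x$y; x <- x$x }
  idx <- cell_index(stack, x, y)
  bad <- which(is.na(idx[, 1L]))
  if (length(bad))
    stop("points outside the raster extent at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  lin <- (idx[, "col"] - 1L) * stack$n_rows + idx[, "row"]
  vals <- lapply(stack$layers, function(m) m[lin])
  out <- as.data.frame(vals, optional = TRUE)
  names(out) <- names(stack$layers)
  attr(out, "usable") <- !stack$mask[lin]
  out
}

#' Cell-centre coordinates of every grid cell
#' @param stack a [raster_stack()].
#' @param unmasked_only drop masked cells.
#' @return data frame with columns `x`, `y`, `col`, `row`.
#' @export
cell_centres <- function(stack, unmasked_only = FALSE) {
  d <- stack$cellsize
  g <- expand.grid(row = seq_len(stack$n_rows), col = seq_len(stack$n_cols))
  out <- data.frame(x = stack$x0 + (g$col - 0.5) * d,
                    y = stack$y0 + (g$row - 0.5) * d,
                    col = g$col, row = g$row)
  if (unmasked_only) out <- out[!stack$mask[cbind(g$row, g$col)], , drop = FALSE]
  out
}

#' Read a raster layer from an ESRI ASCII grid file
#'
#' Parses the standard `ncols nrows xllcorner yllcorner cellsize
#' NODATA_value` header; the file's north-to-south rows are converted to
#' the internal south-origin convention, and nodata cells become `NA`.
#'
#' @param path file path.
#' @param name layer name (defaults to the file name without extension).
#' @param role `"environmental"` or `"bias"`.
#' @param stack optional existing [raster_stack()] to append to; geometry
#'   mismatch is an error.
#' @return a [raster_stack()] with the new layer (appended if `stack`
#'   given).
#' @export
read_raster_ascii <- function(path, name = NULL, role = "environmental",
                              stack = NULL) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("incomplete ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("expected ", nc * nr, " values, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # row 1 = north
  m <- m[nr:1, , drop = FALSE]                            # internal: south
  m[m == nodata] <- NA_real_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  add_layer(stack, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m, name, role)
}

#' Read a raster layer from a bare CSV matrix plus explicit geometry
#'
#' The CSV holds a headerless numeric matrix whose first row is the
#' northernmost row (the usual map orientation); geometry comes from the
#' arguments.
#'
#' @inheritParams read_raster_ascii
#' @param x0,y0,cellsize grid geometry (km).
#' @param nodata value treated as missing.
#' @return a [raster_stack()].
#' @export
read_raster_csv <- function(path, x0, y0, cellsize, name = NULL,
                            role = "environmental", nodata = -9999,
                            stack = NULL) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m <- m[nrow(m):1, , drop = FALSE]
  m[m == nodata] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  add_layer(stack, x0, y0, cellsize, m, name, role)
}

add_layer <- function(stack, x0, y0, cellsize, m, name, role) {
  if (is.null(stack))
    return(raster_stack(x0, y0, cellsize, stats::setNames(list(m), name),
                        roles = role))
  same <- isTRUE(all.equal(c(stack$x0, stack$y0, stack$cellsize),
                           c(x0, y0, cellsize))) &&
    nrow(m) == stack$n_rows && ncol(m) == stack$n_cols
  if (!same)
    stop("alignment error: layer '", name,
         "' geometry differs from the existing stack")
  layers <- c(stack$layers, stats::setNames(list(m), name))
  raster_stack(x0, y0, cellsize, layers, roles = c(stack$roles, role))
}

#' Write a layer (or intensity surface) as an ESRI ASCII grid
#'
#' @param x a [raster_stack()] (give `layer`) or an intensity surface.
#' @param path output file.
#' @param layer layer name when `x` is a stack.
#' @param nodata nodata code written for masked cells.
#' @export
write_raster_ascii <- function(x, path, layer = NULL, nodata = -9999) {
  if (inherits(x, "intensity_surface")) {
    m <- x$values; geom <- x
  } else {
    stopifnot(inherits(x, "raster_stack"))
    if (is.null(layer)) layer <- names(x$layers)[1L]
    m <- x$layers[[layer]]; geom <- x
  }
  m[is.na(m)] <- nodata
  m <- m[nrow(m):1, , drop = FALSE]  # back to north-to-south
  hdr <- c(sprintf("ncols %d", geom$n_cols),
           sprintf("nrows %d", geom$n_rows),
           sprintf("xllcorner %.10g", geom$x0),
           sprintf("yllcorner %.10g", geom$y0),
           sprintf("cellsize %.10g", geom$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
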