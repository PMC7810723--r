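#' Single-band raster
#'
#' A minimal in-memory raster: a numeric matrix with a georeference. Row 1 is
#' the top (northernmost) row, column 1 the westernmost column; each pixel
#' covers the half-open square `[origin, origin + cellsize)`. Missing cells are
#' held as `NA` in memory and written out as the `nodata` sentinel.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll coordinates of the lower-left corner of the grid, in the
#'   units of `crs` (metres for projected CRSs, degrees for `"geographic"`).
#' @param cellsize pixel edge length (square pixels).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param crs coordinate reference system, see [crs_geographic()] /
#'   [crs_aeqd()]; may be `NULL` for bands that are never reprojected.
#' @return an object of class `rband`.
#' @export
rband <- function(values, xll = 0, yll = 0, cellsize = 30, nodata = -9999,
                  crs = NULL) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = nodata, crs = crs),
            class = "rband")
}

#' @export
print.rband <- function(x, ...) {
  cat(sprintf("<rband> %d x %d @ %g, origin (%g, %g), crs: %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              if (is.null(x$crs)) "none" else x$crs$type))
  invisible(x)
}

#' @export
dim.rband <- function(x) dim(x$values)

#' Test exact georeference agreement between two bands
#'
#' Alignment requires identical shape, origin, cell size and CRS type. No
#' tolerance matching: misaligned stacks are an error upstream, never silently
#' resampled.
#'
#' @param a,b `rband` objects.
#' @return logical scalar.
#' @export
bands_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(a$xll == b$xll) && isTRUE(a$yll == b$yll) &&
    isTRUE(a$cellsize == b$cellsize) &&
    identical(a$crs$type, b$crs$type)
}

stop_if_misaligned <- function(a, b, what = "raster bands") {
  if (!bands_aligned(a, b))
    stop("stack-alignment error: ", what, " do not share shape/geotransform/CRS",
         call. = FALSE)
  invisible(TRUE)
}

# ---- coordinate reference systems -------------------------------------------

#' Coordinate reference systems
#'
#' Two CRSs are supported. `crs_geographic()` declares that projected x/y
#' coordinates already are longitude/latitude in decimal degrees.
#' `crs_aeqd()` is a local azimuthal-equidistant projection on a sphere,
#' centred on (`lat0`, `lon0`): a point at projected offset (dx, dy) metres
#' from the centre lies at great-circle distance sqrt(dx^2+dy^2) along the
#' initial bearing atan2(dx, dy). This is the natural "local metric grid"
#' for desk-scale landscapes a few kilometres across.
#'
#' @param lon0,lat0 projection centre, decimal degrees.
#' @param radius sphere radius in metres (default: WGS84 equatorial).
#' @return a list with at least element `type`.
#' @export
crs_aeqd <- function(lon0, lat0, radius = 6378137) {
  list(type = "aeqd", lon0 = lon0, lat0 = lat0, radius = radius)
}

#' @rdname crs_aeqd
#' @export
crs_geographic <- function() list(type = "geographic")

#' Convert projected coordinates to longitude/latitude
#'
#' @param crs a CRS from [crs_aeqd()] or [crs_geographic()].
#' @param x,y projected coordinates (vectors of equal length).
#' @return list with numeric vectors `lon`, `lat` (decimal degrees).
#' @export
project_inverse <- function(crs, x, y) {
  if (is.null(crs)) stop("configuration error: raster has no CRS", call. = FALSE)
  if (identical(crs$type, "geographic")) return(list(lon = x, lat = y))
  if (!identical(crs$type, "aeqd"))
    stop("configuration error: unsupported CRS type '", crs$type, "'", call. = FALSE)
  d <- sqrt(x^2 + y^2)
  brg <- atan2(x, y)                      # bearing from north, clockwise
  delta <- d / crs$radius
  phi0 <- crs$lat0 * pi / 180
  lam0 <- crs$lon0 * pi / 180
  phi <- asin(sin(phi0) * cos(delta) + cos(phi0) * sin(delta) * cos(brg))
  lam <- lam0 + atan2(sin(brg) * sin(delta) * cos(phi0),
                      cos(delta) - sin(phi0) * sin(phi))
  out <- list(lon = lam * 180 / pi, lat = phi * 180 / pi)
  # the projection centre itself: bearing undefined, distance 0
  at0 <- which(d == 0)
  if (length(at0)) { out$lon[at0] <- crs$lon0; out$lat[at0] <- crs$lat0 }
  out
}

#' Convert longitude/latitude to projected coordinates
#'
#' Inverse of [project_inverse()]; used to place plots given in geographic
#' coordinates onto a projected grid.
#'
#' @inheritParams project_inverse
#' @param lon,lat decimal degrees.
#' @return list with numeric vectors `x`, `y`.
#' @export
project_forward <- function(crs, lon, lat) {
  if (is.null(crs)) stop("configuration error: raster has no CRS", call. = FALSE)
  if (identical(crs$type, "geographic")) return(list(x = lon, y = lat))
  if (!identical(crs$type, "aeqd"))
    stop("configuration error: unsupported CRS type '", crs$type, "'", call. = FALSE)
  phi0 <- crs$lat0 * pi / 180
  lam0 <- crs$lon0 * pi / 180
  phi <- lat * pi / 180
  dlam <- lon * pi / 180 - lam0
  cosd <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosd <- pmin(1, pmax(-1, cosd))
  delta <- acos(cosd)
  brg <- atan2(sin(dlam) * cos(phi),
               cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  d <- delta * crs$radius
  list(x = d * sin(brg), y = d * cos(brg))
}

# ---- pixel geometry ---------------------------------------------------------

#' Projected coordinates of every pixel centroid
#'
#' @param band an `rband` (only its georeference is used).
#' @return list of two matrices `x`, `y` in projected units, same shape as the
#'   band; centroids sit half a pixel in from the cell corner.
#' @export
centroid_xy <- function(band) {
  nr <- nrow(band$values); nc <- ncol(band$values)
  cs <- band$cellsize
  xs <- band$xll + (seq_len(nc) - 0.5) * cs
  ys <- band$yll + (nr - seq_len(nr) + 0.5) * cs   # row 1 = top
  list(x = matrix(xs, nr, nc, byrow = TRUE),
       y = matrix(ys, nr, nc))
}

#' Latitude and longitude bands of pixel centroids
#'
#' Computes each pixel centroid in the projected CRS and reprojects it to
#' geographic coordinates, yielding the two location bands used as imputation
#' predictors.
#'
#' @param band an `rband` carrying a CRS.
#' @return list of two `rband`s, `lat` and `lon` (decimal degrees).
#' @export
pixel_centroids <- function(band) {
  if (is.null(band$crs))
    stop("configuration error: cannot compute centroids without a CRS", call. = FALSE)
  xy <- centroid_xy(band)
  ll <- project_inverse(band$crs, as.vector(xy$x), as.vector(xy$y))
  shp <- dim(band$values)
  mk <- function(v) rband(matrix(v, shp[1], shp[2]), band$xll, band$yll,
                          band$cellsize, band$nodata, band$crs)
  list(lat = mk(ll$lat), lon = mk(ll$lon))
}

#' Map projected points to (row, col) pixel indices
#'
#' Points use the half-open pixel convention `[origin, origin + cellsize)`.
#' Points outside the grid get `NA` indices.
#'
#' @param band an `rband`.
#' @param x,y projected coordinates.
#' @return data.frame with integer columns `row`, `col`.
#' @export
xy_to_rowcol <- function(band, x, y) {
  nr <- nrow(band$values); nc <- ncol(band$values)
  col <- floor((x - band$xll) / band$cellsize) + 1L
  row <- nr - floor((y - band$yll) / band$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Read a raster band from an ESRI ASCII grid file
#'
#' @param path file path (`.asc`).
#' @param crs optional CRS to attach (the format itself carries none; stack
#'   manifests supply it).
#' @return an `rband`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, crs = NULL) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid (missing header keys): ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  m[m == nodata] <- NA
  rband(m, hdr[["xllcorner"]], hdr[["yllcorner"]], hdr[["cellsize"]],
        nodata, crs)
}

#' Write a raster band to an ESRI ASCII grid file
#'
#' @param band an `rband`.
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(band, path, digits = 10) {
  m <- band$values
  m[is.na(m)] <- band$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(band$xll, digits = 15)),
    paste("yllcorner", format(band$yll, digits = 15)),
    paste("cellsize", format(band$cellsize, digits = 15)),
    paste("NODATA_value", format(band$nodata))
  ), con)
  writeLines(apply(format(m, digits = digits, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  invisible(path)
}

# ---- raster stacks ----------------------------------------------------------

#' Write a named stack of co-registered bands with a YAML manifest
#'
#' The manifest (`stack.yml`) names every band's file and role and carries the
#' shared CRS; [read_stack()] restores the stack from it. All bands must be
#' mutually aligned.
#'
#' @param stack named list of `rband`s.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(length(stack) >= 1, !is.null(names(stack)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- stack[[1]]
  for (nm in names(stack)) stop_if_misaligned(ref, stack[[nm]], nm)
  files <- paste0(names(stack), ".asc")
  for (i in seq_along(stack))
    write_ascii_grid(stack[[i]], file.path(dir, files[i]))
  manifest <- list(
    bands = stats::setNames(as.list(files), names(stack)),
    crs = if (is.null(ref$crs)) NULL else ref$crs
  )
  mf <- file.path(dir, "stack.yml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

#' Read a band stack from its YAML manifest
#'
#' @param dir directory containing `stack.yml` (or a path to the manifest).
#' @return named list of aligned `rband`s sharing the manifest CRS.
#' @export
read_stack <- function(dir) {
  mf <- if (grepl("\\.ya?ml$", dir)) dir else file.path(dir, "stack.yml")
  if (!file.exists(mf)) stop("no stack manifest at ", mf, call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  crs <- manifest$crs
  base <- dirname(mf)
  out <- lapply(manifest$bands, function(f) read_ascii_grid(file.path(base, f), crs))
  ref <- out[[1]]
  for (nm in names(out)) stop_if_misaligned(ref, out[[nm]], nm)
  out
}
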