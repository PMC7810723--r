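#' Cover-bin midpoints and height-bin values
#'
#' Forest canopy cover is carried as the midpoint of its 10-point-wide class
#' (15, 25, ..., 95); canopy height as one of five representative values
#' (3, 8, 18, 38, 70 m). Bins are half-open `[lo, hi)`; the bottom edge of the
#' lowest forest cover bin (10%) is inclusive and the top cover bin closes at
#' 100%; the top height bin (>= 50 m) is unbounded.
#'
#' @name bins
NULL

COVER_BINS <- c(15, 25, 35, 45, 55, 65, 75, 85, 95)
HEIGHT_BINS <- c(3, 8, 18, 38, 70)
HEIGHT_EDGES <- c(0, 5, 10, 25, 50)
DIST_NONE <- 0L
DIST_FIRE <- 1L
DIST_INSECT <- 2L
DIST_YEAR_NONE <- 0L  # sentinel: undisturbed; distinct from valid years

#' Recode percent canopy cover to its bin midpoint
#'
#' @param cover_percent numeric vector, percent cover in `[0, 100]`.
#' @return midpoints (15, 25, ..., 95); values below the 10% forest threshold
#'   return `NA` (non-forest signal — the caller excludes the pixel).
#' @examples
#' bin_cover(c(12, 10, 100))  # 15 15 95
#' @export
bin_cover <- function(cover_percent) {
  if (any(cover_percent > 100, na.rm = TRUE))
    stop("invalid cover percent > 100", call. = FALSE)
  mid <- 10 * floor(cover_percent / 10) + 5
  mid[cover_percent >= 100] <- 95       # top bin closed at 100
  mid[cover_percent < 10] <- NA_real_   # non-forest
  mid
}

#' Recode canopy height to its bin value
#'
#' @param height_m numeric vector, metres; must be non-negative.
#' @return 3, 8, 18, 38 or 70 per the half-open bin table (0-5, 5-10, 10-25,
#'   25-50, >= 50 m).
#' @examples
#' bin_height(c(12, 89, 5))  # 18 70 8
#' @export
bin_height <- function(height_m) {
  if (any(height_m < 0, na.rm = TRUE))
    stop("invalid-record error: negative height", call. = FALSE)
  idx <- findInterval(height_m, HEIGHT_EDGES)   # [lo, hi): left-closed
  out <- HEIGHT_BINS[idx]
  out[is.na(height_m)] <- NA_real_
  out
}

#' Collapse annual disturbance layers to a single code/year pair
#'
#' Keeps, per pixel, the most recent disturbance between the first and last
#' layer years, with fire taking precedence over insect/disease: a pixel that
#' burned in any year carries the fire code and the most recent *fire* year,
#' even if a later insect/disease event occurred. Pixels never disturbed get
#' code 0 and the year sentinel 0.
#'
#' @param annual_layers list of `list(year =, band =)` entries; each `band` is
#'   an `rband` whose cells are 0 (none), 1 (fire) or 2 (insect/disease).
#'   Other disturbance types (harvest, herbicide) are excluded upstream.
#' @return list of two aligned `rband`s: `dist_code`, `dist_year`.
#' @export
collapse_disturbance <- function(annual_layers) {
  if (length(annual_layers) == 0)
    stop("collapse_disturbance needs a template layer; pass at least one band",
         call. = FALSE)
  yrs <- vapply(annual_layers, function(l) as.numeric(l$year), 0)
  ref <- annual_layers[[1]]$band
  for (l in annual_layers) stop_if_misaligned(ref, l$band, "disturbance layers")
  shp <- dim(ref$values)
  fire_yr <- matrix(0, shp[1], shp[2])
  insect_yr <- matrix(0, shp[1], shp[2])
  for (l in annual_layers[order(yrs)]) {     # ascending: later years overwrite
    v <- l$band$values
    v[is.na(v)] <- 0
    fire_yr[v == DIST_FIRE] <- as.numeric(l$year)
    insect_yr[v == DIST_INSECT] <- as.numeric(l$year)
  }
  code <- matrix(DIST_NONE, shp[1], shp[2])
  year <- matrix(DIST_YEAR_NONE, shp[1], shp[2])
  has_insect <- insect_yr > 0
  code[has_insect] <- DIST_INSECT
  year[has_insect] <- insect_yr[has_insect]
  has_fire <- fire_yr > 0                    # fire precedence
  code[has_fire] <- DIST_FIRE
  year[has_fire] <- fire_yr[has_fire]
  mk <- function(m) rband(m, ref$xll, ref$yll, ref$cellsize, ref$nodata, ref$crs)
  list(dist_code = mk(code), dist_year = mk(year))
}

#' Read a vegetation-group recode table
#'
#' Two-column CSV (`source_evg`, `target_evg`); the target may be the literal
#' `DROP` to remove the class from the forest mask. The default table shipped
#' with the package carries the substitutions used for the CONUS-2014 run
#' (692 -> 693, 705 -> 668; 649 and 730 dropped).
#'
#' @param path CSV path; default: the shipped table.
#' @return data.frame with columns `source_evg` (integer) and `target_evg`
#'   (character; a code or `"DROP"`).
#' @export
read_recode_table <- function(path = system.file("extdata", "evg_recode_default.csv",
                                                 package = "plotimpute")) {
  tab <- utils::read.csv(path, colClasses = c("integer", "character"))
  names(tab) <- c("source_evg", "target_evg")
  if (any(duplicated(tab$source_evg)))
    stop("recode table has duplicate source codes", call. = FALSE)
  # reject cycles / chains: a target may not itself be a recoded source
  tgt <- suppressWarnings(as.integer(tab$target_evg))
  if (any(stats::na.omit(tgt) %in% tab$source_evg))
    stop("recode table contains chained/cyclic substitutions", call. = FALSE)
  tab
}

apply_recode <- function(evg, recode_table) {
  if (is.null(recode_table) || nrow(recode_table) == 0)
    return(list(evg = evg, dropped = rep(FALSE, length(evg))))
  m <- match(evg, recode_table$source_evg)
  hit <- !is.na(m)
  tgt <- recode_table$target_evg[m[hit]]
  dropped <- rep(FALSE, length(evg))
  dropped[hit][tgt == "DROP"] <- TRUE
  keep <- hit & !dropped
  evg[keep] <- as.numeric(recode_table$target_evg[m[keep]])
  list(evg = evg, dropped = dropped)
}

#' Build the forest mask and recode the vegetation-group band
#'
#' A pixel enters the mask when its canopy cover is at or above the 10% forest
#' threshold (equivalently: it falls in the lowest forest cover bin or higher),
#' its vegetation group is not in `exclude_evg` (developed / agricultural
#' classes), and its group is not dropped by the recode table. Recode
#' substitutions are applied to the returned group band.
#'
#' @param cover_band `rband` of percent canopy cover (raw percent 0-100).
#' @param evg_band aligned `rband` of vegetation-group codes.
#' @param recode_table data.frame from [read_recode_table()], or `NULL`.
#' @param exclude_evg vegetation-group codes masked out wholesale.
#' @return list: `forest_mask` (logical-valued `rband`), `evg` (recoded
#'   `rband`).
#' @export
build_forest_mask <- function(cover_band, evg_band, recode_table = NULL,
                              exclude_evg = integer()) {
  stop_if_misaligned(cover_band, evg_band, "cover and vegetation-group bands")
  cov <- cover_band$values
  evg <- evg_band$values
  rc <- apply_recode(as.vector(evg), recode_table)
  evg_new <- matrix(rc$evg, nrow(evg), ncol(evg))
  dropped <- matrix(rc$dropped, nrow(evg), ncol(evg))
  mask <- !is.na(cov) & cov >= 10 & !is.na(evg_new) &
    !(evg_new %in% exclude_evg) & !dropped
  evg_new[!mask] <- NA
  g <- cover_band
  list(forest_mask = rband(mask * 1, g$xll, g$yll, g$cellsize, g$nodata, g$crs),
       evg = rband(evg_new, g$xll, g$yll, g$cellsize, g$nodata, g$crs))
}

#' Verify that every masked vegetation group has a reference plot
#'
#' The imputation cannot run if a vegetation group present on the landscape has
#' no reference plot keyed to it; such classes must be recoded or dropped
#' upstream.
#'
#' @param evg_band recoded group band (masked pixels non-`NA`).
#' @param reference_evg vector of group codes present in the reference table.
#' @return `TRUE` invisibly, or an error naming the uncovered class(es).
#' @export
check_reference_coverage <- function(evg_band, reference_evg) {
  present <- unique(stats::na.omit(as.vector(
    if (inherits(evg_band, "rband")) evg_band$values else evg_band)))
  missing <- setdiff(present, unique(reference_evg))
  if (length(missing))
    stop("unresolved-class error: vegetation group(s) with no reference plot: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Assemble the analysis-ready target stack
#'
#' Applies the full preprocessing chain to raw landscape bands: forest masking
#' with vegetation-group recoding, midpoint binning of cover and height,
#' collapse of annual disturbance layers, and per-pixel centroid latitude and
#' longitude. Non-masked pixels are set to `NA` in every output band.
#'
#' @param raw named list of `rband`s with elements `cover` (percent), `height`
#'   (m), `evg`, `slope`, `aspect`, `elevation`, `bio1` ... `bio6`; and either
#'   `dist_code`/`dist_year` (already collapsed) or none.
#' @param annual_disturbance optional list for [collapse_disturbance()].
#' @param recode_table see [build_forest_mask()].
#' @param exclude_evg see [build_forest_mask()].
#' @return named list of aligned `rband`s (`cover_bin`, `height_bin`, `evg`,
#'   `slope`, `aspect`, `elevation`, `bio1`..`bio6`, `dist_code`, `dist_year`,
#'   `lat`, `lon`, `forest_mask`) — the target stack consumed by the
#'   imputation engine.
#' @export
prep_target_stack <- function(raw, annual_disturbance = NULL,
                              recode_table = NULL, exclude_evg = integer()) {
  need <- c("cover", "height", "evg", "slope", "aspect", "elevation",
            paste0("bio", 1:6))
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing raw bands: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ref <- raw$cover
  for (nm in names(raw)) stop_if_misaligned(ref, raw[[nm]], nm)

  fm <- build_forest_mask(raw$cover, raw$evg, recode_table, exclude_evg)
  mask <- fm$forest_mask$values > 0

  if (!is.null(annual_disturbance)) {
    dd <- collapse_disturbance(annual_disturbance)
    stop_if_misaligned(ref, dd$dist_code, "collapsed disturbance")
  } else if (!is.null(raw$dist_code) && !is.null(raw$dist_year)) {
    dd <- list(dist_code = raw$dist_code, dist_year = raw$dist_year)
  } else {
    z <- rband(matrix(0, nrow(ref$values), ncol(ref$values)),
               ref$xll, ref$yll, ref$cellsize, ref$nodata, ref$crs)
    dd <- list(dist_code = z, dist_year = z)
  }

  ll <- pixel_centroids(ref)
  mk <- function(v) {
    v[!mask] <- NA
    rband(v, ref$xll, ref$yll, ref$cellsize, ref$nodata, ref$crs)
  }
  stack <- list(
    cover_bin = mk(matrix(bin_cover(as.vector(raw$cover$values)),
                          nrow(ref$values), ncol(ref$values))),
    height_bin = mk(matrix(bin_height(as.vector(pmax(raw$height$values, 0))),
                           nrow(ref$values), ncol(ref$values))),
    evg = fm$evg,
    slope = mk(raw$slope$values), aspect = mk(raw$aspect$values),
    elevation = mk(raw$elevation$values),
    bio1 = mk(raw$bio1$values), bio2 = mk(raw$bio2$values),
    bio3 = mk(raw$bio3$values), bio4 = mk(raw$bio4$values),
    bio5 = mk(raw$bio5$values), bio6 = mk(raw$bio6$values),
    dist_code = mk(dd$dist_code$values), dist_year = mk(dd$dist_year$values),
    lat = mk(ll$lat$values), lon = mk(ll$lon$values),
    forest_mask = fm$forest_mask
  )
  stack
}
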