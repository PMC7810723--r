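#' Tree and plot table column contract
#'
#' Delimited tree tables mirror the inventory field names: `PLT_CN` (plot ID),
#' `STATUSCD` (1 = live, 2 = dead, 3 = cut and removed), `STANDING_DEAD_CD`
#' (1 = standing dead, only valid on dead trees), `SPCD` (species code), `DIA`
#' (diameter at breast height, cm), `HT` (height, m), `TPA_UNADJ`
#' (trees-per-area expansion factor; the area unit is declared by the caller),
#' `CROWN_RADIUS` (m). Plot tables carry `CN` (plot ID), `X`/`Y` (projected
#' coordinates in the stack CRS), `CONDCNT` (condition count; 1 = single
#' condition), and up to three disturbance slots `DSTRBCD1..3` (0 none,
#' 1 fire, 2 insect/disease) with matching `DSTRBYR1..3`.
#'
#' @name table_contract
NULL

STATUS_LIVE <- 1L
STATUS_DEAD <- 2L
STATUS_CUT <- 3L

#' Count standing-dead trees on a plot
#'
#' @param trees data.frame of tree records (see [table_contract]).
#' @return integer count of records with `STANDING_DEAD_CD == 1`.
#' @export
count_standing_dead <- function(trees) {
  if (nrow(trees) == 0) return(0L)
  flag <- !is.na(trees$STANDING_DEAD_CD) & trees$STANDING_DEAD_CD == 1
  if (any(flag & trees$STATUSCD != STATUS_DEAD))
    stop("invalid-record error: standing-dead flag on a non-dead tree",
         call. = FALSE)
  sum(flag)
}

#' Reduce a plot's disturbance slots to a single code/year pair
#'
#' Same precedence logic as the landscape-side layer collapse: fire beats
#' insect/disease regardless of recency; within a type the most recent year
#' wins. Undisturbed plots get code 0 / year 0.
#'
#' @param codes up to three disturbance codes (0/NA = empty slot, 1 = fire,
#'   2 = insect/disease).
#' @param years matching years.
#' @return list(`dist_code`, `dist_year`).
#' @export
assign_plot_disturbance <- function(codes, years) {
  codes <- as.numeric(codes); years <- as.numeric(years)
  empty_code <- is.na(codes) | codes == 0
  if (any(!is.na(years) & years > 0 & empty_code))
    stop("invalid-record error: disturbance year present without code",
         call. = FALSE)
  keep <- !empty_code & !is.na(years) & years > 0
  codes <- codes[keep]; years <- years[keep]
  if (!length(codes))
    return(list(dist_code = DIST_NONE, dist_year = DIST_YEAR_NONE))
  if (any(codes == DIST_FIRE)) {
    list(dist_code = DIST_FIRE,
         dist_year = as.integer(max(years[codes == DIST_FIRE])))
  } else {
    list(dist_code = DIST_INSECT, dist_year = as.integer(max(years)))
  }
}

#' Top-stratum height from a tree list
#'
#' The plot's height is the mean height of the nine live trees centred on the
#' 70th-percentile tree: live heights are sorted ascending, the anchor rank is
#' `ceiling(0.7 n)`, and the window of nine ranks centred there is clipped to
#' the list bounds. Plots with fewer than nine live trees average all of them.
#'
#' @param trees tree records (see [table_contract]).
#' @return height in metres, or `NA` when the plot has no live tree with a
#'   height (undefined-height signal; the caller excludes the plot).
#' @export
top_stratum_height <- function(trees) {
  h <- trees$HT[trees$STATUSCD == STATUS_LIVE & !is.na(trees$HT)]
  n <- length(h)
  if (n == 0) return(NA_real_)
  h <- sort(h)
  if (n < 9) return(mean(h))
  r <- ceiling(0.7 * n)
  lo <- max(1L, r - 4L); hi <- min(n, r + 4L)
  mean(h[lo:hi])
}

#' Overlap-corrected canopy cover from a tree list
#'
#' Percent of ground covered by live-tree crowns under the random-placement
#' overlap correction: `C = 100 (1 - exp(-A))`, where `A` is the summed crown
#' area per unit ground area, `A = sum(pi r_i^2 tpa_i) / unit_area`. The
#' expansion factor `tpa_i` scales each record to `unit_area` of ground
#' (10,000 m2 when the factor is per hectare, 4,046.86 m2 when per acre).
#'
#' @param trees tree records (see [table_contract]).
#' @param unit_area ground area, in m2, that `TPA_UNADJ` expands to.
#' @return percent cover in `[0, 100)`.
#' @export
canopy_cover <- function(trees, unit_area = 10000) {
  stopifnot(unit_area > 0)
  live <- trees[trees$STATUSCD == STATUS_LIVE, , drop = FALSE]
  if (nrow(live) == 0) return(0)
  if (any(is.na(live$CROWN_RADIUS)))
    stop("invalid-record error: live tree without crown radius", call. = FALSE)
  a <- sum(pi * live$CROWN_RADIUS^2 * live$TPA_UNADJ) / unit_area
  100 * (1 - exp(-a))
}

#' Two species with the highest basal area
#'
#' Per-species basal area is `sum(pi (DIA/2)^2 * TPA_UNADJ)` over live trees.
#' Exact ties are broken by ascending species code.
#'
#' @param trees tree records (see [table_contract]).
#' @return integer vector of length 2: the top two species codes, the second
#'   `NA` for monospecific plots; both `NA` when no live tree exists.
#' @export
top_two_species <- function(trees) {
  live <- trees[trees$STATUSCD == STATUS_LIVE & !is.na(trees$DIA), , drop = FALSE]
  if (nrow(live) == 0) return(c(NA_integer_, NA_integer_))
  ba <- tapply(pi * (live$DIA / 2)^2 * live$TPA_UNADJ, live$SPCD, sum)
  sp <- as.integer(names(ba))
  ord <- order(-ba, sp)  # descending basal area, ties by ascending code
  top <- sp[ord][1:2]
  c(top[1], if (length(sp) >= 2) top[2] else NA_integer_)
}

#' Build the imputation-ready reference table
#'
#' Joins the plot and tree tables, derives plot attributes (binned cover and
#' height, disturbance, standing-dead count, top-two species), and samples the
#' predictor bands of the target stack at each plot's location. Multi-condition
#' plots are split off into a validation table; plots below the 10% cover
#' threshold, without live trees, or outside the raster extent are dropped
#' (with counts reported as attributes).
#'
#' @param plot_df plot table (see [table_contract]).
#' @param tree_df tree table.
#' @param stack target stack from [prep_target_stack()].
#' @param unit_area see [canopy_cover()].
#' @return data.frame of reference plot records (one row per retained
#'   single-condition plot) with columns `plot_id`, `x`, `y`, `lat`, `lon`,
#'   `slope`, `aspect`, `elevation`, `bio1`..`bio6`, `dist_code`, `dist_year`,
#'   `cover_pct`, `height_m`, `cover_bin`, `height_bin`, `evg`,
#'   `standing_dead`, `sp1`, `sp2`, `condition_count`. The excluded
#'   multi-condition plots are attached as `attr(, "validation")` with the
#'   same columns; drop counts as `attr(, "dropped")`.
#' @export
build_reference_table <- function(plot_df, tree_df, stack, unit_area = 10000) {
  stopifnot(all(c("CN", "X", "Y") %in% names(plot_df)))
  trees_by_plot <- split(tree_df, tree_df$PLT_CN)

  rc <- xy_to_rowcol(stack$cover_bin, plot_df$X, plot_df$Y)
  n_outside <- sum(is.na(rc$row))

  sample_band <- function(band, row, col)
    band$values[cbind(row, col)]

  rows <- vector("list", nrow(plot_df))
  for (i in seq_len(nrow(plot_df))) {
    p <- plot_df[i, ]
    if (is.na(rc$row[i])) next                        # outside extent
    trees <- trees_by_plot[[as.character(p$CN)]]
    if (is.null(trees) || !any(trees$STATUSCD == STATUS_LIVE)) next
    cov <- canopy_cover(trees, unit_area)
    if (cov < 10) next                                # below forest threshold
    hgt <- top_stratum_height(trees)
    if (is.na(hgt)) next
    dist <- assign_plot_disturbance(
      c(p$DSTRBCD1, p$DSTRBCD2, p$DSTRBCD3),
      c(p$DSTRBYR1, p$DSTRBYR2, p$DSTRBYR3))
    sp <- top_two_species(trees)
    r <- rc$row[i]; cc <- rc$col[i]
    evg <- sample_band(stack$evg, r, cc)
    rows[[i]] <- data.frame(
      plot_id = p$CN, x = p$X, y = p$Y,
      lat = sample_band(stack$lat, r, cc),
      lon = sample_band(stack$lon, r, cc),
      slope = sample_band(stack$slope, r, cc),
      aspect = sample_band(stack$aspect, r, cc),
      elevation = sample_band(stack$elevation, r, cc),
      bio1 = sample_band(stack$bio1, r, cc), bio2 = sample_band(stack$bio2, r, cc),
      bio3 = sample_band(stack$bio3, r, cc), bio4 = sample_band(stack$bio4, r, cc),
      bio5 = sample_band(stack$bio5, r, cc), bio6 = sample_band(stack$bio6, r, cc),
      dist_code = dist$dist_code, dist_year = dist$dist_year,
      cover_pct = cov, height_m = hgt,
      cover_bin = bin_cover(cov), height_bin = bin_height(hgt),
      evg = if (!is.null(p$EVG) && !is.na(p$EVG)) p$EVG else evg,
      standing_dead = count_standing_dead(trees),
      sp1 = sp[1], sp2 = sp[2],
      condition_count = if (is.null(p$CONDCNT) || is.na(p$CONDCNT)) 1L
                        else as.integer(p$CONDCNT)
    )
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no usable plots in reference table", call. = FALSE)
  # plots that fell on non-forest pixels have NA sampled predictors: drop
  on_mask <- !is.na(tab$lat)
  n_offmask <- sum(!on_mask)
  tab <- tab[on_mask, , drop = FALSE]
  single <- tab$condition_count == 1L
  ref <- tab[single, , drop = FALSE]
  rownames(ref) <- NULL
  val <- tab[!single, , drop = FALSE]
  rownames(val) <- NULL
  attr(ref, "validation") <- val
  attr(ref, "dropped") <- c(outside_extent = n_outside, off_mask = n_offmask,
                            multi_condition = nrow(val))
  ref
}
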