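#' Pixel-wise confusion matrix
#'
#' Cross-tabulates imputed against target class values over masked pixels.
#' Rows are the imputed classes, columns the target classes.
#'
#' @param imputed_band,target_band aligned `rband`s of class values.
#' @param mask logical matrix or `rband`; compared pixels.
#' @param labels class vocabulary (ordered); defaults to the union of values
#'   present. A value outside the vocabulary is an error naming the code.
#' @return square integer matrix with `dimnames`, class `confusion_matrix`.
#' @export
confusion <- function(imputed_band, target_band, mask = NULL, labels = NULL) {
  stop_if_misaligned(imputed_band, target_band, "imputed and target bands")
  iv <- imputed_band$values; tv <- target_band$values
  if (!is.null(mask)) {
    mm <- if (inherits(mask, "rband")) mask$values > 0 else mask
    iv <- iv[mm]; tv <- tv[mm]
  }
  ok <- !is.na(iv) & !is.na(tv)
  iv <- iv[ok]; tv <- tv[ok]
  if (is.null(labels)) labels <- sort(unique(c(iv, tv)))
  bad <- setdiff(unique(c(iv, tv)), labels)
  if (length(bad))
    stop("class code(s) outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(iv, levels = labels), factor(tv, levels = labels))
  m <- matrix(as.integer(cm), length(labels), length(labels),
              dimnames = list(imputed = as.character(labels),
                              target = as.character(labels)))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix from counts
#'
#' @param counts square numeric matrix, rows = imputed, columns = target.
#' @param labels class labels.
#' @return a `confusion_matrix`.
#' @export
as_confusion <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  dimnames(counts) <- list(imputed = labels, target = labels)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Overall, user's and producer's accuracy
#'
#' Overall accuracy is the matrix trace over the grand total. User's accuracy
#' for class i is the diagonal count over the row (imputed) total — the
#' probability the mapped class is correct on the ground. Producer's accuracy
#' is the diagonal over the column (target) total — the probability a ground
#' class was mapped correctly. Empty rows/columns yield `NA`.
#'
#' @param cm square count matrix (rows = imputed, columns = target).
#' @return list: `overall`, `users` (named by class), `producers`, `total`.
#' @export
accuracy_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  d <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  users <- ifelse(rs > 0, d / rs, NA_real_)
  producers <- ifelse(cs > 0, d / cs, NA_real_)
  names(users) <- rownames(cm); names(producers) <- colnames(cm)
  list(overall = sum(d) / total, users = users, producers = producers,
       total = total)
}

#' Percent summary rate, rounded half-up to one decimal
#'
#' Matches the reporting convention of the accuracy-summary tables (e.g.
#' 1257/2858 prints as 44.0).
#'
#' @param count numerator.
#' @param denominator denominator.
#' @param digits decimal places (default 1).
#' @return percent, rounded half-up.
#' @export
summary_rate <- function(count, denominator, digits = 1) {
  stopifnot(denominator > 0)
  p <- 100 * count / denominator
  floor(p * 10^digits + 0.5) / 10^digits
}

# ---- plot footprints ---------------------------------------------------------

#' Pixels whose centroid falls within a plot's footprint
#'
#' The splayed footprint of a standard four-subplot inventory plot (7.3 m
#' subplot radius, 36.6 m between subplot centres) is a disc of radius 40.25 m
#' around the plot centre. Distance is Euclidean in the projected CRS.
#'
#' @param band `rband` providing the georeference.
#' @param x,y plot centre, projected coordinates.
#' @param radius footprint radius in projected units (default 40.25 m).
#' @return data.frame of `row`, `col` pixel indices (possibly empty when the
#'   plot lies outside the extent), clipped to the grid.
#' @export
footprint_pixels <- function(band, x, y, radius = 40.25) {
  nr <- nrow(band$values); nc <- ncol(band$values); cs <- band$cellsize
  # candidate window around the centre, then exact centroid-distance test
  cmin <- max(1L, floor((x - radius - band$xll) / cs) + 1L)
  cmax <- min(nc, floor((x + radius - band$xll) / cs) + 1L)
  rmax <- min(nr, nr - floor((y - radius - band$yll) / cs))
  rmin <- max(1L, nr - floor((y + radius - band$yll) / cs))
  if (cmin > cmax || rmin > rmax)
    return(data.frame(row = integer(0), col = integer(0)))
  grid <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  cx <- band$xll + (grid$col - 0.5) * cs
  cy <- band$yll + (nr - grid$row + 0.5) * cs
  keep <- (cx - x)^2 + (cy - y)^2 <= radius^2
  grid[keep, , drop = FALSE]
}

#' Footprint agreement between validation plots and a map
#'
#' For every validation plot, examines the forested pixels whose centroid lies
#' within the plot footprint and records: whether at least one pixel's cover
#' bin (height bin) matches the plot's; whether the footprint's weighted cover
#' value (equal-weight mean of pixel cover midpoints) is within 10 percentage
#' points of the plot's cover, and the weighted height within 5 m of the
#' plot's height; and whether any pixel's imputed plot shares at least one of
#' the validation plot's top-two basal-area species. Plots with zero forested
#' footprint pixels are excluded from the denominators and counted separately.
#'
#' @param val_plots validation table (columns `x`, `y`, `cover_pct`,
#'   `height_m`, `cover_bin`, `height_bin`, `sp1`, `sp2`).
#' @param imap an `imputed_map`, or `NULL` when `cover_band`/`height_band`
#'   are supplied directly (agreement against the target rasters).
#' @param cover_band,height_band attribute bands to compare against; default:
#'   derived from `imap`.
#' @param radius footprint radius, m.
#' @param cover_tol,height_tol tolerances: percentage points of cover, metres.
#' @return list with `per_plot` (data.frame of flags and pixel counts),
#'   `summary` (data.frame of counts and percent rates), `n_plots`,
#'   `n_forested` (plots with at least one forested footprint pixel).
#' @export
footprint_agreement <- function(val_plots, imap = NULL,
                                cover_band = NULL, height_band = NULL,
                                radius = 40.25,
                                cover_tol = 10, height_tol = 5) {
  if (is.null(cover_band)) cover_band <- attribute_raster(imap, "cover_bin")
  if (is.null(height_band)) height_band <- attribute_raster(imap, "height_bin")
  species <- !is.null(imap)
  if (species) {
    sp1_band <- attribute_raster(imap, "sp1")
    sp2_band <- attribute_raster(imap, "sp2")
  }
  n <- nrow(val_plots)
  per <- data.frame(plot = seq_len(n), n_pixels = 0L,
                    cover_any = NA, height_any = NA,
                    cover_weighted = NA, height_weighted = NA,
                    species_any = NA)
  for (i in seq_len(n)) {
    fp <- footprint_pixels(cover_band, val_plots$x[i], val_plots$y[i], radius)
    if (nrow(fp) == 0) next
    ij <- cbind(fp$row, fp$col)
    cov <- cover_band$values[ij]
    hgt <- height_band$values[ij]
    ok <- !is.na(cov)
    per$n_pixels[i] <- sum(ok)
    if (!any(ok)) next                       # no forested footprint pixel
    cov <- cov[ok]; hgt <- hgt[ok]
    per$cover_any[i] <- any(cov == val_plots$cover_bin[i])
    per$height_any[i] <- any(hgt == val_plots$height_bin[i])
    per$cover_weighted[i] <-
      abs(mean(cov) - val_plots$cover_pct[i]) <= cover_tol
    per$height_weighted[i] <-
      abs(mean(hgt) - val_plots$height_m[i]) <= height_tol
    if (species) {
      s1 <- sp1_band$values[ij][ok]; s2 <- sp2_band$values[ij][ok]
      tops <- stats::na.omit(c(val_plots$sp1[i], val_plots$sp2[i]))
      per$species_any[i] <- any(s1 %in% tops | s2 %in% tops, na.rm = TRUE)
    }
  }
  forested <- per$n_pixels > 0
  denom <- sum(forested)
  rate_row <- function(flag) {
    cnt <- sum(per[[flag]][forested], na.rm = TRUE)
    data.frame(measure = flag, count = cnt, denominator = denom,
               rate_percent = if (denom > 0) summary_rate(cnt, denom) else NA_real_)
  }
  measures <- c("cover_any", "height_any", "cover_weighted", "height_weighted")
  if (species) measures <- c(measures, "species_any")
  list(per_plot = per,
       summary = do.call(rbind, lapply(measures, rate_row)),
       n_plots = n, n_forested = denom)
}

# ---- Kolmogorov-Smirnov ------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs, evaluated
#' exactly at the pooled sample points (ties handled). The two-sided p-value
#' uses the asymptotic Kolmogorov series `2 * sum((-1)^(k-1) exp(-2 k^2 t^2))`
#' (first 100 terms) at `t = sqrt(n_a n_b / (n_a + n_b)) * D`.
#'
#' @param a,b numeric samples (non-empty).
#' @return list of class `ks_result`: `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("ks_two_sample: empty sample", call. = FALSE)
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  t <- sqrt(ne) * D
  if (t < 0.05) {
    # Kolmogorov CDF is < 1e-100 here; the truncated alternating series is
    # unreliable, the tail probability is 1
    p <- 1
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(list(D = D, p_value = p, n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.3g (n = %d, %d)\n",
              x$D, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Standing-dead trees versus disturbance class
#'
#' Compares the distribution of per-plot standing-dead counts between disturbed
#' and undisturbed plots with two-sided Kolmogorov-Smirnov tests (burned vs.
#' undisturbed; insect/disease vs. undisturbed).
#'
#' @param reference reference table with `dist_code` and `standing_dead`.
#' @return data.frame with one row per comparison: group sizes, mean counts,
#'   `D`, `p_value`; a comparison with an empty group is reported with `NA`
#'   statistics and a notice.
#' @export
dead_tree_disturbance_analysis <- function(reference) {
  sd0 <- reference$standing_dead[reference$dist_code == DIST_NONE]
  cmp <- function(code, label) {
    sdx <- reference$standing_dead[reference$dist_code == code]
    if (!length(sdx) || !length(sd0)) {
      message("disturbance analysis: group '", label,
              "' or undisturbed group empty; comparison skipped")
      return(data.frame(comparison = label, n_disturbed = length(sdx),
                        n_undisturbed = length(sd0),
                        mean_disturbed = if (length(sdx)) mean(sdx) else NA_real_,
                        mean_undisturbed = if (length(sd0)) mean(sd0) else NA_real_,
                        D = NA_real_, p_value = NA_real_))
    }
    ks <- ks_two_sample(sdx, sd0)
    data.frame(comparison = label, n_disturbed = length(sdx),
               n_undisturbed = length(sd0),
               mean_disturbed = mean(sdx), mean_undisturbed = mean(sd0),
               D = ks$D, p_value = ks$p_value)
  }
  rbind(cmp(DIST_FIRE, "fire_vs_undisturbed"),
        cmp(DIST_INSECT, "insect_vs_undisturbed"))
}

#' Read a confusion matrix from a labelled CSV
#'
#' First column = imputed class labels, remaining columns = target classes.
#'
#' @param path CSV path.
#' @return a `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  stopifnot(identical(labels, colnames(m)))
  as_confusion(m, labels)
}

#' Write a confusion matrix to a labelled CSV
#'
#' @param cm a `confusion_matrix`.
#' @param path output path.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(imputed = rownames(cm), unclass(cm), check.names = FALSE)
  names(df)[-1] <- colnames(cm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
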