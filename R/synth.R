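#' Synthetic-landscape configuration
#'
#' Desk-scale study conditions: a 200 x 200 grid of 30 m pixels, 500 reference
#' plots over 12 vegetation-group classes, smooth biophysical surfaces with a
#' 10-pixel correlation length, cover/height attribute noise of about 15% of
#' the narrowest bin width (1.5 cover points / 0.75 m — classified vegetation
#' rasters are blocky, with high within-stand uniformity), and disturbance
#' rates of 5% fire and 8% insect/disease over
#' 1999-2014 — proportions comparable to a national inventory network. Every
#' vegetation-group class receives at least one plot (the imputation engine's
#' hard requirement).
#'
#' @param nrow,ncol grid shape (pixels).
#' @param cellsize pixel edge, m.
#' @param n_plots single-condition reference plots.
#' @param n_val_plots multi-condition validation plots.
#' @param n_evg vegetation-group classes (<= 32).
#' @param corr_length correlation length of smooth surfaces, pixels.
#' @param cover_noise_sd,height_noise_sd pixel attribute noise (percent
#'   cover / metres).
#' @param p_fire,p_insect per-plot disturbance probabilities.
#' @param years candidate disturbance years.
#' @param trees_min,trees_lambda live trees per plot: `trees_min + Poisson(trees_lambda)`.
#' @param dead_lambda baseline standing-dead trees per plot (Poisson mean).
#' @param fire_dead_effect,insect_dead_effect additive Poisson means for extra
#'   standing-dead trees on disturbed plots.
#' @param nonforest_frac fraction of the grid below the 10% cover threshold.
#' @param n_zones vertical map-zone strips.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(nrow = 200, ncol = 200, cellsize = 30,
                         n_plots = 500, n_val_plots = 60, n_evg = 12,
                         corr_length = 10,
                         cover_noise_sd = 1.5, height_noise_sd = 0.75,
                         p_fire = 0.05, p_insect = 0.08,
                         years = 1999:2014,
                         trees_min = 4, trees_lambda = 12,
                         dead_lambda = 2,
                         fire_dead_effect = 5, insect_dead_effect = 3,
                         nonforest_frac = 0.12, n_zones = 1) {
  stopifnot(n_evg <= 32, n_plots >= n_evg,
            cover_noise_sd >= 0, height_noise_sd >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Smooth Gaussian surface: white noise smoothed by a separable squared-
# exponential kernel, standardized to mean 0 / sd 1.
gauss_field <- function(nr, nc, corr_length) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_length <= 0) return(w)
  smat <- function(n) {
    s <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * corr_length^2))
    s / rowSums(s)
  }
  f <- smat(nr) %*% w %*% t(smat(nc))
  (f - mean(f)) / stats::sd(f)
}

# Nudge a value away from bin edges so derived attributes re-bin stably.
nudge_off_edges <- function(x, edges, eps = 0.15) {
  for (e in edges) {
    close <- abs(x - e) < eps
    x[close] <- e + eps
  }
  x
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds smooth elevation/topography/biophysical surfaces, blocky
#' vegetation-group regions (nearest-seed growth), a non-forest margin, a plot
#' network in which each pixel descends from its nearest same-group plot, and
#' per-year disturbance layers consistent with the plots' disturbance records.
#' Pixel cover/height surfaces are the generating plot's values plus Gaussian
#' noise, so the truth map supports exact recovery checks at zero noise.
#'
#' @param config a [synth_config()].
#' @param seed integer run seed.
#' @return list: `raw` (named `rband`s: cover, height, evg, slope, aspect,
#'   elevation, bio1..bio6), `annual_disturbance` (layers for
#'   [collapse_disturbance()]), `zone` (`rband`), `truth` (list: `plot_index`
#'   `rband`, `plots` data.frame of true plot attributes), `crs`.
#' @export
generate_landscape <- function(config = synth_config(), seed = 1L) {
  set.seed(rng_substream_seed(seed, "landscape"))
  nr <- config$nrow; nc <- config$ncol; cs <- config$cellsize
  crs <- crs_aeqd(lon0 = -105, lat0 = 45)
  mk <- function(m) rband(m, 0, 0, cs, crs = crs)

  f <- replicate(9, gauss_field(nr, nc, config$corr_length), simplify = FALSE)
  elevation <- 1500 + 400 * f[[1]]
  slope <- pmin(pmax(12 + 9 * f[[2]], 0), 55)
  aspect <- (180 + 130 * f[[3]]) %% 360
  bio <- list(
    bio1 = 2200 + 300 * f[[4]],            # photosynthetically active radiation
    bio2 = 800 + 250 * f[[5]],             # annual precipitation, mm
    bio3 = 55 + 12 * f[[6]],               # relative humidity, %
    bio4 = 18 + 5 * f[[7]],                # max temperature, C
    bio5 = 2 + 4 * f[[8]],                 # min temperature, C
    bio6 = 9 + 3 * f[[9]]                  # vapour pressure deficit, hPa
  )

  # blocky vegetation-group regions: nearest of 3 seeded patches per class
  evg_codes <- 600L + seq_len(config$n_evg)
  n_seed <- config$n_evg * 3L
  sr <- sample.int(nr, n_seed, replace = TRUE)
  sc <- sample.int(nc, n_seed, replace = TRUE)
  slab <- c(evg_codes, sample(evg_codes, n_seed - config$n_evg, replace = TRUE))
  pr <- as.vector(row(matrix(0, nr, nc)))
  pc <- as.vector(col(matrix(0, nr, nc)))
  d2 <- outer(pr, sr, "-")^2 + outer(pc, sc, "-")^2
  evg_vec <- slab[max.col(-d2, ties.method = "first")]
  evg <- matrix(evg_vec, nr, nc)

  # non-forest margin from one more smooth field
  f0 <- gauss_field(nr, nc, config$corr_length)
  nonforest <- f0 < stats::quantile(f0, config$nonforest_frac)

  zone <- matrix(rep(ceiling(seq_len(nc) / nc * config$n_zones), each = nr),
                 nr, nc)

  # plot network: sample forest pixels, guarantee every class has a plot
  forest_cells <- which(!nonforest)
  pk <- sample(forest_cells, config$n_plots)
  slot <- config$n_plots
  for (code in evg_codes) {
    cells_c <- forest_cells[evg[forest_cells] == code]
    if (!length(cells_c)) next
    if (!any(evg[pk] == code)) {
      pk[slot] <- cells_c[1]
      slot <- slot - 1L
    }
  }
  # structure surfaces: cover and height vary smoothly along the landscape
  # (twice the biophysical correlation length) with a vegetation-group offset,
  # the way canopy structure tracks gradients on real landscapes
  f_cov <- gauss_field(nr, nc, 2 * config$corr_length)
  f_hgt <- gauss_field(nr, nc, 2 * config$corr_length)
  cov_off <- sample(seq(-10, 10, length.out = config$n_evg))
  hgt_off <- sample(seq(-6, 6, length.out = config$n_evg))
  pl_evg <- evg[pk]
  ci <- match(pl_evg, evg_codes)
  pl_cover <- pmin(pmax(55 + 30 * f_cov[pk] + cov_off[ci], 10.5), 99.5)
  pl_cover <- nudge_off_edges(pl_cover, seq(10, 100, 10))
  pl_height <- pmin(pmax(20 + 13 * f_hgt[pk] + hgt_off[ci], 1), 85)
  pl_height <- nudge_off_edges(pl_height, HEIGHT_EDGES)

  dr <- stats::runif(config$n_plots)
  pl_dist <- ifelse(dr < config$p_fire, DIST_FIRE,
                    ifelse(dr < config$p_fire + config$p_insect, DIST_INSECT,
                           DIST_NONE))
  pl_year <- ifelse(pl_dist == DIST_NONE, DIST_YEAR_NONE,
                    sample(config$years, config$n_plots, replace = TRUE))
  # some burned plots also carry an older insect/disease record: exercises
  # the fire-precedence rule end to end
  extra_insect <- pl_dist == DIST_FIRE & stats::runif(config$n_plots) < 0.3
  extra_year <- ifelse(extra_insect,
                       sample(config$years, config$n_plots, replace = TRUE),
                       NA)

  # generating plot of each forest pixel: nearest plot of the same class
  gen <- matrix(NA_integer_, nr, nc)
  prow <- ((pk - 1) %% nr) + 1; pcol <- ((pk - 1) %/% nr) + 1
  for (code in unique(evg_vec)) {
    cells_c <- forest_cells[evg[forest_cells] == code]
    if (!length(cells_c)) next
    plots_c <- which(pl_evg == code)
    if (!length(plots_c)) {            # class with no plot: drop from forest
      nonforest[cells_c] <- TRUE
      next
    }
    cr <- ((cells_c - 1) %% nr) + 1; cc <- ((cells_c - 1) %/% nr) + 1
    dd <- outer(cr, prow[plots_c], "-")^2 + outer(cc, pcol[plots_c], "-")^2
    gen[cells_c] <- plots_c[max.col(-dd, ties.method = "first")]
  }
  forest_cells <- which(!nonforest)

  # attribute surfaces descend from the generating plot
  cover <- matrix(stats::runif(nr * nc, 0, 9.5), nr, nc)   # non-forest default
  height <- matrix(stats::runif(nr * nc, 0, 4), nr, nc)
  gvec <- gen[forest_cells]
  cover[forest_cells] <- pmin(pmax(
    pl_cover[gvec] + stats::rnorm(length(gvec), 0, config$cover_noise_sd),
    10), 100)
  height[forest_cells] <- pmin(pmax(
    pl_height[gvec] + stats::rnorm(length(gvec), 0, config$height_noise_sd),
    0), 95)
  dist_code_px <- matrix(DIST_NONE, nr, nc)
  dist_year_px <- matrix(DIST_YEAR_NONE, nr, nc)
  dist_code_px[forest_cells] <- pl_dist[gvec]
  dist_year_px[forest_cells] <- pl_year[gvec]
  extra_px_year <- matrix(NA_real_, nr, nc)
  extra_px_year[forest_cells] <- extra_year[gvec]

  annual <- list()
  for (y in sort(unique(c(pl_year[pl_year > 0], extra_year[!is.na(extra_year)])))) {
    lay <- matrix(0, nr, nc)
    lay[dist_year_px == y & dist_code_px == DIST_FIRE] <- DIST_FIRE
    lay[dist_year_px == y & dist_code_px == DIST_INSECT] <- DIST_INSECT
    ins <- !is.na(extra_px_year) & extra_px_year == y & lay == 0
    lay[ins] <- DIST_INSECT
    annual[[length(annual) + 1]] <- list(year = y, band = mk(lay))
  }

  xs <- (pcol - 0.5) * cs
  ys <- (nr - prow + 0.5) * cs
  plots <- data.frame(
    plot_index = seq_len(config$n_plots),
    CN = 1000L + seq_len(config$n_plots),
    X = xs, Y = ys,
    evg = pl_evg, cover_pct = pl_cover, height_m = pl_height,
    cover_bin = bin_cover(pl_cover), height_bin = bin_height(pl_height),
    dist_code = pl_dist, dist_year = pl_year,
    extra_insect_year = extra_year,
    zone = zone[pk]
  )

  list(
    raw = c(list(cover = mk(cover), height = mk(height), evg = mk(evg),
                 slope = mk(slope), aspect = mk(aspect),
                 elevation = mk(elevation)),
            lapply(bio, mk)),
    annual_disturbance = annual,
    zone = mk(zone),
    truth = list(plot_index = mk(gen + 0), plots = plots),
    crs = crs
  )
}

#' Read the shipped synthetic species pools
#'
#' Fixed per-vegetation-group species pools (8-15 codes each, drawn from
#' inventory-style species codes) so that species-match validation against
#' basal-area dominants is meaningful on synthetic data. The pools are
#' synthetic: codes are realistic but the group/species associations are
#' invented.
#'
#' @return data.frame with columns `evg`, `spcd`, `weight`.
#' @export
read_species_pools <- function() {
  utils::read.csv(system.file("extdata", "species_pools_synthetic.csv",
                              package = "plotimpute"))
}

# Build one plot's tree list so its derived attributes land exactly on the
# plot's true cover and height: heights are scaled so the nine-tree top-stratum
# rule returns height_m, crown radii so the overlap-corrected cover equals
# cover_pct.
synth_tree_list <- function(cn, cover_pct, height_m, n_live, n_dead, pool,
                            unit_area = 10000, max_retry = 20) {
  for (attempt in seq_len(max_retry)) {
    ht <- height_m * exp(stats::rnorm(n_live, 0, 0.25))
    tsh <- top_stratum_height(data.frame(STATUSCD = STATUS_LIVE, HT = ht))
    ht <- ht * height_m / tsh
    dia <- pmax(1.5, ht * 1.6 + stats::rnorm(n_live, 0, 4))
    tpa <- stats::runif(n_live, 5, 60)
    r0 <- stats::runif(n_live, 1, 3.5)
    a0 <- sum(pi * r0^2 * tpa) / unit_area
    target <- -log(1 - cover_pct / 100)
    r <- r0 * sqrt(target / a0)
    nsp <- min(nrow(pool), sample(1:3, 1))
    spp <- pool$spcd[sample.int(nrow(pool), nsp, prob = pool$weight)]
    sp <- spp[sample.int(nsp, n_live, replace = TRUE, prob = nsp:1)]
    live <- data.frame(PLT_CN = cn, STATUSCD = STATUS_LIVE,
                       STANDING_DEAD_CD = 0L, SPCD = sp, DIA = dia, HT = ht,
                       TPA_UNADJ = tpa, CROWN_RADIUS = r)
    trees <- live
    if (n_dead > 0) {
      dht <- height_m * exp(stats::rnorm(n_dead, -0.2, 0.3))
      trees <- rbind(trees, data.frame(
        PLT_CN = cn, STATUSCD = STATUS_DEAD, STANDING_DEAD_CD = 1L,
        SPCD = pool$spcd[sample.int(nrow(pool), n_dead, replace = TRUE)],
        DIA = pmax(1.5, dht * 1.6), HT = dht,
        TPA_UNADJ = stats::runif(n_dead, 5, 30), CROWN_RADIUS = 0))
    }
    ok_cov <- isTRUE(all.equal(bin_cover(canopy_cover(trees, unit_area)),
                               bin_cover(cover_pct)))
    ok_hgt <- isTRUE(all.equal(bin_height(top_stratum_height(trees)),
                               bin_height(height_m)))
    if (ok_cov && ok_hgt) return(trees)
  }
  stop(sprintf(paste0("generation error: tree list for plot %s did not land in",
                      " bins (cover %.1f%%, height %.1f m) after %d attempts"),
               format(cn), cover_pct, height_m, max_retry), call. = FALSE)
}

#' Generate plot and tree tables for a synthetic landscape
#'
#' Synthesizes a tree list for every true plot whose derived canopy cover and
#' top-stratum height reproduce the plot's assigned bins, with species drawn
#' from the vegetation group's pool and elevated standing-dead counts on
#' disturbed plots (additive Poisson effects). Also places multi-condition
#' validation plots at random forest pixels, with attributes descending from
#' their pixel's generating plot.
#'
#' @param config a [synth_config()].
#' @param landscape output of [generate_landscape()] (same config).
#' @param seed integer run seed.
#' @return list: `plots` (plot table including validation plots, see
#'   [table_contract]), `trees` (tree table).
#' @export
generate_plots <- function(config, landscape, seed = 1L) {
  set.seed(rng_substream_seed(seed, "plots"))
  pools <- read_species_pools()
  tp <- landscape$truth$plots
  n <- nrow(tp)

  plot_rows <- vector("list", n)
  tree_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- pools[pools$evg == tp$evg[i], , drop = FALSE]
    if (nrow(pool) == 0)
      pool <- data.frame(evg = tp$evg[i], spcd = 999L, weight = 1)
    n_live <- config$trees_min + stats::rpois(1, config$trees_lambda)
    n_dead <- stats::rpois(1, config$dead_lambda) +
      if (tp$dist_code[i] == DIST_FIRE) stats::rpois(1, config$fire_dead_effect)
      else if (tp$dist_code[i] == DIST_INSECT) stats::rpois(1, config$insect_dead_effect)
      else 0L
    trees <- synth_tree_list(tp$CN[i], tp$cover_pct[i], tp$height_m[i],
                             n_live, n_dead, pool)
    tree_rows[[i]] <- trees
    has_extra <- !is.na(tp$extra_insect_year[i])
    plot_rows[[i]] <- data.frame(
      CN = tp$CN[i], X = tp$X[i], Y = tp$Y[i], CONDCNT = 1L,
      EVG = tp$evg[i],
      DSTRBCD1 = tp$dist_code[i],
      DSTRBYR1 = tp$dist_year[i],
      DSTRBCD2 = if (has_extra) DIST_INSECT else 0L,
      DSTRBYR2 = if (has_extra) tp$extra_insect_year[i] else 0L,
      DSTRBCD3 = 0L, DSTRBYR3 = 0L)
  }

  # multi-condition validation plots at random forest pixels
  gen <- landscape$truth$plot_index$values
  cells <- sample(which(!is.na(gen)), config$n_val_plots)
  nr <- config$nrow; cs <- config$cellsize
  vrow <- ((cells - 1) %% nr) + 1; vcol <- ((cells - 1) %/% nr) + 1
  val_rows <- vector("list", config$n_val_plots)
  vtree_rows <- vector("list", config$n_val_plots)
  for (j in seq_len(config$n_val_plots)) {
    src <- tp[gen[cells[j]], ]
    cn <- 90000L + j
    vcov <- nudge_off_edges(
      pmin(pmax(src$cover_pct + stats::rnorm(1, 0, 6), 10.5), 99.5),
      seq(10, 100, 10))
    vhgt <- nudge_off_edges(
      pmin(pmax(src$height_m + stats::rnorm(1, 0, 2.5), 1), 85),
      HEIGHT_EDGES)
    pool <- pools[pools$evg == src$evg, , drop = FALSE]
    if (nrow(pool) == 0)
      pool <- data.frame(evg = src$evg, spcd = 999L, weight = 1)
    n_live <- config$trees_min + stats::rpois(1, config$trees_lambda)
    vtree_rows[[j]] <- synth_tree_list(cn, vcov, vhgt, n_live,
                                       stats::rpois(1, config$dead_lambda), pool)
    val_rows[[j]] <- data.frame(
      CN = cn, X = (vcol[j] - 0.5) * cs, Y = (nr - vrow[j] + 0.5) * cs,
      CONDCNT = 2L, EVG = src$evg,
      DSTRBCD1 = src$dist_code, DSTRBYR1 = src$dist_year,
      DSTRBCD2 = 0L, DSTRBYR2 = 0L, DSTRBCD3 = 0L, DSTRBYR3 = 0L)
  }

  list(plots = rbind(do.call(rbind, plot_rows), do.call(rbind, val_rows)),
       trees = rbind(do.call(rbind, tree_rows), do.call(rbind, vtree_rows)))
}

#' Write a synthetic landscape to disk in pipeline formats
#'
#' Everything is written in the formats the pipeline readers consume: ASCII
#' grids with a YAML stack manifest for the raw bands, one grid per
#' disturbance year (listed in `annual.yml`), zone and truth grids, and CSV
#' plot/tree tables.
#'
#' @param landscape from [generate_landscape()].
#' @param tables from [generate_plots()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(landscape$raw, file.path(dir, "raw"))
  ad <- file.path(dir, "annual")
  dir.create(ad, showWarnings = FALSE)
  entries <- list()
  for (l in landscape$annual_disturbance) {
    f <- sprintf("dist_%d.asc", l$year)
    write_ascii_grid(l$band, file.path(ad, f))
    entries[[as.character(l$year)]] <- f
  }
  yaml::write_yaml(entries, file.path(ad, "annual.yml"))
  write_ascii_grid(landscape$zone, file.path(dir, "zone.asc"))
  write_ascii_grid(landscape$truth$plot_index, file.path(dir, "truth_plot_index.asc"))
  utils::write.csv(landscape$truth$plots, file.path(dir, "truth_plots.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(tables$trees, file.path(dir, "trees.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read annual disturbance layers written by [write_landscape()]
#'
#' @param dir the `annual/` directory.
#' @param crs CRS to attach to the layers.
#' @return list of `list(year =, band =)` entries.
#' @export
read_annual_disturbance <- function(dir, crs = NULL) {
  entries <- yaml::read_yaml(file.path(dir, "annual.yml"))
  lapply(names(entries), function(y)
    list(year = as.integer(y),
         band = read_ascii_grid(file.path(dir, entries[[y]]), crs)))
}
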