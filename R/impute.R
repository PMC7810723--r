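#' Imputation configuration
#'
#' Defaults follow the published national-scale run: 83 classification trees
#' per response variable (three responses: cover bin, height bin, vegetation
#' group — 249 trees in all), each grown on a 66% subsample drawn *without*
#' replacement, splitting stops when a child bucket would fall below five
#' observations, and `floor(sqrt(p))` candidate variables are drawn at each
#' node. When `responses_as_split_candidates` is `TRUE` (default) the other
#' response bands participate in routing alongside the predictors, so target
#' pixels are matched on both predictor and response values.
#'
#' @param trees_per_response trees grown per response variable.
#' @param responses response variable names.
#' @param predictors predictor variable names.
#' @param categorical which variables are categorical (subset splits).
#' @param bootstrap_fraction subsample fraction per tree (0 < f < 1).
#' @param min_bucket minimum observations per terminal bucket.
#' @param responses_as_split_candidates logical; see above.
#' @param max_classes_per_run refuse zones with more vegetation-group classes
#'   than this.
#' @return list of class `impute_config`.
#' @export
impute_config <- function(trees_per_response = 83,
                          responses = c("cover_bin", "height_bin", "evg"),
                          predictors = c("lat", "lon", "slope", "aspect",
                                         "elevation", paste0("bio", 1:6),
                                         "dist_code", "dist_year"),
                          categorical = c("evg", "dist_code"),
                          bootstrap_fraction = 0.66,
                          min_bucket = 5,
                          responses_as_split_candidates = TRUE,
                          max_classes_per_run = 32) {
  stopifnot(trees_per_response >= 1,
            bootstrap_fraction > 0, bootstrap_fraction < 1,
            min_bucket >= 2)
  structure(list(trees_per_response = as.integer(trees_per_response),
                 responses = responses, predictors = predictors,
                 categorical = categorical,
                 bootstrap_fraction = bootstrap_fraction,
                 min_bucket = as.integer(min_bucket),
                 responses_as_split_candidates = responses_as_split_candidates,
                 max_classes_per_run = as.integer(max_classes_per_run)),
            class = "impute_config")
}

#' Derive a reproducible sub-seed from a run seed and a stream name
#'
#' One seeded generator per run, forked per stage by named streams, keeps
#' stage-level reproducibility independent of pipeline ordering. The derived
#' seed stays below 2^31.
#'
#' @param seed integer run seed.
#' @param name stream name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
rng_substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(1 + (h * 7919 + as.numeric(seed)) %% 2147483645)
}

# ---- single classification tree ---------------------------------------------

gini_from_counts <- function(counts, n) 1 - sum((counts / n)^2)

# Best split of node rows `idx` on variable `var`.
# Returns NULL or list(gain, thr, lset, rset, nL) where for categorical vars
# lset/rset are the level sets routed left/right.
best_split_var <- function(xv, yv, K, min_bucket, categorical, gini_parent) {
  n <- length(xv)
  if (categorical) {
    # order levels by the within-level proportion of the node majority class,
    # then scan as if ordered
    tabs <- table(factor(yv, levels = seq_len(K)), xv)
    lev <- colnames(tabs)
    maj <- which.max(rowSums(tabs))
    p <- tabs[maj, ] / pmax(1, colSums(tabs))
    ord_lev <- lev[order(p, lev)]
    rank <- match(as.character(xv), ord_lev)
    o <- order(rank)
    xs <- rank[o]
  } else {
    o <- order(xv)
    xs <- xv[o]
  }
  ys <- yv[o]
  cc <- matrix(0, n, K)
  cc[cbind(seq_len(n), ys)] <- 1
  cc <- apply(cc, 2, cumsum)
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1)
  nL <- seq_len(n - 1)
  valid <- xs[nL] < xs[nL + 1] & nL >= min_bucket & (n - nL) >= min_bucket
  if (!any(valid)) return(NULL)
  tot <- cc[n, ]
  ccL <- cc[nL, , drop = FALSE]
  ccR <- matrix(tot, n - 1, length(tot), byrow = TRUE) - ccL
  gL <- 1 - rowSums((ccL / nL)^2)
  gR <- 1 - rowSums((ccR / (n - nL))^2)
  child <- (nL * gL + (n - nL) * gR) / n
  child[!valid] <- Inf
  i <- which.min(child)           # gain ties: smallest cut, deterministic
  gain <- gini_parent - child[i]
  if (gain <= 1e-12) return(NULL)
  if (categorical) {
    list(gain = gain, thr = NA_real_, lsets = ord_lev, cut = xs[i], nL = nL[i])
  } else {
    list(gain = gain, thr = (xs[i] + xs[i + 1]) / 2, lset = NULL, rset = NULL,
         nL = nL[i])
  }
}

# Grow one classification tree on the in-bag rows.
# X: data.frame of all reference rows; y: integer class codes 1..K (all rows);
# candidates: variable names; cat_vars: which are categorical.
grow_tree <- function(X, y, K, candidates, cat_vars, mtry, min_bucket, inbag) {
  env <- new.env()
  env$var <- character(0); env$thr <- numeric(0)
  env$lset <- list(); env$rset <- list()
  env$left <- integer(0); env$right <- integer(0)
  env$leaf_id <- integer(0); env$nL <- integer(0); env$nR <- integer(0)
  env$leaf_rows <- list(); env$leaf_major <- integer(0)
  env$n_leaves <- 0L

  alloc <- function() {
    k <- length(env$var) + 1L
    env$var[k] <- NA_character_; env$thr[k] <- NA_real_
    env$lset[k] <- list(NULL); env$rset[k] <- list(NULL)
    env$left[k] <- 0L; env$right[k] <- 0L
    env$leaf_id[k] <- 0L; env$nL[k] <- 0L; env$nR[k] <- 0L
    k
  }
  make_leaf <- function(k, idx) {
    env$n_leaves <- env$n_leaves + 1L
    env$leaf_id[k] <- env$n_leaves
    env$leaf_rows[[env$n_leaves]] <- idx
    cnt <- tabulate(y[idx], nbins = K)
    env$leaf_major[env$n_leaves] <- which.max(cnt)  # ties: smallest class
    k
  }
  build <- function(idx) {
    k <- alloc()
    n <- length(idx)
    cnt <- tabulate(y[idx], nbins = K)
    gp <- gini_from_counts(cnt, n)
    if (n < 2 * min_bucket || gp <= 0) return(make_leaf(k, idx))
    cand <- candidates[sort(sample.int(length(candidates),
                                       min(mtry, length(candidates))))]
    best <- NULL; best_var <- NA_character_
    for (v in cand) {
      s <- best_split_var(X[[v]][idx], y[idx], K, min_bucket,
                          v %in% cat_vars, gp)
      if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
        best <- s; best_var <- v
      }
    }
    if (is.null(best)) return(make_leaf(k, idx))
    env$var[k] <- best_var
    if (best_var %in% cat_vars) {
      lv <- best$lsets[seq_len(best$cut)]
      rv <- best$lsets[-seq_len(best$cut)]
      env$lset[[k]] <- lv; env$rset[[k]] <- rv
      goleft <- as.character(X[[best_var]][idx]) %in% lv
    } else {
      env$thr[k] <- best$thr
      goleft <- X[[best_var]][idx] <= best$thr
    }
    idxL <- idx[goleft]; idxR <- idx[!goleft]
    env$nL[k] <- length(idxL); env$nR[k] <- length(idxR)
    env$left[k] <- build(idxL)
    env$right[k] <- build(idxR)
    k
  }
  build(inbag)
  list(var = env$var, thr = env$thr, lset = env$lset, rset = env$rset,
       left = env$left, right = env$right, leaf_id = env$leaf_id,
       nL = env$nL, nR = env$nR,
       leaf_rows = env$leaf_rows, leaf_major = env$leaf_major,
       inbag = inbag)
}

#' Route observations to a tree's terminal buckets
#'
#' A categorical value never seen at a node during training is routed to the
#' child that held more in-bag observations.
#'
#' @param tree a fitted tree (internal representation).
#' @param X data.frame of observations carrying every split variable.
#' @return integer vector of leaf ids, one per row of `X`.
#' @export
route_tree <- function(tree, X) {
  out <- integer(nrow(X))
  rec <- function(k, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (tree$leaf_id[k] > 0L) { out[idx] <<- tree$leaf_id[k]; return(invisible(NULL)) }
    v <- tree$var[k]
    if (!is.null(tree$lset[[k]])) {
      xv <- as.character(X[[v]][idx])
      gl <- xv %in% tree$lset[[k]]
      gr <- xv %in% tree$rset[[k]]
      unseen <- !(gl | gr)
      if (any(unseen)) {       # unseen-level policy: larger child
        if (tree$nL[k] >= tree$nR[k]) gl[unseen] <- TRUE else gr[unseen] <- TRUE
      }
      rec(tree$left[k], idx[gl])
      rec(tree$right[k], idx[!gl])
    } else {
      gl <- X[[v]][idx] <= tree$thr[k]
      rec(tree$left[k], idx[gl])
      rec(tree$right[k], idx[!gl])
    }
  }
  rec(1L, seq_len(nrow(X)))
  out
}

# ---- model fitting ----------------------------------------------------------

#' Fit the random-forest imputation model
#'
#' Grows `trees_per_response` classification trees for each response variable
#' on 66% subsamples of the reference plots and records, per tree, which
#' in-bag plots occupy each terminal bucket — the co-occurrence index used at
#' imputation time. Out-of-bag misclassification is computed per response.
#'
#' @param reference reference table from [build_reference_table()] (or any
#'   data.frame with `plot_id` plus all configured variables).
#' @param config an [impute_config()].
#' @param seed integer seed for subsampling and candidate draws.
#' @return object of class `imputation_model`: per-response tree lists, the
#'   reference table, response label sets, OOB error per response.
#' @export
fit_imputation <- function(reference, config = impute_config(), seed = 1L) {
  n <- nrow(reference)
  stopifnot(n >= 1)
  vars_needed <- union(config$predictors, config$responses)
  miss <- setdiff(vars_needed, names(reference))
  if (length(miss)) stop("reference table lacks variables: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  set.seed(rng_substream_seed(seed, "fit"))
  nbag <- max(1L, floor(config$bootstrap_fraction * n))
  forests <- list(); labels <- list(); oob <- numeric(0)
  single_plot <- n == 1L
  if (single_plot)
    warning("single reference plot: out-of-bag error undefined, reported as 0")
  for (yname in config$responses) {
    labs <- sort(unique(reference[[yname]]))
    y <- match(reference[[yname]], labs)
    K <- length(labs)
    # with responses_as_split_candidates the response surfaces (available for
    # target pixels just like the predictors) participate in routing,
    # including the forest's own response — matching on the response value is
    # the point of the method, and it is what drives the very low OOB errors
    candidates <- config$predictors
    if (config$responses_as_split_candidates)
      candidates <- c(candidates, config$responses)
    mtry <- max(1L, floor(sqrt(length(candidates))))
    trees <- vector("list", config$trees_per_response)
    votes <- matrix(0L, n, K)
    for (t in seq_len(config$trees_per_response)) {
      inbag <- sort(sample.int(n, nbag))
      tr <- grow_tree(reference, y, K, candidates, config$categorical,
                      mtry, config$min_bucket, inbag)
      trees[[t]] <- tr
      oob_idx <- setdiff(seq_len(n), inbag)
      if (length(oob_idx)) {
        lf <- route_tree(tr, reference[oob_idx, , drop = FALSE])
        pred <- tr$leaf_major[lf]
        votes[cbind(oob_idx, pred)] <- votes[cbind(oob_idx, pred)] + 1L
      }
    }
    voted <- rowSums(votes) > 0
    if (!any(voted)) {
      if (!single_plot)
        warning("no out-of-bag observations; OOB error reported as 0")
      err <- 0
    } else {
      pred <- max.col(votes[voted, , drop = FALSE], ties.method = "first")
      err <- mean(pred != y[voted])
    }
    forests[[yname]] <- trees
    labels[[yname]] <- labs
    oob[yname] <- err
  }
  structure(list(forests = forests, labels = labels, reference = reference,
                 config = config, oob = oob, seed = seed),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> %d plots, %d trees (%d per response)\n",
              nrow(x$reference),
              length(x$forests) * x$config$trees_per_response,
              x$config$trees_per_response))
  cat("OOB error:", paste(names(x$oob), sprintf("%.4f", x$oob),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Out-of-bag error table
#'
#' @param model an `imputation_model`.
#' @return data.frame with columns `response`, `oob_error`.
#' @export
oob_report <- function(model) {
  data.frame(response = names(model$oob), oob_error = as.numeric(model$oob),
             row.names = NULL)
}

# ---- imputation -------------------------------------------------------------

# Masked-pixel variable table in row-major pixel order.
pixel_table <- function(stack, mask = stack$forest_mask$values > 0) {
  which_masked <- which(mask)                       # column-major
  rows <- row(mask)[which_masked]; cols <- col(mask)[which_masked]
  o <- order(rows, cols)                            # row-major processing order
  cells <- which_masked[o]
  vars <- setdiff(names(stack), "forest_mask")
  X <- as.data.frame(lapply(stack[vars], function(b) b$values[cells]))
  attr(X, "cells") <- cells
  X
}

#' Terminal-bucket co-occurrence tally
#'
#' Runs each observation down every tree of every response forest and counts,
#' per reference plot, the trees in which the observation and the (in-bag)
#' plot share a terminal bucket.
#'
#' @param model an [fit_imputation()] model.
#' @param X data.frame of observations carrying all routing variables.
#' @return numeric matrix, `nrow(X)` x number of reference plots.
#' @export
co_occurrence_votes <- function(model, X) {
  npix <- nrow(X)
  votes <- matrix(0, npix, nrow(model$reference))
  for (yname in names(model$forests)) {
    for (tr in model$forests[[yname]]) {
      lf <- route_tree(tr, X)
      by_leaf <- split(seq_len(npix), lf)
      for (leaf in names(by_leaf)) {
        plots <- tr$leaf_rows[[as.integer(leaf)]]
        pix <- by_leaf[[leaf]]
        votes[pix, plots] <- votes[pix, plots] + 1
      }
    }
  }
  votes
}

#' Impute a reference plot ID to every masked pixel
#'
#' Each masked pixel's variable vector is run down all trees of all response
#' forests; every in-bag reference plot sharing the pixel's terminal bucket
#' contributes one vote per tree. The plot with the most votes is assigned;
#' ties are split uniformly at random (seeded, pixels in row-major order).
#'
#' @param model an [fit_imputation()] model.
#' @param stack target stack from [prep_target_stack()].
#' @param seed integer seed for tie-breaking.
#' @return object of class `imputed_map`: `plot_id` (`rband` of assigned plot
#'   IDs, nodata off-mask), `vote_margin` (`rband`, winning minus runner-up
#'   vote share), and the reference attribute table.
#' @export
impute_map <- function(model, stack, seed = 1L) {
  check_reference_coverage(stack$evg$values[stack$forest_mask$values > 0],
                           model$reference$evg)
  X <- pixel_table(stack)
  cells <- attr(X, "cells")
  npix <- nrow(X)
  votes <- co_occurrence_votes(model, X)
  set.seed(rng_substream_seed(seed, "tiebreak"))
  assigned <- max.col(votes, ties.method = "random")
  vmax <- votes[cbind(seq_len(npix), assigned)]
  votes[cbind(seq_len(npix), assigned)] <- -Inf
  v2 <- votes[cbind(seq_len(npix), max.col(votes, ties.method = "first"))]
  ntrees <- length(model$forests) * model$config$trees_per_response
  g <- stack$forest_mask
  idmat <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  idmat[cells] <- model$reference$plot_id[assigned]
  mgmat <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  mgmat[cells] <- (vmax - pmax(v2, 0)) / ntrees
  structure(list(
    plot_id = rband(idmat, g$xll, g$yll, g$cellsize, g$nodata, g$crs),
    vote_margin = rband(mgmat, g$xll, g$yll, g$cellsize, g$nodata, g$crs),
    reference = model$reference,
    seed = seed),
    class = "imputed_map")
}

#' Raster of a plot attribute over an imputed map
#'
#' @param imap an `imputed_map`.
#' @param attribute column of the reference table to map (e.g. `"cover_bin"`).
#' @return an `rband` with the attribute of each pixel's imputed plot.
#' @export
attribute_raster <- function(imap, attribute) {
  ref <- imap$reference
  stopifnot(attribute %in% names(ref))
  g <- imap$plot_id
  m <- matrix(ref[[attribute]][match(g$values, ref$plot_id)],
              nrow(g$values), ncol(g$values))
  rband(m, g$xll, g$yll, g$cellsize, g$nodata, g$crs)
}

#' Zonal imputation
#'
#' Fits and imputes independently for each zone of a zone raster, restricting
#' the reference plots to those whose vegetation group occurs in the zone, and
#' stitches the per-zone maps. A zone whose masked pixels span more vegetation
#' groups than `max_classes_per_run` is refused with guidance to subdivide it;
#' a zone with no reference plots is an error.
#'
#' @param reference reference table.
#' @param stack target stack.
#' @param zone_band `rband` of integer zone labels, aligned with the stack.
#' @param config an [impute_config()].
#' @param seed run seed; per-zone seeds are forked substreams.
#' @return an `imputed_map` covering all zones, with per-zone models in
#'   `$models` and a per-zone OOB table in `$oob`.
#' @export
run_zonal <- function(reference, stack, zone_band, config = impute_config(),
                      seed = 1L) {
  stop_if_misaligned(stack$forest_mask, zone_band, "zone raster")
  mask <- stack$forest_mask$values > 0
  zvals <- zone_band$values
  zones <- sort(unique(zvals[mask & !is.na(zvals)]))
  g <- stack$forest_mask
  idmat <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  mgmat <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  models <- list(); oob_rows <- list()
  for (z in zones) {
    zmask <- mask & !is.na(zvals) & zvals == z
    evgs_z <- unique(stats::na.omit(stack$evg$values[zmask]))
    if (length(evgs_z) > config$max_classes_per_run)
      stop(sprintf(paste0("zone %s has %d vegetation-group classes, more than ",
                          "max_classes_per_run = %d; subdivide the zone into ",
                          "smaller map zones and rerun"),
                   format(z), length(evgs_z), config$max_classes_per_run),
           call. = FALSE)
    ref_z <- reference[reference$evg %in% evgs_z, , drop = FALSE]
    if (nrow(ref_z) == 0)
      stop("zone-skipped error: zone ", format(z), " has no reference plots",
           call. = FALSE)
    check_reference_coverage(stack$evg$values[zmask], ref_z$evg)
    zseed <- rng_substream_seed(seed, paste0("zone:", format(z)))
    model <- fit_imputation(ref_z, config, seed = zseed)
    stack_z <- stack
    fmz <- g; fmz$values <- zmask * 1
    stack_z$forest_mask <- fmz
    imap_z <- impute_map(model, stack_z, seed = zseed)
    idmat[zmask] <- imap_z$plot_id$values[zmask]
    mgmat[zmask] <- imap_z$vote_margin$values[zmask]
    models[[format(z)]] <- model
    oob_rows[[format(z)]] <- cbind(zone = z, oob_report(model))
  }
  structure(list(
    plot_id = rband(idmat, g$xll, g$yll, g$cellsize, g$nodata, g$crs),
    vote_margin = rband(mgmat, g$xll, g$yll, g$cellsize, g$nodata, g$crs),
    reference = reference,
    models = models,
    oob = do.call(rbind, oob_rows),
    seed = seed),
    class = "imputed_map")
}
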