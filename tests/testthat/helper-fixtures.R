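# Shared fixture builders and independent oracles.

ALL_VARS <- c("lat", "lon", "slope", "aspect", "elevation", paste0("bio", 1:6),
              "dist_code", "dist_year", "cover_bin", "height_bin", "evg")

# A reference table of n plots with reproducible, mildly structured variables.
mk_reference <- function(n, seed = 42, n_evg = 3) {
  set.seed(seed)
  data.frame(
    plot_id = 1000L + seq_len(n),
    lat = 45 + stats::runif(n, 0, 0.05),
    lon = -105 + stats::runif(n, 0, 0.05),
    slope = stats::runif(n, 0, 40),
    aspect = stats::runif(n, 0, 360),
    elevation = stats::runif(n, 1000, 2000),
    bio1 = stats::rnorm(n, 2200, 200), bio2 = stats::rnorm(n, 800, 150),
    bio3 = stats::rnorm(n, 55, 8), bio4 = stats::rnorm(n, 18, 3),
    bio5 = stats::rnorm(n, 2, 2), bio6 = stats::rnorm(n, 9, 2),
    dist_code = sample(0:2, n, replace = TRUE, prob = c(.8, .1, .1)),
    dist_year = 0L,
    cover_bin = sample(seq(15, 95, 10), n, replace = TRUE),
    height_bin = sample(c(3, 8, 18, 38, 70), n, replace = TRUE),
    evg = sample(600L + seq_len(n_evg), n, replace = TRUE)
  ) |>
    transform(dist_year = ifelse(dist_code > 0, 2005L, 0L))
}

# A stack whose masked pixels carry exactly the variables of an assigned plot
# (by row index into `ref`), laid out on an nr x nc grid.
mk_stack_from_ref <- function(ref, gen, cellsize = 30) {
  nr <- nrow(gen); nc <- ncol(gen)
  crs <- crs_aeqd(-105, 45)
  mk <- function(v) {
    m <- matrix(v[gen], nr, nc)
    rband(m, 0, 0, cellsize, crs = crs)
  }
  st <- lapply(ALL_VARS, function(vn) mk(ref[[vn]]))
  names(st) <- ALL_VARS
  st$forest_mask <- rband(matrix(1, nr, nc), 0, 0, cellsize, crs = crs)
  st
}

# Scalar tree walker: an independent re-implementation of leaf routing.
walk_tree <- function(tree, xrow) {
  k <- 1L
  while (tree$leaf_id[k] == 0L) {
    v <- tree$var[k]
    if (!is.null(tree$lset[[k]])) {
      xv <- as.character(xrow[[v]])
      if (xv %in% tree$lset[[k]]) k <- tree$left[k]
      else if (xv %in% tree$rset[[k]]) k <- tree$right[k]
      else k <- if (tree$nL[k] >= tree$nR[k]) tree$left[k] else tree$right[k]
    } else {
      k <- if (xrow[[v]] <= tree$thr[k]) tree$left[k] else tree$right[k]
    }
  }
  tree$leaf_id[k]
}

# Naive co-occurrence tally: routes the pixel and every in-bag plot through
# each tree independently and counts shared terminal buckets.
naive_votes <- function(model, X) {
  ref <- model$reference
  votes <- matrix(0, nrow(X), nrow(ref))
  for (forest in model$forests) {
    for (tree in forest) {
      plot_leaf <- vapply(tree$inbag, function(i)
        walk_tree(tree, ref[i, , drop = FALSE]), 0L)
      for (p in seq_len(nrow(X))) {
        lf <- walk_tree(tree, X[p, , drop = FALSE])
        hits <- tree$inbag[plot_leaf == lf]
        votes[p, hits] <- votes[p, hits] + 1
      }
    }
  }
  votes
}

# Small disturbance layer helper.
mk_layer <- function(year, codes, nr = 2, nc = 2, cellsize = 30) {
  list(year = year, band = rband(matrix(codes, nr, nc), 0, 0, cellsize))
}
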