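test_that("default configuration grows 249 trees across three responses", {
  ref <- mk_reference(40)
  model <- fit_imputation(ref, impute_config(), seed = 2)
  expect_equal(sum(lengths(model$forests)), 249)
  expect_named(model$forests, c("cover_bin", "height_bin", "evg"))
  expect_true(all(model$oob >= 0 & model$oob <= 1))
})

test_that("in-bag plots at the leaves sum to the bootstrap sample size", {
  ref <- mk_reference(60)
  cfg <- impute_config(trees_per_response = 10)
  model <- fit_imputation(ref, cfg, seed = 5)
  nbag <- floor(cfg$bootstrap_fraction * nrow(ref))
  for (forest in model$forests)
    for (tree in forest) {
      expect_equal(sum(lengths(tree$leaf_rows)), nbag)
      expect_equal(sort(unlist(tree$leaf_rows)), tree$inbag)
    }
})

test_that("a single reference plot yields one-leaf trees and a warned zero OOB", {
  ref <- mk_reference(1)
  expect_warning(model <- fit_imputation(ref, impute_config(trees_per_response = 3),
                                         seed = 1), "single reference plot")
  expect_true(all(model$oob == 0))
  for (forest in model$forests)
    for (tree in forest) expect_equal(tree$leaf_id, 1L)
  gen <- matrix(1L, 4, 4)
  stack <- mk_stack_from_ref(ref, gen)
  imap <- impute_map(model, stack, seed = 1)
  expect_true(all(imap$plot_id$values == ref$plot_id))
})

test_that("widely separated pure clusters give zero OOB error", {
  ref <- mk_reference(24)
  cl <- rep(c(0, 1), each = 12)
  ref$elevation <- 1000 + 5000 * cl + runif(24)
  ref$cover_bin <- ifelse(cl == 0, 35, 85)
  ref$height_bin <- ifelse(cl == 0, 8, 38)
  ref$evg <- ifelse(cl == 0, 601L, 602L)
  cfg <- impute_config(trees_per_response = 25,
                       predictors = "elevation")
  model <- fit_imputation(ref, cfg, seed = 3)
  expect_equal(unname(model$oob), c(0, 0, 0))
})

test_that("shuffled labels over k equiprobable classes give OOB near (k-1)/k", {
  set.seed(77)
  k <- 4
  ref <- mk_reference(300)
  ref$cover_bin <- sample(seq(15, 45, 10), 300, replace = TRUE)   # pure noise
  cfg <- impute_config(trees_per_response = 30, responses = "cover_bin",
                       responses_as_split_candidates = FALSE)
  model <- fit_imputation(ref, cfg, seed = 8)
  expect_equal(unname(model$oob), (k - 1) / k, tolerance = 0.1)
})

test_that("engine co-occurrence tally equals the naive leaf-intersection oracle", {
  # exhaustive check on small instances: <= 50 plots, <= 5 trees per forest
  for (case in list(list(n = 12, tpr = 2, seed = 21),
                    list(n = 50, tpr = 5, seed = 22),
                    list(n = 30, tpr = 3, seed = 23))) {
    ref <- mk_reference(case$n, seed = case$seed)
    cfg <- impute_config(trees_per_response = case$tpr)
    model <- fit_imputation(ref, cfg, seed = case$seed)
    # probe pixels: some equal to reference rows, some perturbed
    X <- ref[sample(case$n, 8), names(ref) != "plot_id"]
    X$elevation <- X$elevation + rnorm(8, 0, 30)
    engine <- co_occurrence_votes(model, X)
    oracle <- naive_votes(model, X)
    expect_equal(engine, oracle)
  }
})

test_that("a pixel matching a well-separated plot is assigned that plot", {
  # 10-plot set; plot 7 sits far from the others in elevation and carries its
  # own vegetation group, so its co-occurrence tally dominates
  ref <- mk_reference(10, seed = 31)
  ref$elevation <- c(seq(500, 1400, length.out = 9), 10000)[c(1:6, 10, 7:9)]
  ref$evg <- c(rep(601L, 6), 699L, rep(601L, 3))
  gen <- matrix(7L, 3, 3)                            # all pixels = plot 7's vector
  stack <- mk_stack_from_ref(ref, gen)
  cfg <- impute_config(trees_per_response = 60, responses = "evg",
                       predictors = "elevation", min_bucket = 2)
  model <- fit_imputation(ref, cfg, seed = 4)
  imap <- impute_map(model, stack, seed = 4)
  expect_true(all(imap$plot_id$values == ref$plot_id[7]))
  # and the tally itself agrees tree-by-tree with the brute-force oracle
  X <- ref[7, names(ref) != "plot_id"]
  expect_equal(co_occurrence_votes(model, X), naive_votes(model, X))
})

test_that("exact vote ties are split uniformly at random across pixels", {
  # two plots with identical vectors and labels; a forest of two one-leaf-pair
  # trees makes every pixel's vote an exact tie
  ref <- mk_reference(2, seed = 41)
  ref[2, setdiff(names(ref), "plot_id")] <- ref[1, setdiff(names(ref), "plot_id")]
  cfg <- impute_config(trees_per_response = 2, responses = "cover_bin",
                       predictors = "lon")
  model <- fit_imputation(ref, cfg, seed = 6)
  gen <- matrix(1L, 25, 40)                          # 1000 identical pixels
  stack <- mk_stack_from_ref(ref, gen)
  X <- plotimpute:::pixel_table(stack)
  v <- co_occurrence_votes(model, X)
  expect_equal(v[, 1], v[, 2])   # exact tie at every pixel by construction
  imap <- impute_map(model, stack, seed = 9)
  n1 <- sum(imap$plot_id$values == ref$plot_id[1])
  # binomial 99% interval around 500/1000
  expect_gt(n1, 459)
  expect_lt(n1, 541)
})

test_that("identical inputs and seed give a bit-identical imputed map", {
  ref <- mk_reference(30, seed = 51)
  gen <- matrix(sample(30, 64, replace = TRUE), 8, 8)
  stack <- mk_stack_from_ref(ref, gen)
  cfg <- impute_config(trees_per_response = 8)
  a <- impute_map(fit_imputation(ref, cfg, seed = 12), stack, seed = 12)
  b <- impute_map(fit_imputation(ref, cfg, seed = 12), stack, seed = 12)
  expect_identical(a$plot_id$values, b$plot_id$values)
  expect_identical(a$vote_margin$values, b$vote_margin$values)
  c <- impute_map(fit_imputation(ref, cfg, seed = 13), stack, seed = 13)
  expect_false(identical(a$plot_id$values, c$plot_id$values))
})

test_that("an unseen categorical level routes to the larger child", {
  ref <- mk_reference(40, seed = 61)
  model <- fit_imputation(ref, impute_config(trees_per_response = 5), seed = 7)
  X <- ref[1:3, names(ref) != "plot_id"]
  X$evg <- 699L        # never seen in training
  v <- co_occurrence_votes(model, X)
  o <- naive_votes(model, X)      # oracle implements the same policy
  expect_equal(v, o)
  expect_true(all(rowSums(v) > 0))
})

test_that("single-zone zonal run reproduces the direct fit and imputation", {
  ref <- mk_reference(30, seed = 71)
  gen <- matrix(sample(30, 100, replace = TRUE), 10, 10)
  stack <- mk_stack_from_ref(ref, gen)
  zone <- stack$forest_mask
  cfg <- impute_config(trees_per_response = 6)
  zonal <- run_zonal(ref, stack, zone, cfg, seed = 3)
  zseed <- rng_substream_seed(3, "zone:1")
  direct <- impute_map(fit_imputation(ref, cfg, seed = zseed), stack, seed = zseed)
  expect_identical(zonal$plot_id$values, direct$plot_id$values)
})

test_that("zones never receive plots of vegetation groups they lack", {
  ref <- mk_reference(40, seed = 81, n_evg = 4)
  # zone 1 holds groups 601/602, zone 2 holds 603/604
  gen <- matrix(0L, 10, 10)
  left_plots <- which(ref$evg %in% c(601L, 602L))
  right_plots <- which(ref$evg %in% c(603L, 604L))
  gen[, 1:5] <- sample(left_plots, 50, replace = TRUE)
  gen[, 6:10] <- sample(right_plots, 50, replace = TRUE)
  stack <- mk_stack_from_ref(ref, gen)
  zone <- stack$forest_mask
  zone$values <- matrix(rep(c(1, 2), each = 50), 10, 10)
  out <- run_zonal(ref, stack, zone, impute_config(trees_per_response = 5),
                   seed = 2)
  imputed_evg <- matrix(ref$evg[match(out$plot_id$values, ref$plot_id)], 10, 10)
  expect_true(all(imputed_evg[, 1:5] %in% c(601L, 602L)))
  expect_true(all(imputed_evg[, 6:10] %in% c(603L, 604L)))
  expect_equal(nrow(out$oob), 6)   # 2 zones x 3 responses
})

test_that("a zone exceeding the class budget is refused with guidance", {
  ref <- mk_reference(80, seed = 91, n_evg = 33)
  # make sure all 33 groups appear among plots and pixels
  ref$evg <- 600L + (seq_len(80) %% 33L) + 1L
  gen <- matrix(rep_len(seq_len(80), 64), 8, 8)
  stack <- mk_stack_from_ref(ref, gen)
  zone <- stack$forest_mask
  expect_error(run_zonal(ref, stack, zone, impute_config(), seed = 1),
               "max_classes_per_run")
  expect_error(run_zonal(ref, stack, zone,
                         impute_config(max_classes_per_run = 40), seed = 1),
               NA)
})

test_that("imputing a vegetation group with no reference plot is an error", {
  ref <- mk_reference(20, seed = 95, n_evg = 2)
  gen <- matrix(sample(20, 36, replace = TRUE), 6, 6)
  stack <- mk_stack_from_ref(ref, gen)
  stack$evg$values[1, 1] <- 777
  model <- fit_imputation(ref, impute_config(trees_per_response = 3), seed = 1)
  expect_error(impute_map(model, stack, seed = 1), "777")
})

test_that("imputed plots recover the generating plots under small noise", {
  cfg <- synth_config(nrow = 80, ncol = 80, n_plots = 150, n_val_plots = 10,
                      n_evg = 6)
  L <- generate_landscape(cfg, seed = 17)
  tabs <- generate_plots(cfg, L, seed = 17)
  stack <- prep_target_stack(L$raw, L$annual_disturbance)
  ref <- build_reference_table(tabs$plots, tabs$trees, stack)
  model <- fit_imputation(ref, impute_config(), seed = 17)
  imap <- impute_map(model, stack, seed = 17)
  gen <- L$truth$plot_index$values
  ok <- !is.na(imap$plot_id$values) & !is.na(gen)
  tp <- L$truth$plots
  ii <- match(imap$plot_id$values[ok], tp$CN)
  for (v in c("cover_bin", "height_bin", "evg"))
    expect_gte(mean(tp[[v]][ii] == tp[[v]][gen[ok]]), 0.90)
})
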