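mk_class_band <- function(m) rband(m, 0, 0, 30)

test_that("confusion matrix counts agree with a per-pixel loop oracle", {
  set.seed(14)
  labs <- c(15, 25, 35)
  a <- mk_class_band(matrix(sample(labs, 100, TRUE), 10, 10))
  b <- mk_class_band(matrix(sample(labs, 100, TRUE), 10, 10))
  cm <- confusion(a, b)
  oracle <- matrix(0L, 3, 3, dimnames = list(as.character(labs), as.character(labs)))
  for (i in 1:10) for (j in 1:10) {
    r <- as.character(a$values[i, j]); c <- as.character(b$values[i, j])
    oracle[r, c] <- oracle[r, c] + 1L
  }
  expect_equal(unclass(cm), oracle, ignore_attr = TRUE)
  expect_equal(sum(cm), 100)
  # identical rasters give a purely diagonal matrix
  cmd <- confusion(a, a)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # one differing pixel lands off-diagonal
  one <- mk_class_band(matrix(15, 1, 1))
  two <- mk_class_band(matrix(25, 1, 1))
  cm1 <- confusion(one, two)
  expect_equal(cm1["15", "25"], 1L)
  expect_equal(sum(cm1), 1)
  # a code outside the vocabulary is a named error
  expect_error(confusion(a, b, labels = c(15, 25)), "35")
})

test_that("accuracy metrics satisfy their algebraic identities", {
  expect_identity <- function(cm) {
    m <- accuracy_metrics(cm)
    rs <- rowSums(cm); cs <- colSums(cm)
    users <- ifelse(is.na(m$users), 0, m$users)
    prods <- ifelse(is.na(m$producers), 0, m$producers)
    expect_equal(m$overall, sum(users * rs) / sum(cm))
    expect_equal(m$overall, sum(prods * cs) / sum(cm))
    # transposition swaps user's and producer's accuracy
    mt <- accuracy_metrics(t(unclass(cm)))
    expect_equal(mt$users, m$producers)
    expect_equal(mt$producers, m$users)
  }
  expect_identity(as_confusion(diag(5) * 7, as.character(1:5)))
  set.seed(2)
  for (r in 1:10) {
    k <- sample(2:8, 1)
    expect_identity(as_confusion(matrix(rpois(k * k, 20), k, k),
                                 as.character(seq_len(k))))
  }
  ident <- accuracy_metrics(as_confusion(diag(4) * 3, as.character(1:4)))
  expect_equal(ident$overall, 1)
  expect_true(all(ident$users == 1) && all(ident$producers == 1))
})

test_that("summary rates round half-up to one decimal", {
  expect_equal(summary_rate(1257, 2858), 44.0)
  expect_equal(summary_rate(1, 16), 6.3)       # 6.25 rounds up
  expect_equal(summary_rate(0, 10), 0)
})

test_that("footprint pixel sets follow exact centroid-in-radius geometry", {
  b <- mk_class_band(matrix(0, 5, 5))
  # plot on the centre pixel's centroid: centre + 4 rook neighbours at 30 m;
  # diagonals at 42.4 m are excluded at radius 40.25 m
  fp <- footprint_pixels(b, 75, 75, 40.25)
  expect_equal(nrow(fp), 5)
  expect_setequal(paste(fp$row, fp$col),
                  c("3 3", "2 3", "4 3", "3 2", "3 4"))
  # exhaustive distance enumeration oracle on the whole grid
  fp2 <- footprint_pixels(b, 100, 40, 65)
  oracle <- expand.grid(row = 1:5, col = 1:5)
  cx <- (oracle$col - 0.5) * 30; cy <- (5 - oracle$row + 0.5) * 30
  oracle <- oracle[(cx - 100)^2 + (cy - 40)^2 <= 65^2, ]
  expect_setequal(paste(fp2$row, fp2$col), paste(oracle$row, oracle$col))
  # radius zero: only the containing pixel
  fp0 <- footprint_pixels(b, 75, 75, 0)
  expect_equal(nrow(fp0), 1)
  # a plot near the corner is clipped to the extent
  fpc <- footprint_pixels(b, 5, 145, 40.25)
  expect_true(all(fpc$row >= 1 & fpc$col >= 1))
  expect_lt(nrow(fpc), 5)
  # outside the extent entirely: empty set
  expect_equal(nrow(footprint_pixels(b, 1e5, 1e5, 40.25)), 0)
})

test_that("footprint sets are invariant under joint translation", {
  b <- mk_class_band(matrix(0, 6, 6))
  shift <- c(1230, -870)
  b2 <- rband(b$values, b$xll + shift[1], b$yll + shift[2], b$cellsize)
  for (pt in list(c(70, 70), c(95, 121), c(10, 170))) {
    a <- footprint_pixels(b, pt[1], pt[2])
    z <- footprint_pixels(b2, pt[1] + shift[1], pt[2] + shift[2])
    expect_equal(a, z)
  }
})

test_that("footprint agreement flags match a hand-computed table", {
  # 4x4 map, two reference plots imputed in blocks
  ref <- data.frame(plot_id = c(1L, 2L),
                    cover_bin = c(55, 25), height_bin = c(18, 8),
                    cover_pct = c(55, 25), height_m = c(18, 8),
                    sp1 = c(101L, 202L), sp2 = c(310L, NA))
  idmat <- cbind(matrix(1, 4, 2), matrix(2, 4, 2))     # cols 1-2 plot 1
  imap <- structure(list(plot_id = mk_class_band(idmat), reference = ref),
                    class = "imputed_map")
  val <- data.frame(
    # plot A at centre of pixel (2,2): plus shape = 4x plot 1 + 1x plot 2
    # cover_any: bin 55 present -> TRUE
    # weighted cover = (4*55 + 25)/5 = 49; |49 - 52| <= 10 -> TRUE
    # weighted height = (4*18 + 8)/5 = 16; |16 - 16| <= 5 -> TRUE
    x = 45, y = 75, cover_pct = 52, height_m = 16, cover_bin = 55,
    height_bin = 18, sp1 = 101L, sp2 = 999L)
  val <- rbind(val, data.frame(
    # plot B at centre of pixel (2,3): plus shape spans both blocks:
    # pixels (2,3),(1,3),(3,3),(2,4) plot 2 and (2,2) plot 1
    # weighted cover = (55 + 4*25)/5 = 31; |31 - 70| > 10 -> FALSE
    # cover_any: plot 2 bin 25 != 65, plot 1 bin 55 != 65 -> FALSE
    # height: bins {18, 8}, plot bin 8 -> any TRUE; weighted = (18+4*8)/5 = 10
    #   |10 - 8.2| <= 5 -> TRUE; species 202 matches sp1 -> TRUE
    x = 75, y = 75, cover_pct = 70, height_m = 8.2, cover_bin = 65,
    height_bin = 8, sp1 = 202L, sp2 = NA))
  fa <- footprint_agreement(val, imap)
  expect_equal(fa$per_plot$n_pixels, c(5L, 5L))
  expect_equal(fa$per_plot$cover_any, c(TRUE, FALSE))
  expect_equal(fa$per_plot$cover_weighted, c(TRUE, FALSE))
  expect_equal(fa$per_plot$height_any, c(TRUE, TRUE))
  expect_equal(fa$per_plot$height_weighted, c(TRUE, TRUE))
  expect_equal(fa$per_plot$species_any, c(TRUE, TRUE))
  expect_equal(fa$n_forested, 2)
  expect_equal(fa$summary$rate_percent[fa$summary$measure == "cover_any"], 50)
})

test_that("plots with no forested footprint pixel leave the denominator", {
  ref <- data.frame(plot_id = 1L, cover_bin = 55, height_bin = 18,
                    cover_pct = 55, height_m = 18, sp1 = 101L, sp2 = NA)
  idmat <- matrix(NA_real_, 4, 4); idmat[2, 2] <- 1
  imap <- structure(list(plot_id = mk_class_band(idmat), reference = ref),
                    class = "imputed_map")
  val <- data.frame(x = c(45, 105), y = c(75, 15),
                    cover_pct = 55, height_m = 18, cover_bin = 55,
                    height_bin = 18, sp1 = 101L, sp2 = NA)
  fa <- footprint_agreement(val, imap)
  expect_equal(fa$n_plots, 2)
  expect_equal(fa$n_forested, 1)
  expect_equal(fa$summary$denominator, rep(1, 5))
})

test_that("two-sample KS statistic matches an exhaustive ECDF sweep", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  ks <- ks_two_sample(a, b)
  # brute-force sweep at all six sample points
  pts <- sort(unique(c(a, b)))
  D <- max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
  expect_equal(ks$D, D)
  expect_equal(ks$D, 1 / 3)
  # identical samples: D = 0, p = 1
  same <- ks_two_sample(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  # disjoint supports: D = 1
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("KS p-values agree with the stats oracle and calibrate under the null", {
  set.seed(33)
  for (r in 1:5) {
    a <- rnorm(40); b <- rnorm(55, 0.3)
    ours <- ks_two_sample(a, b)
    theirs <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$D, unname(theirs$statistic))
    expect_equal(ours$p_value, unname(theirs$p.value), tolerance = 1e-4)
  }
  # null calibration: p-values of identically distributed samples are uniform
  # (unequal sample sizes, so D is not confined to a coarse lattice)
  set.seed(101)
  ps <- replicate(100, ks_two_sample(rnorm(150), rnorm(123))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("disturbance raises standing-dead counts detectably", {
  set.seed(55)
  n <- 200
  refdf <- data.frame(
    dist_code = rep(c(0L, 1L), each = n),
    standing_dead = c(rpois(n, 2), rpois(n, 2) + rpois(n, 5)))
  out <- dead_tree_disturbance_analysis(refdf)
  fire <- out[out$comparison == "fire_vs_undisturbed", ]
  expect_lt(fire$p_value, 0.01)
  expect_gt(fire$mean_disturbed, fire$mean_undisturbed)
  # an empty group is skipped with a notice, not an error
  expect_message(out2 <- dead_tree_disturbance_analysis(refdf),
                 "skipped")
  expect_true(is.na(out2$p_value[out2$comparison == "insect_vs_undisturbed"]))
})

test_that("confusion CSV round trip preserves labels and counts", {
  cm <- as_confusion(matrix(c(5, 1, 2, 9), 2, 2), c("fire", "none"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, f)
  cm2 <- read_confusion_csv(f)
  expect_equal(unclass(cm2), unclass(cm), ignore_attr = TRUE)
  expect_equal(rownames(cm2), c("fire", "none"))
})
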