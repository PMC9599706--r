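make_random_set <- function(n, p, seed = 1, lo = 1000, hi = 2000) {
  set.seed(seed)
  new_spectra_set(seq(hi, lo, length.out = p),
                  matrix(rnorm(n * p), n, p),
                  data.frame(spectrum_id = sprintf("r%02d", seq_len(n)),
                             condition = rep(c("a", "b"), length.out = n)))
}

test_that("PCA matches an independent eigendecomposition of the covariance matrix", {
  set <- make_random_set(10, 30, seed = 3)
  pca <- run_pca(set, q = 10)
  # centered data of 10 spectra has rank 9; compare the meaningful fractions
  ev <- eigen(stats::cov(set$absorbance), symmetric = TRUE)$values
  expect_equal((pca$singular_values^2 / sum(pca$singular_values^2))[1:9],
               (ev / sum(ev[ev > 0]))[1:9], tolerance = 1e-8)
  # loading rows orthonormal
  G <- pca$loadings %*% t(pca$loadings)
  expect_equal(G, diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  # explained fractions non-increasing, in [0,1], summing to <= 1
  f <- pca$explained_variance_fraction
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= 0 & f <= 1))
  expect_lte(sum(f), 1 + 1e-9)
  # full-rank reconstruction reproduces the centered data
  Xc <- sweep(set$absorbance, 2L, pca$center)
  expect_equal(pca$scores %*% pca$loadings, Xc, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("two distinct spectra give a rank-one decomposition", {
  set <- make_random_set(2, 20, seed = 5)
  pca <- run_pca(set, q = 2)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("duplicating every spectrum leaves loadings and variance fractions unchanged", {
  set <- make_random_set(6, 25, seed = 7)
  dup <- new_spectra_set(set$wavenumber,
                         rbind(set$absorbance, set$absorbance),
                         data.frame(spectrum_id = sprintf("d%02d", 1:12),
                                    condition = rep(set$metadata$condition, 2)))
  p1 <- run_pca(set, q = 3)
  p2 <- run_pca(dup, q = 3)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p1$explained_variance_fraction, p2$explained_variance_fraction,
               tolerance = 1e-10)
})

test_that("PC signs follow the largest-loading-positive convention", {
  set <- make_random_set(8, 40, seed = 11)
  pca <- run_pca(set, q = 4)
  for (i in 1:4) expect_gt(pca$loadings[i, which.max(abs(pca$loadings[i, ]))], 0)
})

test_that("per-wavenumber R2 is complete, bounded, and 1 for rank-one data", {
  # rank-one structure: every row a multiple of one profile
  w <- seq(2000, 1000, length.out = 40)
  profile <- sin(seq_len(40) / 4)
  coefs <- c(1, 2.5, -1, 0.5, 3)
  X <- outer(coefs, profile)
  set <- new_spectra_set(w, X, data.frame(spectrum_id = paste0("s", 1:5),
                                          condition = "x"))
  pca <- run_pca(set, q = 4)
  r2 <- per_wavenumber_r2(pca, set, k = 1)
  nz <- profile != 0
  expect_equal(unname(r2[1, nz]), rep(1, sum(nz)), tolerance = 1e-9)
  # completeness on full-rank random data
  set2 <- make_random_set(8, 12, seed = 13)
  pca2 <- run_pca(set2, q = 8)
  r2f <- per_wavenumber_r2(pca2, set2, k = 8)
  expect_equal(unname(attr(r2f, "cumulative")), rep(1, 12), tolerance = 1e-9)
  expect_true(all(r2f >= -1e-12 & r2f <= 1 + 1e-12))
  expect_error(per_wavenumber_r2(pca2, set2, k = 9), "k must be")
})

test_that("Ward clustering matches the brute-force variance-increase oracle", {
  set.seed(17)
  X <- matrix(rnorm(18), 6, 3)
  set <- new_spectra_set(seq(1300, 1000, length.out = 3), X,
                         data.frame(spectrum_id = paste0("s", 1:6), condition = "x"))
  pca <- run_pca(set, q = 3)
  dend <- hca_ward(pca)
  expect_equal(dend$height, brute_force_ward_heights(pca$scores), tolerance = 1e-9)
  # linkage heights non-decreasing (Ward monotonicity)
  expect_true(all(diff(dend$height) >= -1e-12))
  tab <- dendrogram_table(dend)
  expect_equal(nrow(tab), 5L)
})

test_that("identical score rows merge at height zero", {
  X <- rbind(c(1, 2, 3, 1), c(1, 2, 3, 1), c(4, 0, 1, 2))
  set <- new_spectra_set(seq(1400, 1000, length.out = 4), X,
                         data.frame(spectrum_id = c("a", "b", "c"), condition = "x"))
  dend <- hca_ward(run_pca(set, q = 2))
  expect_lt(dend$height[1], 1e-9)
})

test_that("default synthetic cohorts separate into pure condition clusters", {
  set <- area_normalize_set(generate_study(n = c(untreated = 15, steatotic = 15, ex4 = 15),
                                           seed = 19))
  win <- extract_region_set(set, 2750, 3100)
  for (i in seq_len(nrow(win$absorbance))) {
    win$absorbance[i, ] <- baseline_rubberband(get_spectrum(win, i))$absorbance
  }
  pca <- run_pca(win, q = 3)
  cl <- cutree(hca_ward(pca), k = 3)
  purity <- sum(apply(table(cl, win$metadata$condition), 1, max)) / length(cl)
  expect_equal(purity, 1)
  # score-space separation: centroids far apart relative to within-group spread
  reps <- class_representatives(pca)
  within_sd <- mean(vapply(split(as.data.frame(pca$scores), win$metadata$condition),
                           function(d) mean(apply(d, 2, sd)), numeric(1)))
  expect_gt(min(dist(reps)), 3 * within_sd)
  # top components dominate and fractions are ordered
  f <- pca$explained_variance_fraction
  expect_gt(f[1], 0.5)
  expect_true(all(diff(f) <= 0))
})

test_that("class representatives are score centroids with the centering identity", {
  set <- make_random_set(9, 15, seed = 23)
  set$metadata$condition <- rep(c("a", "b", "c"), each = 3)
  pca <- run_pca(set, q = 3)
  reps <- class_representatives(pca)
  expect_equal(reps["a", ], colMeans(pca$scores[1:3, ]), ignore_attr = TRUE)
  # size-weighted grand mean of centroids is the origin (scores are centered)
  sizes <- table(set$metadata$condition)[rownames(reps)]
  grand <- colSums(reps * as.numeric(sizes)) / sum(sizes)
  expect_equal(unname(grand), rep(0, 3), tolerance = 1e-9)
  # single-member condition: centroid equals that row
  set$metadata$condition <- c("solo", rep("rest", 8))
  pca2 <- run_pca(set, q = 2)
  expect_equal(class_representatives(pca2)["solo", ], pca2$scores[1, ], ignore_attr = TRUE)
  # unlabeled spectra excluded with a warning
  set$metadata$condition[2] <- NA
  pca3 <- run_pca(set, q = 2)
  expect_warning(class_representatives(pca3), "unlabeled")
})

test_that("biplot associations follow angular proximity with a none fallback", {
  set <- make_random_set(8, 20, seed = 29)
  set$metadata$condition <- rep(c("a", "b"), each = 4)
  pca <- run_pca(set, q = 2)
  bt <- biplot_table(pca)
  expect_equal(nrow(bt), 20L)
  expect_true(all(bt$association %in% c("a", "b", "none")))
  # a loading exactly collinear with one centroid associates with it
  reps <- class_representatives(pca)[, 1:2]
  pca_mod <- pca
  pca_mod$loadings[1:2, 1] <- reps["a", ] * 2
  bt2 <- biplot_table(pca_mod)
  expect_equal(bt2$association[1], "a")
  # near-zero loading -> none
  pca_mod$loadings[1:2, 2] <- c(1e-9, 1e-9)
  expect_equal(biplot_table(pca_mod)$association[2], "none")
  # ester region associates with the steatotic condition on default cohorts
  study <- area_normalize_set(generate_study(n = c(untreated = 10, steatotic = 10, ex4 = 10),
                                             seed = 31))
  win <- extract_region_set(study, 1600, 1780)
  for (i in seq_len(nrow(win$absorbance))) {
    win$absorbance[i, ] <- baseline_rubberband(get_spectrum(win, i))$absorbance
  }
  bt3 <- biplot_table(run_pca(win, q = 3))
  ester <- bt3[bt3$wavenumber >= 1730 & bt3$wavenumber <= 1750, ]
  expect_gt(mean(ester$association == "steatotic"), 0.9)
})

test_that("condition-level dendrogram has one leaf per condition", {
  set <- area_normalize_set(generate_study(n = c(untreated = 5, steatotic = 5, ex4 = 5),
                                           seed = 37))
  win <- extract_region_set(set, 2750, 3100)
  pca <- run_pca(win, q = 3)
  rd <- representatives_dendrogram(pca)
  expect_setequal(rd$labels, c("untreated", "steatotic", "ex4"))
  expect_equal(length(rd$height), 2L)
  nwk <- attr(rd, "newick")
  if (!is.na(nwk)) expect_match(nwk, "steatotic")
})
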