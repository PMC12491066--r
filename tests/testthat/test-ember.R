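test_that("the scan grid enumerates the acquisition protocol", {
  g <- build_scan_grid()
  expect_identical(nrow(g), 128L)
  expect_identical(sum(g$mode == "lambda_lambda"), 110L)
  expect_identical(sum(g$mode == "mono"), 18L)
  # detection starts 10 nm above the excitation line, 20 nm windows to 780
  ll <- g[g$mode == "lambda_lambda", ]
  expect_true(all(ll$em_start_nm >= ll$ex_nm + 10))
  expect_true(all(ll$em_end_nm - ll$em_start_nm == 20))
  expect_equal(max(g$em_end_nm), 780)
  # closed form: windows per excitation = (780 - (ex + 10)) / 20
  per_ex <- table(ll$ex_nm)
  exs <- as.numeric(names(per_ex))
  expect_equal(as.vector(per_ex), (780 - (exs + 10)) / 20)

  single <- build_scan_grid(lambda_spec = list(ex_from = 670, ex_to = 670,
                                               ex_step = 20, em_offset = 10,
                                               em_window = 20, em_stop = 780),
                            mono_spec = NULL)
  expect_identical(nrow(single), 5L)
  expect_equal(single$em_start_nm, seq(680, 760, by = 20))

  # 480-780 nm span (300 nm) leaves a 20 nm remainder for 40 nm windows
  expect_error(build_scan_grid(lambda_spec = list(ex_from = 470, ex_to = 470,
                                                  ex_step = 20, em_offset = 10,
                                                  em_window = 40, em_stop = 780),
                               mono_spec = NULL),
               "remainder")
})

test_that("segmentation finds planted blobs and ignores blanks", {
  grid <- build_scan_grid()
  blank <- ember_stack(grid, array(0, dim = c(32, 32, nrow(grid))))
  expect_identical(segment_particles(blank), list())

  # one bright disk (radius 5) on a zero background, flat across channels
  img <- matrix(0, 64, 64)
  ctr <- c(32, 32)
  for (r in 1:64) for (cc in 1:64) {
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= 25) img[r, cc] <- 100
  }
  stack1 <- ember_stack(grid, array(rep(img, nrow(grid)),
                                    dim = c(64, 64, nrow(grid))))
  masks <- segment_particles(stack1)
  expect_length(masks, 1L)
  disk_area <- sum(img > 0)
  expect_gte(masks[[1]]$area, 0.9 * disk_area)
  expect_equal(masks[[1]]$centroid, ctr, tolerance = 0.5)

  # two disks far apart: two masks, centroids within 1 px
  img2 <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    if ((r - 16)^2 + (cc - 16)^2 <= 9) img2[r, cc] <- 100
    if ((r - 48)^2 + (cc - 48)^2 <= 9) img2[r, cc] <- 80
  }
  stack2 <- ember_stack(grid, array(rep(img2, nrow(grid)),
                                    dim = c(64, 64, nrow(grid))))
  masks2 <- segment_particles(stack2, min_area = 5L)
  expect_length(masks2, 2L)
  cents <- t(vapply(masks2, function(m) m$centroid, numeric(2)))
  cents <- cents[order(cents[, 1]), ]
  expect_true(all(abs(cents - rbind(c(16, 16), c(48, 48))) <= 1))

  # min_area drops sub-threshold specks
  expect_length(segment_particles(stack2, min_area = 1000L), 0L)
})

test_that("profiles are per-mask channel means", {
  grid <- build_scan_grid()
  n_ch <- nrow(grid)
  imgs <- array(7, dim = c(16, 16, n_ch))
  stack <- ember_stack(grid, imgs)
  mask <- list(pixels = cbind(3:6, 3:6), area = 4L, centroid = c(4.5, 4.5))
  profs <- extract_profiles(stack, list(mask))
  expect_equal(dim(profs), c(1L, n_ch))
  expect_true(all(profs == 7))

  # one-pixel mask returns that pixel's values
  imgs2 <- array(seq_len(16 * 16 * n_ch), dim = c(16, 16, n_ch))
  stack2 <- ember_stack(grid, imgs2)
  px <- list(pixels = cbind(5L, 9L), area = 1L, centroid = c(5, 9))
  expect_equal(as.vector(extract_profiles(stack2, list(px))),
               imgs2[5, 9, ])

  # checkerboard of 0/10 averages to 5 in every channel
  cb <- outer(1:16, 1:16, function(r, cc) 10 * ((r + cc) %% 2))
  stack3 <- ember_stack(grid, array(rep(cb, n_ch), dim = c(16, 16, n_ch)))
  region <- as.matrix(expand.grid(1:4, 1:4))
  profs3 <- extract_profiles(stack3, list(list(pixels = region, area = 16L,
                                               centroid = c(2.5, 2.5))))
  expect_true(all(profs3 == 5))

  empty <- list(pixels = matrix(integer(0), 0, 2), area = 0L, centroid = c(NA, NA))
  expect_error(extract_profiles(stack, list(empty)), "empty particle mask")
})

test_that("profile normalization sums to one and is scale invariant", {
  p <- rbind(c(2, 2, 4))
  expect_equal(normalize_profiles(p), rbind(c(0.25, 0.25, 0.5)))
  n1 <- normalize_profiles(p)
  expect_equal(normalize_profiles(n1), n1, tolerance = 1e-12)   # idempotent
  expect_equal(normalize_profiles(1000 * p), n1)                # scale invariant
  set.seed(2)
  many <- matrix(runif(50 * 8, 0.1, 5), 50)
  expect_equal(rowSums(normalize_profiles(many)), rep(1, 50), tolerance = 1e-9)
  expect_error(normalize_profiles(rbind(c(0, 0, 0))), "non-positive total")
})

test_that("PCA embedding matches an independent eigendecomposition", {
  pts <- rbind(c(1, 0, 2, 1), c(2, 1, 0, 3), c(0, 2, 1, 2))
  emb <- pca_embed(pts, n_components = 2L)
  # oracle: eigendecomposition of the 4x4 covariance matrix
  ev <- eigen(cov(pts), symmetric = TRUE)
  centred <- sweep(pts, 2, colMeans(pts))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v    # same sign convention
    expect_equal(emb$coordinates[, j], as.vector(centred %*% v),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(emb$explained_variance[j],
                 ev$values[j] / sum(pmax(ev$values, 0)), tolerance = 1e-9)
  }
  expect_false(is.unsorted(rev(emb$explained_variance)))

  same <- matrix(1, 5, 3)
  emb0 <- pca_embed(same)
  expect_true(all(abs(emb0$coordinates) < 1e-12))

  line <- outer(seq(0, 1, length.out = 6), c(1, 2, 3))
  embl <- pca_embed(line)
  expect_equal(embl$explained_variance[1L], 1, tolerance = 1e-9)

  expect_error(pca_embed(pts[1:2, ], n_components = 2L), "at least 3 profiles")
})

test_that("QDA accuracy matches a hand-rolled Gaussian discriminant", {
  set.seed(7)
  x <- rbind(matrix(rnorm(400, 0), ncol = 2),
             matrix(rnorm(400, 10), ncol = 2))     # 10 s.d. apart
  g <- rep(c("WT", "P301S"), each = 200)
  acc <- qda_discrimination(x, g)
  expect_gte(as.numeric(acc), 0.99)
  expect_equal(as.numeric(acc), oracle_qda_accuracy(x, factor(g)))

  # shuffled labels on one cloud: resubstitution near chance
  set.seed(8)
  x0 <- matrix(rnorm(800), ncol = 2)
  g0 <- sample(rep(c("WT", "P301S"), each = 200))
  acc0 <- as.numeric(qda_discrimination(x0, g0))
  expect_gte(acc0, 0.45)
  expect_lte(acc0, 0.62)
  expect_equal(acc0, oracle_qda_accuracy(x0, factor(g0)))

  tiny <- rbind(matrix(rnorm(6), ncol = 2), matrix(rnorm(6, 5), ncol = 2))
  expect_error(qda_discrimination(tiny, rep(c("a", "b"), each = 3)),
               "needs >= 4 particles")
})

test_that("per-inducer accuracies average into the overall score", {
  expect_equal(discrimination_score(c(`1` = 1.0, `2` = 0.5))$overall, 0.75)
  expect_equal(discrimination_score(c(`4` = 0.88))$overall, 0.88)
  expect_equal(discrimination_score(rep(0.66, 13))$overall, 0.66)
  expect_error(discrimination_score(numeric(0)), "empty")
  expect_error(discrimination_score(c(a = 1.2)), "0, 1")
})

test_that("the pipeline is invariant to global intensity scaling", {
  sim <- gen_ember(n_particles_per_class = 15L, image_size = 60L,
                   shift_nm = 40, noise_sd = 30, seed = 21L)
  res1 <- ember_pipeline(sim$stacks[[1L]], sim$stacks[[2L]], sensitivity = 0.5)
  scaled <- lapply(sim$stacks, function(s) {
    s$images <- s$images * 3.7
    s
  })
  res2 <- ember_pipeline(scaled[[1L]], scaled[[2L]], sensitivity = 0.5)
  expect_identical(res1$n_particles, res2$n_particles)
  expect_equal(res1$accuracy, res2$accuracy)
  expect_equal(abs(res1$embedding$coordinates), abs(res2$embedding$coordinates),
               tolerance = 1e-8)
})
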