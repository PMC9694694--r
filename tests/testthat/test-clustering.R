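test_that("partial distance rescales by observed-coordinate count", {
  v <- rep(100, 48)
  expect_equal(partial_distance(v, v), 0)

  # complete profiles reduce to plain Euclidean distance
  x <- v
  x[5] <- 103
  x[9] <- 104
  expect_equal(partial_distance(x, v), 5)
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(48)
    b <- rnorm(48)
    expect_equal(partial_distance(a, b), sqrt(sum((a - b)^2)))
  }

  # length-2 toy case with one missing coordinate: d^2 = (2/1) * 1
  expect_equal(partial_distance(c(1, NA), c(2, 5)), sqrt(2))

  expect_error(partial_distance(c(NA, NA), c(1, 2)), "observed")
})

test_that("membership update reproduces the closed-form hand cases", {
  # equidistant from 4 prototypes -> uniform weights
  V <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  w <- update_memberships(matrix(c(0, 0), 1), V, m = 2)
  expect_equal(as.numeric(w), rep(0.25, 4))

  # distances (1, 2) with m = 2 -> (0.8, 0.2)
  V2 <- rbind(c(1, 0), c(2, 0))
  w2 <- update_memberships(matrix(c(0, 0), 1), V2, m = 2)
  expect_equal(as.numeric(w2), c(0.8, 0.2))

  # coinciding with a prototype -> crisp assignment
  w3 <- update_memberships(matrix(c(1, 0), 1), V2, m = 2)
  expect_equal(as.numeric(w3), c(1, 0))

  # rows always sum to 1
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40)
  X[sample(length(X), 30)] <- NA
  W <- update_memberships(X, matrix(rnorm(3 * 6), 3), m = 1.7)
  expect_equal(rowSums(W), rep(1, 40), tolerance = 1e-9)
  expect_true(all(W >= 0 & W <= 1))
})

test_that("centroid update is the w^m-weighted mean over observing profiles", {
  # uniform weights on complete data -> arithmetic mean
  X <- rbind(c(0, 2), c(4, 6), c(8, 10))
  W <- matrix(1 / 2, 3, 2)
  V <- update_centroids(X, W, m = 1.5)
  expect_equal(V[1, ], colMeans(X))

  # single profile -> the profile itself
  expect_equal(as.numeric(update_centroids(matrix(c(3, 7), 1), matrix(1, 1, 1), 2)),
               c(3, 7))

  # points {0, 10} with w = (0.8, 0.2), m = 2: (0.64*0 + 0.04*10) / 0.68
  V2 <- update_centroids(matrix(c(0, 10), 2, 1), matrix(c(0.8, 0.2), 2, 1), 2)
  expect_equal(as.numeric(V2), 0.4 / 0.68, tolerance = 1e-12)

  # a coordinate no profile observes is an error
  Xna <- rbind(c(1, NA), c(2, NA))
  expect_error(update_centroids(Xna, matrix(0.5, 2, 2), 2), "Coordinate 2")
})

test_that("pdsfcm recovers well-separated blobs and minimises monotonically", {
  set.seed(5)
  mu1 <- rep(100, 48)
  mu2 <- rep(200, 48)
  X <- rbind(
    t(replicate(15, mu1 + rnorm(48, 0, 3))),
    t(replicate(15, mu2 + rnorm(48, 0, 3)))
  )
  fit <- pdsfcm(X, 2, m = 2, seed = 9)
  proto_means <- sort(rowMeans(fit$prototypes))
  expect_equal(proto_means, c(100, 200), tolerance = 0.05)
  expect_true(all(apply(fit$memberships, 1, max) > 0.99))
  expect_equal(rowSums(fit$memberships), rep(1, 30), tolerance = 1e-9)
  expect_true(all(diff(fit$objective_history) <= 1e-8))

  # identical profiles: prototype equals the profile, objective ~ 0
  Xc <- matrix(rep(c(1:10) * 10, 8), 8, 10, byrow = TRUE)
  fitc <- pdsfcm(Xc, 2, m = 2, seed = 2)
  expect_equal(fitc$objective, 0, tolerance = 1e-6)
  expect_equal(as.numeric(fitc$prototypes[1, ]), c(1:10) * 10, tolerance = 1e-4)

  expect_error(pdsfcm(Xc, 8, m = 2), "more profiles")

  # objective history is non-increasing on messy incomplete data too
  set.seed(8)
  Xm <- matrix(rnorm(50 * 12, 100, 20), 50)
  Xm[sample(length(Xm), 120)] <- NA
  for (sd in 1:3) {
    f <- pdsfcm(Xm, 3, m = 1.8, restarts = 1, seed = sd)
    expect_true(all(diff(f$objective_history) <= 1e-8))
  }
})

test_that("on complete data pdsfcm agrees with the reference FCM", {
  skip_if_not_installed("e1071")
  set.seed(13)
  X <- rbind(
    t(replicate(20, rep(100, 20) + rnorm(20, 0, 4))),
    t(replicate(20, rep(160, 20) + rnorm(20, 0, 4))),
    t(replicate(20, rep(240, 20) + rnorm(20, 0, 4)))
  )
  ours <- pdsfcm(X, 3, m = 2, restarts = 5, tol = 1e-9, max_iter = 500, seed = 31)
  ref <- e1071::cmeans(X, centers = 3, m = 2, iter.max = 500)
  # same objective at the optimum
  ref_obj <- sum(ref$membership^2 * csarima:::partial_dist2(X, ref$centers))
  expect_equal(ours$objective, ref_obj, tolerance = 1e-6 * ref_obj)
  # same partition up to label permutation
  expect_equal(label_accuracy(hard_assignment(ours), ref$cluster), 1)
})

test_that("Fukuyama-Sugeno behaves as a validity index", {
  set.seed(17)
  blobs <- function(centers, n, sd) {
    do.call(rbind, lapply(centers, function(mu) {
      t(replicate(n, rep(mu, 24) + rnorm(24, 0, sd)))
    }))
  }
  X <- blobs(c(80, 160, 260), 12, 3)

  f2 <- pdsfcm(X, 2, m = 2, seed = 1)
  f3 <- pdsfcm(X, 3, m = 2, seed = 1)
  expect_lt(f3$validity, f2$validity)

  # duplicating every profile doubles the index
  fs1 <- fukuyama_sugeno(X, f3$memberships, f3$prototypes, 2)
  fs2 <- fukuyama_sugeno(rbind(X, X), rbind(f3$memberships, f3$memberships),
                         f3$prototypes, 2)
  expect_equal(fs2, 2 * fs1, tolerance = 1e-10)

  # label permutation leaves index and objective unchanged
  perm <- c(3, 1, 2)
  fs_perm <- fukuyama_sugeno(X, f3$memberships[, perm],
                             f3$prototypes[perm, ], 2)
  expect_equal(fs_perm, fs1, tolerance = 1e-10)
})

test_that("grid search selects the generating cluster count deterministically", {
  set <- generate_pp_set(K = 3, n_per_cluster = 20, noise_sd = 5, seed = 101)
  grid <- cluster_search_grid(nC_range = 2:6, m_grid = c(1.6, 2.0, 2.4),
                              restarts = 3)
  sel <- select_clustering(set$X, grid, seed = 77)
  expect_equal(sel$n_clusters, 3)
  expect_gte(label_accuracy(hard_assignment(sel), set$labels), 0.95)

  sel2 <- select_clustering(set$X, grid, seed = 77)
  expect_identical(sel$prototypes, sel2$prototypes)
  expect_identical(sel$memberships, sel2$memberships)

  # a single-cell grid returns that cell's fit
  one <- select_clustering(set$X, cluster_search_grid(nC_range = 2, m_grid = 2,
                                                      restarts = 2), seed = 5)
  expect_equal(one$n_clusters, 2)
})

test_that("partial windows are scored against prototypes by prefix distance", {
  set <- generate_pp_set(K = 3, n_per_cluster = 15, noise_sd = 3, seed = 55)
  fit <- pdsfcm(set$X, 3, m = 2, seed = 3)

  # a prefix copied from a prototype gets its cluster the largest weight
  x <- rep(NA_real_, 48)
  x[1:12] <- fit$prototypes[2, 1:12]
  w <- score_membership(x, fit)
  expect_equal(which.max(w), 2)
  expect_equal(sum(w), 1, tolerance = 1e-9)

  # degenerate single-cluster set
  single <- fit
  single$n_clusters <- 1L
  single$prototypes <- fit$prototypes[1, , drop = FALSE]
  expect_equal(score_membership(x, single), 1)

  # equidistant prefix in a two-cluster set
  two <- fit
  two$n_clusters <- 2L
  two$prototypes <- rbind(rep(90, 48), rep(110, 48))
  xeq <- rep(NA_real_, 48)
  xeq[1:5] <- 100
  expect_equal(score_membership(xeq, two), c(0.5, 0.5))

  expect_error(score_membership(rep(NA_real_, 48), fit), "observed")
})
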