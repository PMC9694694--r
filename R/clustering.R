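#' Partial distance between an incomplete profile and a complete prototype
#'
#' The partial-distance strategy makes Euclidean distances comparable across
#' profiles with different numbers of missing entries: the sum of squared
#' differences over the observed coordinates is rescaled by D / I, where D is
#' the full profile length and I the number of observed coordinates, i.e.
#' d^2 = (D / I) * sum_k_obs (x_k - v_k)^2. When `x` is complete this reduces
#' exactly to the Euclidean distance.
#'
#' @param x numeric vector, `NA` = missing; at least one observed entry.
#' @param v complete numeric vector of the same length.
#' @return The (non-negative) partial distance d.
#' @examples
#' partial_distance(c(1, NA), c(2, 5)) # sqrt((2/1) * 1) = sqrt(2)
#' @export
partial_distance <- function(x, v) {
  if (length(x) != length(v)) abort("`x` and `v` must have equal length.")
  if (anyNA(v)) abort("The prototype `v` must be complete.")
  obs <- !is.na(x)
  I <- sum(obs)
  if (I == 0) abort("`x` has no observed entries.")
  sqrt((length(x) / I) * sum((x[obs] - v[obs])^2))
}

# Squared partial distances between all rows of X (N x D, NA = missing) and
# all rows of V (nC x D, complete). Returns N x nC matrix.
partial_dist2 <- function(X, V) {
  M <- !is.na(X)
  I <- rowSums(M)
  if (any(I == 0)) abort("Every profile needs at least one observed entry.")
  Xz <- X
  Xz[!M] <- 0
  A <- rowSums(Xz^2)                 # sum_obs x^2 per profile
  B <- Xz %*% t(V)                   # sum_obs x*v
  C <- (M * 1) %*% t(V^2)            # sum_obs v^2
  d2 <- (ncol(X) / I) * (A - 2 * B + C)
  pmax(d2, 0)
}

#' Fuzzy membership update (standard FCM rule with partial distances)
#'
#' Given prototypes, each profile's membership in cluster i is
#' proportional to d(x, v_i)^(-2/(m-1)), normalised so every row sums to 1.
#' If a profile coincides with one or more prototypes (zero distance), it is
#' assigned membership 1/|Z| on each zero-distance cluster and 0 elsewhere
#' (the crisp limit of the update rule).
#'
#' @param X N x D matrix of profiles (`NA` = missing).
#' @param V nC x D matrix of complete prototypes.
#' @param m fuzzifier, > 1.
#' @return N x nC membership matrix with rows summing to 1.
#' @export
update_memberships <- function(X, V, m) {
  if (m <= 1) abort("The fuzzifier `m` must be > 1.")
  d2 <- partial_dist2(X, V)
  eps <- 1e-12
  zero <- d2 < eps
  pow <- d2^(-1 / (m - 1))
  W <- pow / rowSums(pow)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    W[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  W
}

#' Prototype update (weighted mean over observing profiles)
#'
#' Each prototype coordinate is the w^m-weighted mean of that coordinate over
#' the profiles that observe it (the partial-data analogue of the FCM
#' centroid). Prototypes are therefore always complete, provided every
#' coordinate is observed by at least one profile.
#'
#' @param X N x D matrix of profiles (`NA` = missing).
#' @param W N x nC membership matrix.
#' @param m fuzzifier.
#' @return nC x D matrix of complete prototypes.
#' @export
update_centroids <- function(X, W, m) {
  M <- !is.na(X)
  Xz <- X
  Xz[!M] <- 0
  Wm <- W^m
  num <- t(Wm) %*% Xz          # nC x D
  den <- t(Wm) %*% (M * 1)
  if (any(den <= 0)) {
    bad <- which(apply(den, 2, function(col) any(col <= 0)))[1]
    abort(sprintf("Coordinate %d is observed by no profile with positive membership.", bad))
  }
  num / den
}

#' Partial-distance-strategy fuzzy C-means
#'
#' Fits fuzzy C-means to incomplete profiles by alternating the prototype
#' and membership updates, with the partial-distance rescaling making
#' distances comparable across profiles with different missingness. Each
#' restart draws an initial membership matrix from a row-wise symmetric
#' Dirichlet(1) with a seeded generator; the best of `restarts` runs by
#' final objective is returned. Iteration stops when the largest absolute
#' membership change falls below `tol` or after `max_iter` sweeps.
#'
#' @param X N x D numeric matrix of profiles (`NA` = missing), or a `pp_set`
#'   whose windows will be stacked.
#' @param n_clusters number of clusters, < N.
#' @param m fuzzifier, > 1 (default 2).
#' @param restarts independent seeded initialisations (default 5).
#' @param tol convergence tolerance on memberships (default 1e-5).
#' @param max_iter iteration cap per restart (default 200).
#' @param seed integer seed making the fit fully reproducible.
#' @return An object of class `pdsfcm`: a list with `n_clusters`, `fuzzifier`,
#'   `prototypes` (nC x D), `memberships` (N x nC), `objective`,
#'   `objective_history`, `validity` (Fukuyama-Sugeno index), `n_iter`,
#'   `seed`.
#' @export
pdsfcm <- function(X, n_clusters, m = 2, restarts = 5, tol = 1e-5,
                   max_iter = 200, seed = 1L) {
  if (inherits(X, "pp_set")) X <- pp_matrix(X)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N <= n_clusters) {
    abort(sprintf("Need more profiles (%d) than clusters (%d).", N, n_clusters))
  }
  if (m <= 1) abort("The fuzzifier `m` must be > 1.")
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seeds[r], pdsfcm_once(X, n_clusters, m, tol, max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$seed <- as.integer(seed)
  best$validity <- fukuyama_sugeno(X, best$memberships, best$prototypes, m)
  best
}

pdsfcm_once <- function(X, nC, m, tol, max_iter) {
  N <- nrow(X)
  # symmetric Dirichlet(1) rows: normalised Exp(1) draws
  W <- matrix(stats::rexp(N * nC), N, nC)
  W <- W / rowSums(W)
  history <- numeric(0)
  V <- NULL
  for (it in seq_len(max_iter)) {
    V <- update_centroids(X, W, m)
    W_new <- update_memberships(X, V, m)
    history <- c(history, sum(W_new^m * partial_dist2(X, V)))
    delta <- max(abs(W_new - W))
    W <- W_new
    if (delta < tol) break
  }
  structure(
    list(n_clusters = nC, fuzzifier = m, prototypes = V, memberships = W,
         objective = history[length(history)], objective_history = history,
         validity = NA_real_, n_iter = length(history), seed = NA_integer_),
    class = "pdsfcm"
  )
}

#' @export
print.pdsfcm <- function(x, ...) {
  cat(sprintf("<pdsfcm> %d clusters, m = %g, objective %.4g, Fukuyama-Sugeno %.4g (%d iterations)\n",
              x$n_clusters, x$fuzzifier, x$objective, x$validity, x$n_iter))
  invisible(x)
}

#' Fukuyama-Sugeno cluster-validity index
#'
#' Balances within-cluster compactness against prototype separation:
#' FS = sum_ij w_ij^m * (d^2(x_j, v_i) - ||v_i - v_bar||^2), where d is the
#' partial distance, v_bar the grand prototype (the membership-weighted mean
#' of the data under the same observed-coordinate convention as the
#' centroids) and the separation term uses the plain Euclidean distance —
#' prototypes are complete by construction. Lower is better.
#'
#' @param X N x D matrix (`NA` = missing).
#' @param W N x nC membership matrix.
#' @param V nC x D prototype matrix.
#' @param m fuzzifier.
#' @return The scalar index value.
#' @export
fukuyama_sugeno <- function(X, W, V, m) {
  Wm <- W^m
  d2 <- partial_dist2(X, V)
  compact <- sum(Wm * d2)
  # grand prototype: total-membership-weighted mean over observing profiles
  u <- rowSums(Wm)
  M <- !is.na(X)
  Xz <- X
  Xz[!M] <- 0
  vbar <- as.numeric((u %*% Xz) / (u %*% (M * 1)))
  sep2 <- rowSums(sweep(V, 2, vbar)^2)          # ||v_i - v_bar||^2
  separation <- sum(colSums(Wm) * sep2)
  compact - separation
}

#' Cluster-count / fuzzifier search grid
#'
#' Defaults follow the method's identification protocol: cluster counts 2-30
#' and fuzzifiers spanning (1, 3]. The fuzzifier grid starts at 1.2 because
#' the membership update is singular at m = 1 (the crisp limit).
#'
#' @param nC_range integer vector of candidate cluster counts.
#' @param m_grid numeric vector of candidate fuzzifiers (> 1).
#' @param restarts,tol,max_iter passed to [pdsfcm()].
#' @param min_cluster_size smallest admissible hard-assigned cluster during
#'   the search; cells violating it are rejected (a seasonal model cannot be
#'   identified on a near-empty concatenated series).
#' @return A list of class `cluster_search_grid`.
#' @export
cluster_search_grid <- function(nC_range = 2:30,
                                m_grid = seq(1.2, 3, by = 0.2),
                                restarts = 5, tol = 1e-5, max_iter = 200,
                                min_cluster_size = 3) {
  if (any(m_grid <= 1)) abort("All fuzzifier values must be > 1.")
  if (any(nC_range < 2)) abort("Cluster counts must be >= 2.")
  structure(list(nC_range = as.integer(nC_range), m_grid = m_grid,
                 restarts = restarts, tol = tol, max_iter = max_iter,
                 min_cluster_size = min_cluster_size),
            class = "cluster_search_grid")
}

#' Select the cluster count and fuzzifier by exhaustive grid search
#'
#' Runs [pdsfcm()] on every (nC, m) cell of the grid and returns the fit
#' minimising the Fukuyama-Sugeno index. Cells whose smallest hard-assigned
#' cluster (argmax membership) holds fewer than `min_cluster_size` profiles
#' are rejected. Ties break toward fewer clusters, then smaller m. The whole
#' search is deterministic given `seed`.
#'
#' @param X N x D matrix of profiles or a `pp_set`.
#' @param grid a [cluster_search_grid()].
#' @param seed integer seed.
#' @return The winning `pdsfcm` object, with the grid-search table attached
#'   as attribute `search` (tibble: nC, m, objective, validity, admissible).
#' @export
select_clustering <- function(X, grid = cluster_search_grid(), seed = 1L) {
  if (inherits(X, "pp_set")) X <- pp_matrix(X)
  X <- as.matrix(X)
  N <- nrow(X)
  nC_range <- grid$nC_range[grid$nC_range < N]
  if (length(nC_range) == 0) abort("Too few profiles for the requested cluster counts.")
  cells <- expand.grid(nC = nC_range, m = grid$m_grid)
  seeds <- derive_seeds(seed, nrow(cells))
  fits <- vector("list", nrow(cells))
  rows <- purrr::map(seq_len(nrow(cells)), function(k) {
    fit <- pdsfcm(X, cells$nC[k], cells$m[k], restarts = grid$restarts,
                  tol = grid$tol, max_iter = grid$max_iter, seed = seeds[k])
    hard <- tabulate(apply(fit$memberships, 1, which.max), nbins = fit$n_clusters)
    admissible <- min(hard) >= grid$min_cluster_size
    fits[[k]] <<- fit
    tibble::tibble(nC = cells$nC[k], m = cells$m[k],
                   objective = fit$objective, validity = fit$validity,
                   min_cluster = min(hard), admissible = admissible)
  })
  search <- dplyr::bind_rows(rows)
  ok <- which(search$admissible)
  if (length(ok) == 0) {
    abort("Every grid cell was rejected (a hard-assigned cluster smaller than the minimum size); more postprandial periods are needed.")
  }
  ord <- ok[order(search$validity[ok], search$nC[ok], search$m[ok])]
  best <- fits[[ord[1]]]
  best$seed <- as.integer(seed)
  attr(best, "search") <- search
  best
}

#' Membership weights of a partially observed postprandial window
#'
#' Scores an in-progress PP against the fitted prototypes: unobserved
#' positions are treated as missing, partial distances to each prototype are
#' computed, and the fitted fuzzifier's membership rule is applied. This is
#' the weight computation of the real-time forecasting loop.
#'
#' @param x length-D vector with `NA` at unobserved positions (at least one
#'   observed entry).
#' @param cluster_set a `pdsfcm` fit.
#' @return Numeric vector of `n_clusters` weights summing to 1.
#' @export
score_membership <- function(x, cluster_set) {
  V <- cluster_set$prototypes
  if (length(x) != ncol(V)) {
    abort(sprintf("Profile length %d does not match prototype length %d.",
                  length(x), ncol(V)))
  }
  if (all(is.na(x))) abort("`x` has no observed entries.")
  if (nrow(V) == 1) return(1)
  as.numeric(update_memberships(matrix(x, 1), V, cluster_set$fuzzifier))
}

#' Hard cluster assignment (argmax membership, ties to the lowest index)
#'
#' @param cluster_set a `pdsfcm` fit.
#' @return Integer vector of cluster labels, one per profile.
#' @export
hard_assignment <- function(cluster_set) {
  apply(cluster_set$memberships, 1, which.max)
}

#' @rdname pdsfcm
#' @param x a `pdsfcm` object.
#' @param ... unused.
#' @method tidy pdsfcm
#' @export
tidy.pdsfcm <- function(x, ...) {
  V <- x$prototypes
  tibble::tibble(
    cluster = rep(seq_len(nrow(V)), each = ncol(V)),
    slot_in_window = rep(seq_len(ncol(V)), nrow(V)),
    glucose = as.numeric(t(V))
  )
}

#' @rdname pdsfcm
#' @method glance pdsfcm
#' @export
glance.pdsfcm <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters, fuzzifier = x$fuzzifier,
    objective = x$objective, validity = x$validity,
    n_iter = x$n_iter, n_profiles = nrow(x$memberships), seed = x$seed
  )
}

#' Serialise / restore a fitted cluster set as JSON
#'
#' @param cluster_set a `pdsfcm` fit.
#' @param path output JSON path.
#' @return `path` (write) or the restored `pdsfcm` object (read).
#' @export
write_cluster_set <- function(cluster_set, path) {
  jsonlite::write_json(
    list(n_clusters = cluster_set$n_clusters, fuzzifier = cluster_set$fuzzifier,
         seed = cluster_set$seed, validity = cluster_set$validity,
         prototypes = cluster_set$prototypes,
         memberships = cluster_set$memberships),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_cluster_set
#' @export
read_cluster_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(n_clusters = as.integer(j$n_clusters), fuzzifier = j$fuzzifier,
         prototypes = as.matrix(j$prototypes),
         memberships = as.matrix(j$memberships),
         objective = NA_real_, objective_history = numeric(0),
         validity = j$validity, n_iter = NA_integer_, seed = as.integer(j$seed)),
    class = "pdsfcm"
  )
}
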