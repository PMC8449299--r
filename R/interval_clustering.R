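#' Reduce the interval-by-action matrix and embed in 2-D
#'
#' Principal components of the concurrent interval-by-action count matrix
#' are retained until the cumulative explained variance reaches
#' `variance_target` (capped at `max_components`), then a seeded stochastic
#' 2-D embedding (exact t-SNE with a Student-t low-dimensional kernel) maps
#' the retained components to the plane for clustering and display. The
#' same seed always yields the identical embedding.
#'
#' @param interval_action Sparse interval-by-action count matrix (rows named
#'   by interval id; see [build_matrices()]).
#' @param variance_target Fraction of variance to retain in (0, 1\];
#'   default 0.97.
#' @param seed Integer seed for the stochastic embedding (mandatory).
#' @param max_components Cap on retained components (default 10).
#' @param perplexity Neighborhood size of the embedding (default 30; reduced
#'   automatically for small inputs).
#' @return An `"ehr_embedding"` list: `coords` (n x 2 matrix, rows named by
#'   interval id), `n_components`, `explained_variance` (cumulative, at the
#'   retained count), `seed`.
#' @export
reduce_and_embed <- function(interval_action, variance_target = 0.97, seed,
                             max_components = 10, perplexity = 30) {
  stopifnot(variance_target > 0, variance_target <= 1)
  if (missing(seed)) stop("seed is mandatory for the embedding", call. = FALSE)
  m <- as.matrix(interval_action)
  if (nrow(m) < 10) stop("need at least 10 intervals to embed", call. = FALSE)
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- pca$sdev^2
  if (sum(v > 1e-12) < 2) {
    stop("interval-action matrix has rank < 2; nothing to embed",
         call. = FALSE)
  }
  cumvar <- cumsum(v) / sum(v)
  ncomp <- which(cumvar >= variance_target)[1]
  if (is.na(ncomp)) ncomp <- length(cumvar)
  ncomp <- max(2, min(ncomp, max_components, ncol(pca$x)))
  scores <- pca$x[, seq_len(ncomp), drop = FALSE]
  coords <- tsne_embed(scores, seed = seed, perplexity = perplexity)
  rownames(coords) <- rownames(m)
  structure(list(coords = coords, n_components = ncomp,
                 explained_variance = cumvar[ncomp], seed = seed),
            class = "ehr_embedding")
}

#' Choose the cluster count by the elbow of the WSS curve
#'
#' Runs K-means for every candidate `k` (best of `nstart` restarts under a
#' fixed seed), records the total within-cluster sum of squared errors
#' (WSS), and returns the knee of the decreasing WSS-vs-k curve via
#' [knee_point()]. The restart-best WSS curve is already close to monotone,
#' so no smoothing is applied by default. Candidates beyond the number of
#' distinct points are dropped (WSS is 0 there by definition).
#'
#' @param points Numeric matrix of coordinates (e.g. embedding coords).
#' @param k_grid Ascending candidate cluster counts; default 2-15.
#' @param seed Integer seed (mandatory; K-means initialization is random).
#' @param nstart Restarts per `k` (default 10).
#' @param smoothing Passed to [knee_point()]; default 1 (none).
#' @return Selected `k` (integer), with the WSS curve attached as attribute
#'   `"curve"`; propagates a "no knee" error for structureless data.
#' @export
choose_k <- function(points, k_grid = 2:15, seed, nstart = 10, smoothing = 1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  curve <- kmeans_wss(points, k_grid, seed = seed, nstart = nstart)
  if (nrow(curve) < 5) {
    stop("fewer than 5 usable candidate k values; widen k_grid",
         call. = FALSE)
  }
  k <- knee_point(curve$k, curve$wss, smoothing = smoothing)
  k_sel <- as.integer(k)
  attr(k_sel, "curve") <- attr(k, "curve")
  attr(k_sel, "strength") <- attr(k, "strength")
  k_sel
}

#' Scan the K-means WSS curve over candidate cluster counts
#'
#' @inheritParams choose_k
#' @return Tibble `k`, `wss` (best of `nstart` restarts per candidate;
#'   non-increasing, with extra restarts on any violation). Candidates
#'   beyond the number of distinct point locations are dropped with a
#'   warning.
#' @export
kmeans_wss <- function(points, k_grid = 2:15, seed, nstart = 10) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  points <- as.matrix(points)
  stopifnot(!is.unsorted(k_grid))
  n_unique <- nrow(unique(points))
  grid <- k_grid[k_grid <= n_unique]
  if (length(grid) < length(k_grid)) {
    warning("dropping candidate k beyond the ", n_unique,
            " distinct point locations")
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  wss <- vapply(grid, function(k) {
    stats::kmeans(points, centers = k, nstart = nstart,
                  iter.max = 100)$tot.withinss
  }, numeric(1))
  # restart starvation shows up as a WSS increase; retry harder
  bad <- which(diff(wss) > 1e-8)
  for (b in bad) {
    refit <- stats::kmeans(points, centers = grid[b + 1],
                           nstart = nstart * 5, iter.max = 200)$tot.withinss
    wss[b + 1] <- min(wss[b + 1], refit)
  }
  if (any(diff(wss) > 1e-8)) {
    warning("WSS not monotone non-increasing on the grid even after ",
            "extra restarts")
  }
  tibble::tibble(k = grid, wss = wss)
}

#' Cluster concurrent intervals by action composition
#'
#' End-to-end clustering: [reduce_and_embed()] the interval-by-action
#' matrix, pick `k` by the WSS elbow (or use a fixed `k`), and assign each
#' concurrent interval to a cluster with K-means on the 2-D embedding
#' coordinates (clustering in the embedding space mirrors common practice
#' but inherits its distortions; set `cluster_space = "pca"` to cluster on
#' the retained components instead).
#'
#' @inheritParams reduce_and_embed
#' @param k `"auto"` (WSS elbow) or a fixed integer.
#' @param k_grid Candidate grid for `"auto"`; default `seq(5, 100, by = 5)`
#'   truncated to at most half the interval count.
#' @param nstart K-means restarts (default 10).
#' @param cluster_space `"embedding"` (default) or `"pca"`.
#' @return A `"cluster_model"` list: `embedding`, `k`, `assignments`
#'   (integer vector named by interval id), `wss_curve` (tibble or `NULL`
#'   when `k` was fixed).
#' @export
cluster_intervals <- function(interval_action, variance_target = 0.97, seed,
                              k = "auto", k_grid = NULL, nstart = 10,
                              max_components = 10, perplexity = 30,
                              cluster_space = c("embedding", "pca")) {
  cluster_space <- match.arg(cluster_space)
  emb <- reduce_and_embed(interval_action, variance_target, seed,
                          max_components, perplexity)
  pts <- if (cluster_space == "embedding") {
    emb$coords
  } else {
    m <- as.matrix(interval_action)
    stats::prcomp(m, center = TRUE)$x[, seq_len(emb$n_components),
                                      drop = FALSE]
  }
  wss_curve <- NULL
  if (identical(k, "auto")) {
    if (is.null(k_grid)) {
      k_grid <- seq(5, min(100, floor(nrow(pts) / 2)), by = 5)
      if (length(k_grid) < 5) k_grid <- 2:max(5, floor(nrow(pts) / 2))
    }
    k <- choose_k(pts, k_grid, seed = seed, nstart = nstart)
    wss_curve <- attr(k, "curve")
  }
  k <- as.integer(k)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(pts, centers = k, nstart = nstart, iter.max = 100)
  assignments <- stats::setNames(km$cluster, rownames(emb$coords))
  structure(list(embedding = emb, k = k, assignments = assignments,
                 wss_curve = wss_curve),
            class = "cluster_model")
}

#' Score session complexity from cluster assignments
#'
#' A concurrent session is "simple" when all its member intervals fall in
#' one action cluster and "complex" when they span several. Computed as the
#' dot product of the cluster-by-interval indicator matrix with the
#' interval-by-session membership matrix, counting the positive entries per
#' session column; complexity is invariant to cluster relabeling.
#'
#' @param assignments Integer cluster per concurrent interval, named by
#'   interval id (see [cluster_intervals()]).
#' @param interval_session Sparse interval-by-session 0/1 matrix; every row
#'   (interval) must be assigned, else an error.
#' @return A list: `per_session` tibble (`session_id`, `n_clusters`) and
#'   `distribution` tibble (`n_clusters_class` in `"1"`, `"2"`, `"3+"`,
#'   `fraction`; fractions sum to 1).
#' @export
session_complexity <- function(assignments, interval_session) {
  ids <- rownames(interval_session)
  if (!all(ids %in% names(assignments))) {
    stop("every session member interval must have a cluster assignment",
         call. = FALSE)
  }
  cl <- assignments[ids]
  k <- max(cl)
  C <- Matrix::sparseMatrix(i = cl, j = seq_along(ids), x = 1,
                            dims = c(k, length(ids)))
  per_sess_counts <- C %*% interval_session        # cluster x session
  n_clusters <- Matrix::colSums(per_sess_counts > 0)
  per_session <- tibble::tibble(session_id = colnames(interval_session),
                                n_clusters = as.integer(n_clusters))
  cls <- cut(per_session$n_clusters, breaks = c(0, 1, 2, Inf),
             labels = c("1", "2", "3+"))
  tab <- table(cls)
  distribution <- tibble::tibble(
    n_clusters_class = names(tab),
    fraction = as.numeric(tab) / nrow(per_session))
  list(per_session = per_session, distribution = distribution)
}
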