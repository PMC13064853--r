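# internal: squared Euclidean distances between grid positions of a
# rows x cols rectangular lattice, nodes indexed row-major.
grid_dist2 <- function(rows, cols) {
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  outer(r, r, `-`)^2 + outer(c, c, `-`)^2
}

# internal: squared Euclidean distances between data rows and codebook rows
cross_dist2 <- function(X, W) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), `+`) - 2 * tcrossprod(X, W)
  d2[d2 < 0] <- 0 # guard tiny negatives from cancellation
  d2
}

# internal: draw codebook init as data rows; distinct rows when possible
init_codebook <- function(X, k, seed) {
  set.seed(seed)
  idx <- if (nrow(X) >= k) sample.int(nrow(X), k) else
    sample.int(nrow(X), k, replace = TRUE)
  list(codebook = X[idx, , drop = FALSE], init_rows = idx)
}

# internal: resolve a schedule argument (NULL -> default linear decay,
# single number -> constant, vector -> per-step values, function -> f(step))
resolve_schedule <- function(s, n_steps, default_from, default_to) {
  if (is.null(s)) return(seq(default_from, default_to, length.out = max(n_steps, 1L)))
  if (is.function(s)) return(vapply(seq_len(n_steps), s, numeric(1)))
  if (length(s) == 1L) return(rep(as.numeric(s), n_steps))
  if (length(s) != n_steps) stop("schedule length must equal the number of steps")
  as.numeric(s)
}

new_som_model <- function(grid, codebook, seed, mode, init_rows,
                          channels = NULL, normalization = NULL) {
  structure(list(grid = as.integer(grid), codebook = codebook,
                 grid_d2 = grid_dist2(grid[1L], grid[2L]),
                 seed = seed, mode = mode, init_rows = init_rows,
                 channels = channels, normalization = normalization),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d grid (%s training), %d feature(s)\n",
              x$grid[1L], x$grid[2L], x$mode, ncol(x$codebook)))
  invisible(x)
}

#' Best-matching-unit assignment
#'
#' Maps every row of a feature matrix to the index of its nearest codebook
#' vector (Euclidean distance); ties go to the smallest node index.
#'
#' @param X numeric matrix, observations in rows.
#' @param model a `som_model`, or a bare codebook matrix.
#' @return Integer vector of node indices (row-major grid order).
#' @export
som_assign <- function(X, model) {
  W <- if (inherits(model, "som_model")) model$codebook else model
  X <- as.matrix(X)
  if (ncol(X) != ncol(W)) {
    stop(sprintf("feature dimension %d does not match codebook dimension %d",
                 ncol(X), ncol(W)))
  }
  max.col(-cross_dist2(X, W), ties.method = "first")
}

#' Online (sequential) self-organizing-map training
#'
#' Classical stochastic SOM: samples are presented one at a time (drawn with
#' replacement under `seed`); at step `t` the best matching unit `b` is
#' found and every codebook vector `w_k` moves toward the sample `x` by
#' `lr(t) * exp(-d_grid(b, k)^2 / (2 * sigma(t)^2)) * (x - w_k)`. The
#' codebook is initialized from data rows sampled under the same seed, so
#' training is fully deterministic given `(X, seed)`.
#'
#' @param X numeric feature matrix (rows = observations), at least one row.
#' @param grid `c(rows, cols)` of the rectangular node lattice; the default
#'   10 x 10 suits cytometry-style metaclustering.
#' @param n_iter number of sample presentations.
#' @param lr learning-rate schedule: `NULL` for a linear decay 0.05 -> 0.01,
#'   a single number, a length-`n_iter` vector, or a function of the step.
#' @param sigma neighbourhood-radius schedule, same conventions; default
#'   linear decay from `max(grid) / 2` to 0.5. A radius of (numerically)
#'   zero restricts each update to the BMU itself.
#' @param seed integer seed controlling init and presentation order.
#' @return A `som_model`.
#' @export
train_som_online <- function(X, grid = c(10L, 10L), n_iter = 10L * nrow(X),
                             lr = NULL, sigma = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("`X` must contain at least one observation")
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  k <- prod(grid)
  ini <- init_codebook(X, k, seed)
  W <- ini$codebook
  order_idx <- sample.int(nrow(X), n_iter, replace = TRUE) # RNG state follows init
  lr_s <- resolve_schedule(lr, n_iter, 0.05, 0.01)
  sg_s <- resolve_schedule(sigma, n_iter, max(grid) / 2, 0.5)
  D2 <- grid_dist2(grid[1L], grid[2L])
  d <- ncol(X)
  for (t in seq_len(n_iter)) {
    if (lr_s[t] == 0) next
    x <- X[order_idx[t], ]
    b <- max.col(-cross_dist2(matrix(x, 1L, d), W), ties.method = "first")
    h <- if (sg_s[t] < 1e-12) as.numeric(seq_len(k) == b) else
      exp(-D2[b, ] / (2 * sg_s[t]^2))
    W <- W + (lr_s[t] * h) * (matrix(x, k, d, byrow = TRUE) - W)
  }
  new_som_model(grid, W, seed, "online", ini$init_rows)
}

#' Batched self-organizing-map training
#'
#' Order-free SOM variant suited to parallel and out-of-core execution: per
#' epoch the codebook is frozen, every batch independently accumulates the
#' neighbourhood-weighted sums `num_k = sum_i h(bmu(x_i), k) * x_i` and
#' `den_k = sum_i h(bmu(x_i), k)` with
#' `h = exp(-d_grid^2 / (2 * sigma^2))`, the accumulators are added across
#' batches, and each node is replaced by `num_k / den_k` (nodes with zero
#' mass keep their previous vector). Because batch accumulators combine by
#' addition, the trained codebook does not depend on how the data is split
#' into batches. With `sigma = 0` one epoch is exactly one k-means (Lloyd)
#' step on the current codebook.
#'
#' @param X numeric feature matrix.
#' @param grid `c(rows, cols)` node lattice (default 10 x 10).
#' @param n_epochs number of whole-data passes (default 10).
#' @param batch_size rows per batch (default 2048).
#' @param sigma neighbourhood schedule over epochs (`NULL` = linear decay
#'   `max(grid)/2` -> 0.5, a number, vector of length `n_epochs`, or
#'   function of the epoch). Values below 1e-12 mean hard BMU assignment.
#' @param seed integer seed (codebook init only; batch training itself is
#'   deterministic).
#' @param batches optional explicit partition of `1:nrow(X)` as a list of
#'   index vectors, overriding `batch_size`; the result is invariant to
#'   this partition up to floating-point summation order.
#' @return A `som_model`.
#' @export
train_som_batch <- function(X, grid = c(10L, 10L), n_epochs = 10L,
                            batch_size = 2048L, sigma = NULL, seed = 1L,
                            batches = NULL) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("`X` must contain at least one observation")
  if (n_epochs < 1L) stop("`n_epochs` must be >= 1")
  if (is.null(batches)) {
    if (batch_size < 1L) stop("`batch_size` must be >= 1")
    batches <- split(seq_len(nrow(X)),
                     ceiling(seq_len(nrow(X)) / as.numeric(batch_size)))
  }
  k <- prod(grid)
  ini <- init_codebook(X, k, seed)
  W <- ini$codebook
  sg_s <- resolve_schedule(sigma, n_epochs, max(grid) / 2, 0.5)
  D2 <- grid_dist2(grid[1L], grid[2L])
  d <- ncol(X)
  for (e in seq_len(n_epochs)) {
    H <- if (sg_s[e] < 1e-12) diag(k) else exp(-D2 / (2 * sg_s[e]^2))
    num <- matrix(0, k, d)
    den <- numeric(k)
    for (idx in batches) {
      Xb <- X[idx, , drop = FALSE]
      bmu <- max.col(-cross_dist2(Xb, W), ties.method = "first")
      A <- H[bmu, , drop = FALSE] # batch x nodes neighbourhood weights
      num <- num + crossprod(A, Xb)
      den <- den + colSums(A)
    }
    upd <- den > 0
    W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  new_som_model(grid, W, seed, "batch", ini$init_rows)
}

#' Group SOM nodes into metaclusters
#'
#' FlowSOM-style second stage: agglomerative hierarchical clustering of the
#' codebook vectors (Euclidean distance, average linkage) cut at `n_meta`
#' clusters. Deterministic; metacluster ids are numbered in order of first
#' appearance over the node sequence.
#'
#' @param model a `som_model`.
#' @param n_meta number of metaclusters, between 1 and the node count.
#' @return Integer vector mapping each node to its metacluster.
#' @export
metacluster <- function(model, n_meta) {
  stopifnot(inherits(model, "som_model"))
  k <- nrow(model$codebook)
  if (n_meta < 1L || n_meta > k) {
    stop(sprintf("`n_meta` must be between 1 and the number of nodes (%d)", k))
  }
  if (n_meta == k) return(seq_len(k))
  hc <- stats::hclust(stats::dist(model$codebook), method = "average")
  unname(stats::cutree(hc, k = n_meta))
}

#' Homogeneity, completeness and V-measure of a clustering
#'
#' Entropy-based external evaluation of predicted cluster labels against
#' reference classes. Homogeneity `h = 1 - H(C|K) / H(C)` is 1 when every
#' predicted cluster contains a single class; completeness
#' `c = 1 - H(K|C) / H(K)` is 1 when every class lives in a single cluster;
#' the V-measure is their harmonic mean `2hc / (h + c)`. Conventions:
#' `h = 1` when `H(C) = 0`, `c = 1` when `H(K) = 0`, `v = 0` when
#' `h + c = 0`. All three are invariant to relabeling either side.
#'
#' @param labels_true,labels_pred equal-length vectors (any label type).
#' @return List with `homogeneity`, `completeness`, `v_measure`.
#' @export
v_measure <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred) || !length(labels_true)) {
    stop("labelings must have equal positive length")
  }
  n <- length(labels_true)
  tab <- table(labels_true, labels_pred)
  p_ck <- tab / n
  p_c <- rowSums(p_ck)
  p_k <- colSums(p_ck)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h_c <- ent(p_c)
  h_k <- ent(p_k)
  # H(C|K) = -sum_ck p(c,k) log( p(c,k) / p(k) )
  cond <- function(p_joint, p_marg_cols) {
    s <- 0
    for (j in seq_along(p_marg_cols)) {
      col <- p_joint[, j]
      col <- col[col > 0]
      if (length(col)) s <- s - sum(col * log(col / p_marg_cols[j]))
    }
    s
  }
  h_ck <- cond(p_ck, p_k)
  h_kc <- cond(t(p_ck), p_c)
  h <- if (h_c == 0) 1 else 1 - h_ck / h_c
  c_ <- if (h_k == 0) 1 else 1 - h_kc / h_k
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  list(homogeneity = h, completeness = c_, v_measure = v)
}
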