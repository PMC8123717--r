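## k-prototypes clustering for mixed numeric/categorical data, extended to
## honour per-record survey calibration weights.
##
## Dissimilarity between a record and a prototype is
##   d(x, y) = sum_h (x_h - y_h)^2  +  lambda * #{categorical mismatches}
## (squared Euclidean on the numeric block, no square root, plus a
## lambda-weighted Hamming count). Prototypes are weighted means on the
## numeric block and weighted modes on the categorical block; the cost of a
## model is sum_i w_i * d(x_i, prototype(x_i)).

.kp_blocks <- function(x) {
  stopifnot(is.data.frame(x))
  is_num <- vapply(x, is.numeric, logical(1))
  Xn <- as.matrix(x[, is_num, drop = FALSE])
  Xc <- as.matrix(as.data.frame(lapply(x[, !is_num, drop = FALSE],
                                       as.character),
                                stringsAsFactors = FALSE))
  if (ncol(Xc) == 0L) Xc <- matrix(character(0), nrow(x), 0)
  if (ncol(Xn) + ncol(Xc) == 0L) stop("no variables to cluster on")
  list(num = Xn, cat = Xc)
}

#' Mixed numeric/categorical dissimilarity
#'
#' Squared Euclidean distance on the numeric block plus `lambda` times the
#' number of categorical mismatches (Hamming count). No square root is
#' taken. With `lambda = 0` only the numeric block contributes.
#'
#' @param x_num Numeric matrix (n x p) or length-p vector of record values.
#' @param x_cat Character matrix (n x q) or length-q vector of record
#'   labels.
#' @param y_num Length-p numeric prototype center.
#' @param y_cat Length-q character prototype modes.
#' @param lambda Non-negative trade-off between the two blocks.
#' @return Numeric vector of n dissimilarities (length 1 for vector input).
#' @examples
#' mixed_distance(c(1, 2), c("a", "b"), c(4, 6), c("a", "c"), lambda = 2) # 27
#' @export
mixed_distance <- function(x_num, x_cat, y_num, y_cat, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(dim(x_num))) x_num <- matrix(x_num, nrow = 1)
  if (is.null(dim(x_cat))) x_cat <- matrix(as.character(x_cat), nrow = 1)
  if (ncol(x_num) != length(y_num))
    stop("numeric arity mismatch: record has ", ncol(x_num),
         " variables, prototype has ", length(y_num))
  if (ncol(x_cat) != length(y_cat))
    stop("categorical arity mismatch: record has ", ncol(x_cat),
         " variables, prototype has ", length(y_cat))
  d <- numeric(max(nrow(x_num), nrow(x_cat)))
  if (ncol(x_num) > 0)
    d <- d + rowSums((x_num - rep(y_num, each = nrow(x_num)))^2)
  if (ncol(x_cat) > 0)
    d <- d + lambda * rowSums(x_cat != rep(y_cat, each = nrow(x_cat)))
  d
}

# n x k matrix of record-to-prototype dissimilarities
.kp_dist <- function(Xn, Xc, centers, modes, lambda) {
  n <- max(nrow(Xn), nrow(Xc))
  k <- max(nrow(centers), nrow(modes))
  D <- matrix(0, n, k)
  for (j in seq_len(k)) {
    D[, j] <- mixed_distance(Xn, Xc, centers[j, ], modes[j, ], lambda)
  }
  D
}

#' Estimate the numeric/categorical trade-off lambda from the data
#'
#' `lambda` is set to the ratio of the average weighted variance of the
#' numeric variables to the average categorical diversity
#' `1 - sum(f_c^2)` (weighted Gini impurity) over the categorical
#' variables, so that, at the estimate, a typical squared numeric
#' deviation and a typical categorical mismatch contribute comparably to
#' the dissimilarity. Scaling all numeric variables by `c` scales the
#' estimate by `c^2`.
#'
#' @param x data.frame; numeric columns form the numeric block, all other
#'   columns the categorical block.
#' @param weights Positive record weights (default: equal).
#' @return Positive scalar lambda.
#' @export
estimate_lambda <- function(x, weights = NULL) {
  b <- .kp_blocks(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  .check_sample(rep(0, nrow(x)), weights)
  if (ncol(b$num) == 0L || ncol(b$cat) == 0L)
    stop("lambda estimation needs at least one numeric and one categorical variable; supply lambda explicitly")
  num_var <- mean(apply(b$num, 2, wvar, w = weights))
  cat_div <- mean(apply(b$cat, 2, function(col) {
    f <- wtable(col, weights)
    1 - sum(f^2)
  }))
  if (num_var <= 0 || cat_div <= 0)
    stop("all-constant numeric or categorical block; supply lambda explicitly")
  num_var / cat_div
}

# weighted mode with deterministic ties: lexicographically smallest
# category among tied weight-sum maxima
.wmode <- function(x, w) {
  lev <- sort(unique(x))
  s <- vapply(lev, function(l) sum(w[x == l]), numeric(1))
  lev[which.max(s)]
}

.kp_update <- function(Xn, Xc, w, assign, k) {
  centers <- matrix(NA_real_, k, ncol(Xn))
  modes <- matrix(NA_character_, k, ncol(Xc))
  for (j in seq_len(k)) {
    idx <- which(assign == j)
    wj <- w[idx]
    if (ncol(Xn) > 0)
      centers[j, ] <- colSums(Xn[idx, , drop = FALSE] * wj) / sum(wj)
    if (ncol(Xc) > 0)
      modes[j, ] <- apply(Xc[idx, , drop = FALSE], 2, .wmode, w = wj)
  }
  list(centers = centers, modes = modes)
}

# single run from explicit starting prototypes; returns model pieces
.kp_run <- function(Xn, Xc, w, k, lambda, centers, modes, max_iter) {
  n <- max(nrow(Xn), nrow(Xc))
  assign_old <- NULL
  cost_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- .kp_dist(Xn, Xc, centers, modes, lambda)
    assign <- max.col(-D, ties.method = "first")
    # empty-cluster rescue: reseed the prototype with the record farthest
    # (in weighted dissimilarity) from its current prototype, then reassign
    guard <- 0L
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) == 0L || guard >= k) break
      guard <- guard + 1L
      j <- empty[1L]
      far <- which.max(w * D[cbind(seq_len(n), assign)])
      if (ncol(Xn) > 0) centers[j, ] <- Xn[far, ]
      if (ncol(Xc) > 0) modes[j, ] <- Xc[far, ]
      D[, j] <- mixed_distance(Xn, Xc, centers[j, ], modes[j, ], lambda)
      assign <- max.col(-D, ties.method = "first")
    }
    cost <- sum(w * D[cbind(seq_len(n), assign)])
    cost_trace <- c(cost_trace, cost)
    if (!is.null(assign_old) && all(assign == assign_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    up <- .kp_update(Xn, Xc, w, assign, k)
    centers <- up$centers
    modes <- up$modes
    assign_old <- assign
  }
  list(centers = centers, modes = modes, assign = assign,
       cost = cost_trace[length(cost_trace)], cost_trace = cost_trace,
       n_iter = iter, converged = converged)
}

# weighted sampling of k starting records with pairwise-distinct
# (numeric, categorical) profiles
.kp_init_indices <- function(Xn, Xc, w, k) {
  key <- apply(cbind(format(Xn, digits = 15), Xc), 1, paste, collapse = "\r")
  uk <- unique(key)
  if (length(uk) < k)
    stop("k = ", k, " exceeds the number of distinct records (", length(uk), ")")
  reps <- match(uk, key)
  reps[sample.int(length(reps), k, prob = w[reps])]
}

#' Fit a survey-weighted k-prototypes model
#'
#' Alternating assignment/update clustering of mixed data under record
#' weights: each record is assigned to the prototype minimising
#' [mixed_distance()] (ties to the lowest cluster index); numeric centers
#' are then recomputed as weighted means and categorical modes as
#' weight-sum-maximising categories (mode ties to the lexicographically
#' smallest label). Iteration stops when no record changes cluster or
#' `max_iter` is reached. The run is repeated `n_restarts` times from
#' weight-proportional random starting records and the model with minimal
#' weighted cost is returned. The within-run cost sequence is
#' non-increasing and is kept in the model (`cost_trace`).
#'
#' An empty cluster arising during iteration is reseeded with the record
#' farthest (in weighted dissimilarity) from its current prototype, so the
#' fitted model always has k non-empty clusters.
#'
#' @param x data.frame of clustering variables; numeric columns form the
#'   numeric block, character/factor columns the categorical block.
#' @param k Number of clusters (>= 1, at most the number of distinct
#'   records).
#' @param lambda Numeric/categorical trade-off; `NULL` (default) estimates
#'   it with [estimate_lambda()].
#' @param weights Positive record weights (default: equal).
#' @param seed Integer seed governing all restarts.
#' @param max_iter Maximum iterations per run.
#' @param n_restarts Number of random restarts.
#' @param init Optional explicit initialization for a single run: either a
#'   vector of k row indices, or a list with `centers` (k x p matrix) and
#'   `modes` (k x q character matrix). Overrides `n_restarts`.
#' @param person_id Optional record identifiers stored in the model.
#' @return A `kproto_model`: list with `k`, `lambda`, `numeric_vars`,
#'   `categorical_vars`, `numeric_centers`, `categorical_modes`,
#'   `assignments`, `cost`, `cost_trace`, `n_iter`, `seed`, `converged`,
#'   `person_id`, `weights`.
#' @export
kproto_fit <- function(x, k, lambda = NULL, weights = NULL, seed = 1L,
                       max_iter = 100L, n_restarts = 10L, init = NULL,
                       person_id = NULL) {
  b <- .kp_blocks(x)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  .check_sample(rep(0, n), weights)
  stopifnot(k >= 1, max_iter >= 1)
  if (is.null(lambda)) {
    lambda <- if (ncol(b$num) > 0L && ncol(b$cat) > 0L)
      estimate_lambda(x, weights) else if (ncol(b$cat) > 0L) 1 else 0
  }
  if (lambda < 0) stop("lambda must be >= 0")

  make_start <- function(idx_or_proto) {
    if (is.list(idx_or_proto)) {
      list(centers = idx_or_proto$centers, modes = idx_or_proto$modes)
    } else {
      idx <- idx_or_proto
      list(centers = b$num[idx, , drop = FALSE],
           modes = b$cat[idx, , drop = FALSE])
    }
  }

  set.seed(seed)
  starts <- if (!is.null(init)) list(make_start(init)) else {
    lapply(seq_len(n_restarts), function(r)
      make_start(.kp_init_indices(b$num, b$cat, weights, k)))
  }

  best <- NULL
  for (st in starts) {
    run <- .kp_run(b$num, b$cat, weights, k, lambda,
                   st$centers, st$modes, max_iter)
    if (is.null(best) || run$cost < best$cost) best <- run
  }

  colnames(best$centers) <- colnames(b$num)
  colnames(best$modes) <- colnames(b$cat)
  structure(list(
    k = as.integer(k),
    lambda = lambda,
    numeric_vars = colnames(b$num),
    categorical_vars = colnames(b$cat),
    numeric_centers = best$centers,
    categorical_modes = best$modes,
    assignments = best$assign,
    cost = best$cost,
    cost_trace = best$cost_trace,
    n_iter = best$n_iter,
    seed = as.integer(seed),
    converged = best$converged,
    person_id = if (is.null(person_id)) as.character(seq_len(n)) else
      as.character(person_id),
    weights = weights
  ), class = "kproto_model")
}

#' @export
print.kproto_model <- function(x, ...) {
  cat("<kproto_model> k =", x$k, " lambda =", format(x$lambda, digits = 4),
      " cost =", format(x$cost, digits = 6), "\n")
  cat("  ", length(x$assignments), "records,",
      x$n_iter, "iterations,",
      if (x$converged) "converged" else "max_iter reached", "\n")
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign new records to the clusters of a fitted model
#'
#' Each record goes to the nearest prototype under [mixed_distance()] with
#' the model's lambda; prototypes are not updated. Ties go to the lowest
#' cluster index. `newdata` must carry the model's clustering variables
#' (matched by name).
#'
#' @param object A `kproto_model`.
#' @param newdata data.frame with the model's numeric and categorical
#'   variables.
#' @param ... Unused.
#' @return Integer vector of cluster ids in 1..k.
#' @export
predict.kproto_model <- function(object, newdata, ...) {
  miss <- setdiff(c(object$numeric_vars, object$categorical_vars),
                  names(newdata))
  if (length(miss) > 0L)
    stop("newdata is missing clustering variable(s): ",
         paste(miss, collapse = ", "))
  Xn <- as.matrix(newdata[, object$numeric_vars, drop = FALSE])
  Xc <- as.matrix(as.data.frame(lapply(
    newdata[, object$categorical_vars, drop = FALSE], as.character),
    stringsAsFactors = FALSE))
  if (ncol(Xc) == 0L) Xc <- matrix(character(0), nrow(newdata), 0)
  D <- .kp_dist(Xn, Xc, object$numeric_centers, object$categorical_modes,
                object$lambda)
  max.col(-D, ties.method = "first")
}

#' Scan cluster counts and suggest one by the elbow criterion
#'
#' Fits best-of-restarts models for every k in `k_range` and reports the
#' cost curve. To guarantee a non-increasing curve, each k additionally
#' warm-starts one run from the best model at the previous k plus one
#' extra prototype seeded at the record farthest from its assigned
#' prototype. The suggested k maximises the discrete second difference
#' `cost[k-1] - 2 cost[k] + cost[k+1]` (the sharpest turning point of the
#' curve); the full curve is always returned so the choice can be
#' overridden by inspection.
#'
#' @inheritParams kproto_fit
#' @param k_range Increasing integer vector of candidate k (length >= 3
#'   for a suggestion; shorter ranges return `NA` as suggestion).
#' @return List with `k_range`, `costs`, `suggested_k`, `models` (one
#'   fitted `kproto_model` per k).
#' @export
elbow_scan <- function(x, k_range, lambda = NULL, weights = NULL, seed = 1L,
                       max_iter = 100L, n_restarts = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(length(k_range) >= 1, all(k_range >= 1))
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (is.null(lambda)) lambda <- estimate_lambda(x, weights)
  b <- .kp_blocks(x)
  models <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    m <- kproto_fit(x, k, lambda = lambda, weights = weights,
                    seed = seed + i - 1L, max_iter = max_iter,
                    n_restarts = n_restarts)
    if (!is.null(prev) && prev$k == k - 1L) {
      # warm start: previous prototypes plus the worst-served record
      D <- .kp_dist(b$num, b$cat, prev$numeric_centers,
                    prev$categorical_modes, lambda)
      dmin <- D[cbind(seq_len(nrow(x)), prev$assignments)]
      far <- which.max(weights * dmin)
      init <- list(
        centers = rbind(prev$numeric_centers, b$num[far, , drop = TRUE]),
        modes = rbind(prev$categorical_modes, b$cat[far, , drop = TRUE]))
      m2 <- kproto_fit(x, k, lambda = lambda, weights = weights,
                       seed = seed + i - 1L, max_iter = max_iter,
                       init = init)
      if (m2$cost < m$cost) m <- m2
    }
    models[[i]] <- m
    prev <- m
  }
  costs <- vapply(models, function(m) m$cost, numeric(1))
  suggested <- NA_integer_
  if (length(k_range) >= 3L) {
    interior <- 2:(length(k_range) - 1L)
    d2 <- costs[interior - 1L] - 2 * costs[interior] + costs[interior + 1L]
    suggested <- k_range[interior[which.max(d2)]]
  }
  list(k_range = k_range, costs = costs, suggested_k = suggested,
       models = models)
}
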