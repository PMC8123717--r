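test_that("mixed dissimilarity evaluates its closed form", {
  expect_equal(mixed_distance(c(1, 2), c("a", "b"), c(4, 6), c("a", "c"), 2),
               27)
  expect_equal(mixed_distance(c(1, 2), c("a", "b"), c(1, 2), c("a", "b"), 5),
               0)
  # lambda = 0: only the numeric block matters
  expect_equal(mixed_distance(c(1, 2), c("x", "y"), c(4, 6), c("a", "c"), 0),
               25)
  expect_error(mixed_distance(c(1, 2, 3), "a", c(1, 2), "a", 1), "arity")
  expect_error(mixed_distance(c(1, 2), c("a", "b"), c(1, 2), "a", 1), "arity")
})

test_that("lambda estimation matches its closed form and scales quadratically", {
  # two numeric variables with weighted variance 4, one balanced binary
  # categorical: lambda = 4 / (1 - 0.5) = 8
  df <- data.frame(x1 = c(0, 4), x2 = c(2, 6),
                   c1 = c("a", "b"), stringsAsFactors = FALSE)
  expect_equal(estimate_lambda(df), 8)
  df3 <- df; df3$x1 <- 3 * df3$x1; df3$x2 <- 3 * df3$x2
  expect_equal(estimate_lambda(df3), 9 * 8)
  const <- data.frame(x1 = c(0, 4), c1 = c("a", "a"),
                      stringsAsFactors = FALSE)
  expect_error(estimate_lambda(const), "constant")
})

test_that("k = 1 gives the global weighted mean/mode and total dispersion", {
  set.seed(2)
  df <- random_mixed_df(25)
  w <- runif(25, 0.5, 3)
  m <- kproto_fit(df, 1, lambda = 2, weights = w, seed = 1, n_restarts = 1)
  expect_equal(as.numeric(m$numeric_centers),
               c(wmean(df$x1, w), wmean(df$x2, w)))
  # weighted mode, independently computed
  wm <- sapply(c("c1", "c2"), function(v) {
    lev <- sort(unique(df[[v]]))
    lev[which.max(sapply(lev, function(l) sum(w[df[[v]] == l])))]
  })
  expect_equal(as.character(m$categorical_modes), unname(wm))
  expected_cost <- sum(w * mixed_distance(
    as.matrix(df[, 1:2]), as.matrix(df[, 3:4]),
    as.numeric(m$numeric_centers), as.character(m$categorical_modes), 2))
  expect_equal(m$cost, expected_cost)
})

test_that("two well-separated planted groups are recovered at k = 2", {
  set.seed(4)
  g <- rep(1:2, each = 15)
  df <- data.frame(x1 = c(rnorm(15, 0, 0.3), rnorm(15, 10, 0.3)),
                   x2 = c(rnorm(15, 0, 0.3), rnorm(15, 10, 0.3)),
                   c1 = c(rep("a", 15), rep("b", 15)),
                   stringsAsFactors = FALSE)
  m <- kproto_fit(df, 2, lambda = 5, weights = runif(30, 1, 2),
                  seed = 9, n_restarts = 5)
  expect_true(all(table(m$assignments, g) %in% c(0, 15)))
})

test_that("prototypes and cost are invariant to weight splitting", {
  set.seed(6)
  df <- random_mixed_df(20)
  w <- runif(20, 1, 4)
  init <- list(centers = as.matrix(df[c(1, 5, 9), 1:2]),
               modes = as.matrix(df[c(1, 5, 9), 3:4]))
  m1 <- kproto_fit(df, 3, lambda = 1.5, weights = w, init = init)
  df2 <- rbind(df, df)
  m2 <- kproto_fit(df2, 3, lambda = 1.5, weights = c(w / 2, w / 2),
                   init = init)
  expect_equal(m2$numeric_centers, m1$numeric_centers, tolerance = 1e-12)
  expect_equal(m2$categorical_modes, m1$categorical_modes)
  expect_equal(m2$cost, m1$cost, tolerance = 1e-12)
})

test_that("lambda = 0 reduces to weighted k-means on the numeric block", {
  set.seed(7)
  df <- random_mixed_df(40)
  w <- runif(40, 1, 3)
  init <- list(centers = as.matrix(df[c(2, 17, 31), 1:2]),
               modes = as.matrix(df[c(2, 17, 31), 3:4]))
  m <- kproto_fit(df, 3, lambda = 0, weights = w, init = init)
  # same fit with the categorical content scrambled: identical clusters
  df2 <- df
  df2$c1 <- sample(df2$c1); df2$c2 <- sample(df2$c2)
  init2 <- list(centers = init$centers,
                modes = as.matrix(df2[c(2, 17, 31), 3:4]))
  m2 <- kproto_fit(df2, 3, lambda = 0, weights = w, init = init2)
  expect_equal(m2$assignments, m$assignments)
  expect_equal(m2$cost, m$cost)
})

test_that("the within-run cost sequence never increases", {
  set.seed(8)
  for (rep in 1:20) {
    df <- random_mixed_df(sample(10:40, 1))
    w <- runif(nrow(df), 0.5, 5)
    m <- kproto_fit(df, sample(2:4, 1), weights = w,
                    seed = rep, n_restarts = 1)
    expect_true(all(diff(m$cost_trace) <= 1e-9))
  }
})

test_that("permutation of record order leaves the cost unchanged", {
  set.seed(10)
  df <- random_mixed_df(30)
  w <- runif(30, 1, 3)
  init <- list(centers = as.matrix(df[c(3, 20), 1:2]),
               modes = as.matrix(df[c(3, 20), 3:4]))
  m1 <- kproto_fit(df, 2, lambda = 2, weights = w, init = init)
  perm <- sample(30)
  m2 <- kproto_fit(df[perm, ], 2, lambda = 2, weights = w[perm],
                   init = init)
  expect_equal(m2$cost, m1$cost, tolerance = 1e-12)
})

test_that("prediction is a fixed point on training data and honours ties", {
  set.seed(11)
  df <- random_mixed_df(35)
  w <- runif(35, 1, 2)
  m <- kproto_fit(df, 3, lambda = 1, weights = w, seed = 2, n_restarts = 5)
  expect_true(m$converged)
  expect_equal(predict(m, df), m$assignments)
  # a record equal to prototype j lands in cluster j
  proto2 <- data.frame(x1 = m$numeric_centers[2, 1],
                       x2 = m$numeric_centers[2, 2],
                       c1 = m$categorical_modes[2, 1],
                       c2 = m$categorical_modes[2, 2],
                       stringsAsFactors = FALSE)
  expect_equal(predict(m, proto2), 2L)
  # exact tie between two prototypes goes to the lowest cluster index
  tie <- structure(list(
    k = 2L, lambda = 1,
    numeric_vars = "x", categorical_vars = "c",
    numeric_centers = matrix(c(0, 2), 2, 1, dimnames = list(NULL, "x")),
    categorical_modes = matrix(c("a", "a"), 2, 1,
                               dimnames = list(NULL, "c"))),
    class = "kproto_model")
  expect_equal(predict(tie, data.frame(x = 1, c = "a")), 1L)
  expect_error(predict(m, df[, 1:3]), "missing clustering variable")
})

test_that("k exceeding the number of distinct records is refused", {
  df <- data.frame(x = c(1, 1, 2), c = c("a", "a", "b"),
                   stringsAsFactors = FALSE)
  expect_error(kproto_fit(df, 3, lambda = 1, seed = 1), "distinct")
})

test_that("elbow scan returns a full, non-increasing curve and flags the knee", {
  set.seed(12)
  # four clear planted groups in mixed data
  g <- rep(1:4, each = 20)
  df <- data.frame(x1 = rnorm(80, c(0, 8, 0, 8)[g], 0.4),
                   x2 = rnorm(80, c(0, 0, 8, 8)[g], 0.4),
                   c1 = c("a", "b", "c", "d")[g],
                   stringsAsFactors = FALSE)
  sc <- elbow_scan(df, 2:7, lambda = 4, weights = runif(80, 1, 2),
                   seed = 3, n_restarts = 4)
  expect_length(sc$costs, 6)
  expect_true(all(is.finite(sc$costs)))
  expect_true(all(diff(sc$costs) <= 1e-9))
  expect_equal(sc$suggested_k, 4L)
})
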