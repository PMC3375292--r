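test_that("parallel analysis keeps nothing on pure noise, finds planted factors", {
  # null: i.i.d. Gaussian, no structure; retention should be 0 nearly always
  set.seed(42)
  zeros <- vapply(1:10, function(i) {
    x <- matrix(rnorm(300 * 20), 300, 20)
    parallel_analysis(x, n_iterations = 100, seed = i) == 0
  }, logical(1))
  expect_gte(mean(zeros), 0.9)
  # one dominant factor loading 0.9 on 10 variables: always retained
  for (i in 1:5) {
    set.seed(100 + i)
    f <- rnorm(200)
    x <- 0.9 * matrix(f, 200, 10) + sqrt(1 - 0.81) * matrix(rnorm(2000), 200, 10)
    expect_gte(parallel_analysis(x, n_iterations = 100, seed = i), 1)
  }
})

test_that("two perfectly correlated variables retain one component", {
  set.seed(7)
  v <- rnorm(100)
  x <- cbind(a = v, b = 2 * v + 5)
  expect_error(parallel_analysis(cbind(x, c = 1)), "constant")
  n <- parallel_analysis(x, n_iterations = 200, seed = 3)
  expect_identical(as.integer(n), 1L)
  expect_equal(attr(n, "eigenvalues")[1], 2)   # closed form
})

test_that("a single retained component is unrotated and scores match", {
  set.seed(8)
  f <- rnorm(150)
  x <- 0.8 * matrix(f, 150, 5) + 0.6 * matrix(rnorm(750), 150, 5)
  m <- pca_varimax(x, 1)
  ev <- eigen(cor(x), symmetric = TRUE)
  unrot <- ev$vectors[, 1] * sqrt(ev$values[1])
  # loadings are the unrotated loadings (up to sign convention)
  expect_equal(abs(unname(m$loadings[, 1])), abs(unrot), tolerance = 1e-10)
  # Bartlett scores track the unrotated component direction
  expect_gt(abs(cor(m$scores[, 1], scale(x) %*% ev$vectors[, 1])), 0.999)
})

test_that("varimax rotation recovers planted two-block structure", {
  set.seed(9)
  f1 <- rnorm(400); f2 <- rnorm(400)
  x <- cbind(0.85 * matrix(f1, 400, 5) + 0.5 * matrix(rnorm(2000), 400, 5),
             0.85 * matrix(f2, 400, 5) + 0.5 * matrix(rnorm(2000), 400, 5))
  m <- pca_varimax(x, 2)
  L <- abs(m$loadings)
  block <- rep(1:2, each = 5)
  main <- apply(L, 1, which.max)
  expect_true(all(main == block) || all(main == 3 - block))
  cross <- vapply(seq_len(10), function(i) min(L[i, ]), numeric(1))
  expect_true(all(cross < 0.15))
  # communalities invariant under rotation; varprops sum below 1
  ev <- eigen(cor(x), symmetric = TRUE)
  L0 <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_equal(rowSums(m$loadings^2), unname(rowSums(L0^2)), tolerance = 1e-8)
  expect_lte(sum(m$varprop), 1)
})

test_that("rotation preserves total retained variance on real-shaped data", {
  h <- hierarchy_config(2, 3, 12, sd_individual = 1, sd_within = 1.2,
                        seed = 55)
  s <- sample_population(diaemus_profile(), h)
  x <- s[, c("duration_ms", paste0("f0_anchor_", 1:4),
             paste0("harm_db_", 1:3))]
  m <- pca_varimax(x, 3)
  ev <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(m$varprop) * ncol(x), sum(ev[1:3]), tolerance = 1e-8)
})
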