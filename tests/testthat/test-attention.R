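test_that("query/key/value projections are plain matrix products", {
  X <- matrix(0, 4, 3)
  W <- diag(3)
  qkv <- project_qkv(X, W, W, W)
  expect_true(all(qkv$Q == 0) && all(qkv$K == 0) && all(qkv$V == 0))

  X2 <- phytofuse:::with_seed(1, matrix(stats::rnorm(12), 4))
  qkv2 <- project_qkv(X2, W, W, W)
  expect_equal(qkv2$Q, X2)

  Wq <- phytofuse:::with_seed(2, matrix(stats::rnorm(6), 3, 2))
  by_hand <- t(apply(X2, 1, function(r) colSums(r * Wq)))
  expect_equal(project_qkv(X2, Wq, Wq, Wq)$Q, by_hand, tolerance = 1e-12)
  expect_error(project_qkv(X2, diag(2), diag(2), diag(2)), "d rows")
})

test_that("scaled dot-product attention matches scalar evaluations", {
  one <- scaled_dot_attention(matrix(1, 1, 1), matrix(2, 1, 1), matrix(5, 1, 1), 1)
  expect_equal(one$A, matrix(1))
  expect_equal(one$output, matrix(5))

  # zero keys give uniform attention: output rows are column means of V
  Q <- phytofuse:::with_seed(3, matrix(stats::rnorm(6), 3, 2))
  V <- phytofuse:::with_seed(4, matrix(stats::rnorm(6), 3, 2))
  unif <- scaled_dot_attention(Q, matrix(0, 3, 2), V, 2)
  expect_equal(unif$A, matrix(1 / 3, 3, 3))
  expect_equal(unif$output[1, ], colMeans(V))

  # two-logit case reduces to a sigmoid: softmax(1/sqrt(2), 0)
  sda <- scaled_dot_attention(
    Q = matrix(c(1, 0), 1), K = diag(2), V = matrix(c(1, 0), 2), d_k = 2
  )
  expect_equal(drop(sda$output), 1 / (1 + exp(-1 / sqrt(2))), tolerance = 1e-12)
  expect_error(scaled_dot_attention(Q, matrix(0, 3, 2), V, 0), "d_k")
})

test_that("multi-head reduces to single-head under identity output maps", {
  d <- 3
  m1 <- attention_init(d, h = 1, d_k = d, seed = 10)
  m1$params$W_O <- diag(d)
  X <- phytofuse:::with_seed(5, matrix(stats::rnorm(15), 5))
  qkv <- project_qkv(X, m1$params$W_Q1, m1$params$W_K1, m1$params$W_V1)
  single <- scaled_dot_attention(qkv$Q, qkv$K, qkv$V, d)
  mh <- multi_head(X, m1)
  expect_equal(mh$output, single$output, tolerance = 1e-12)

  # duplicating a head and stacking (I; 0) in W_O reproduces the single head
  m2 <- attention_init(d, h = 2, d_k = d, seed = 10)
  for (nm in c("W_Q", "W_K", "W_V")) {
    m2$params[[paste0(nm, 2)]] <- m1$params[[paste0(nm, 1)]]
    m2$params[[paste0(nm, 1)]] <- m1$params[[paste0(nm, 1)]]
  }
  m2$params$W_O <- rbind(diag(d), matrix(0, d, d))
  expect_equal(multi_head(X, m2)$output, single$output, tolerance = 1e-12)
})

test_that("multi-head agrees with a naive loop-based reference", {
  m <- attention_init(4, h = 2, d_k = 3, seed = 21)
  X <- phytofuse:::with_seed(22, matrix(stats::rnorm(24), 6))
  naive_softmax_row <- function(v) exp(v - max(v)) / sum(exp(v - max(v)))
  heads <- lapply(1:2, function(j) {
    Q <- X %*% m$params[[paste0("W_Q", j)]]
    K <- X %*% m$params[[paste0("W_K", j)]]
    V <- X %*% m$params[[paste0("W_V", j)]]
    S <- matrix(0, 6, 6)
    for (a in 1:6) for (b in 1:6) S[a, b] <- sum(Q[a, ] * K[b, ]) / sqrt(3)
    A <- t(apply(S, 1, naive_softmax_row))
    A %*% V
  })
  ref <- cbind(heads[[1]], heads[[2]]) %*% m$params$W_O
  expect_equal(multi_head(X, m)$output, ref, tolerance = 1e-12)
})

test_that("window prediction composes project -> attend -> concat -> pool -> affine", {
  m <- attention_init(3, h = 2, d_k = 2, seed = 31)
  X <- phytofuse:::with_seed(32, matrix(stats::rnorm(12), 4))
  out <- multi_head(X, m)$output
  by_hand <- sum(m$params$head_w * out[4, ]) + m$params$head_b
  expect_equal(temporal_encode_predict(X, m), by_hand, tolerance = 1e-12)
  expect_equal(
    temporal_encode_predict(X, m, pooling = "mean"),
    sum(m$params$head_w * colMeans(out)) + m$params$head_b,
    tolerance = 1e-12
  )

  # zero output map and head weights leave only the bias
  m0 <- m
  m0$params$W_O <- m0$params$W_O * 0
  m0$params$head_w <- m0$params$head_w * 0
  m0$params$head_b <- 2.5
  expect_equal(temporal_encode_predict(X, m0), 2.5)
  expect_error(temporal_encode_predict(X[0, , drop = FALSE], m), "empty")
})

test_that("attention invariants hold over random inputs", {
  for (seed in 1:30) {
    dat <- phytofuse:::with_seed(seed, {
      T_len <- sample(2:8, 1)
      d <- sample(2:5, 1)
      list(
        X = matrix(stats::rnorm(T_len * d), T_len),
        model = attention_init(d, h = 2, d_k = 3, seed = seed + 500),
        perm = sample(T_len)
      )
    })
    mh <- multi_head(dat$X, dat$model)
    for (A in mh$attention) {
      expect_true(all(A >= 0))
      expect_lt(max(abs(rowSums(A) - 1)), 1e-12)
    }
    # convex-hull bounding of each head's output in the V columns
    j <- 1
    qkv <- project_qkv(
      dat$X, dat$model$params$W_Q1, dat$model$params$W_K1, dat$model$params$W_V1
    )
    sda <- scaled_dot_attention(qkv$Q, qkv$K, qkv$V, 3)
    for (col in seq_len(ncol(sda$output))) {
      expect_gte(min(sda$output[, col]) - min(qkv$V[, col]), -1e-12)
      expect_lte(max(sda$output[, col]) - max(qkv$V[, col]), 1e-12)
    }
    # permutation equivariance without positional encoding
    mh_perm <- multi_head(dat$X[dat$perm, , drop = FALSE], dat$model)
    expect_equal(mh_perm$output, mh$output[dat$perm, , drop = FALSE], tolerance = 1e-10)
    expect_equal(
      temporal_encode_predict(dat$X[dat$perm, , drop = FALSE], dat$model, pooling = "mean"),
      temporal_encode_predict(dat$X, dat$model, pooling = "mean"),
      tolerance = 1e-10
    )
  }
})

test_that("softmax is stable at extreme logits", {
  X <- matrix(c(1e4, -1e4, 0, 1e4), 2)
  m <- attention_init(2, h = 1, d_k = 2, seed = 1)
  mh <- multi_head(X, m)
  expect_true(all(is.finite(mh$output)))
  expect_lt(max(abs(rowSums(mh$attention[[1]]) - 1)), 1e-12)
})

test_that("positional encoding breaks permutation symmetry when enabled", {
  m <- attention_init(3, h = 2, d_k = 2, positional = TRUE, seed = 3)
  X <- phytofuse:::with_seed(4, matrix(stats::rnorm(15), 5))
  p1 <- temporal_encode_predict(X, m, pooling = "mean")
  p2 <- temporal_encode_predict(X[5:1, , drop = FALSE], m, pooling = "mean")
  expect_gt(abs(p1 - p2), 1e-8)
})

test_that("attention backprop matches central finite differences", {
  for (i in 1:4) {
    cfg <- phytofuse:::with_seed(100 + i, list(
      T_len = sample(3:6, 1), d = sample(2:4, 1),
      pooling = sample(c("last", "mean"), 1)
    ))
    m <- attention_init(cfg$d, h = 2, d_k = 2, pooling = cfg$pooling, seed = 200 + i)
    dat <- phytofuse:::with_seed(300 + i, list(
      X = lapply(1:2, function(k) matrix(stats::rnorm(cfg$T_len * cfg$d), cfg$T_len)),
      y = stats::rnorm(2)
    ))
    an <- attention_backprop(m, dat$X, dat$y)$grads
    num <- finite_diff_grads(m, dat$X, dat$y)
    expect_lt(max_rel_grad_err(an, num), 1e-5)
  }
})
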