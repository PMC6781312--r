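test_that("orthogonal columns all have VIF 1", {
  set.seed(1)
  M <- scale(matrix(rnorm(40 * 4), 40, 4), scale = FALSE)
  U <- svd(M)$u
  expect_equal(unname(vif(data_block(U, "orth"))), rep(1, 4),
               tolerance = 1e-10)
})

test_that("VIF equals the inverse-correlation-matrix diagonal", {
  set.seed(2)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + 1e-3 * rnorm(n)
  b <- data_block(cbind(x1 = x1, x2 = x2, x3 = x3), "tri")
  oracle <- diag(solve(cor(b$values)))
  expect_equal(unname(vif(b)), unname(oracle), tolerance = 1e-6)
})

test_that("VIF is invariant under affine rescaling of a column", {
  b <- rand_block(30, 4, seed = 3)
  v0 <- vif(b)
  b2 <- b
  b2$values[, 2] <- 100 * b$values[, 2] - 7
  expect_equal(unname(vif(b2)), unname(v0), tolerance = 1e-8)
})

test_that("perfect collinearity yields Inf with a warning and a lone
           column errors", {
  set.seed(4)
  x <- rnorm(20)
  b <- data_block(cbind(a = x, b = 2 * x, c = rnorm(20)), "col")
  w <- capture_warnings(v <- vif(b))
  expect_match(w, "collinear", all = TRUE)
  expect_true(is.infinite(v[["a"]]))
  expect_error(vif(data_block(cbind(a = rnorm(5)), "one")),
               "two variables")
})

test_that("adding a pure-noise variable never lowers other VIFs", {
  b <- rand_block(30, 4, seed = 5)
  b$values[, 2] <- b$values[, 1] + 0.3 * b$values[, 2]
  v0 <- vif(b)
  set.seed(6)
  b2 <- data_block(cbind(b$values, noise = rnorm(30)), "plus")
  v1 <- vif(b2)
  expect_true(all(v1[names(v0)] >= v0 - 1e-10))
})

test_that("BIP and VIP satisfy their normalization identities", {
  models <- list(
    { cs <- case_study(seed = 2)
      fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3) },
    { sys <- linked_system(seed = 30)
      fit_mbplspm(sys$X1, sys$X2, sys$X3, sys$Y, 2) },
    { sys <- linked_system(seed = 31)
      fit_mbpls(list(sys$X1, sys$X2, sys$X3), sys$Y, 3) })
  for (m in models) {
    b <- bip(m); v <- vip(m)
    expect_equal(sum(b^2), length(b), tolerance = 1e-6)
    expect_equal(sum(v^2), length(v), tolerance = 1e-6)
    # squared variant is the square of the rooted one
    expect_equal(bip(m, squared = TRUE), b^2, tolerance = 1e-10)
  }
})

test_that("a single predictor block has BIP exactly 1", {
  X <- rand_block(20, 4, "X1", seed = 32)
  Y <- rand_block(20, 2, "Y", seed = 33, role = "predictee")
  fit <- fit_mbplspm(X, NULL, NULL, Y, 2)
  expect_equal(unname(bip(fit)), 1, tolerance = 1e-12)
})

test_that("identical blocks share BIP 1 by symmetry", {
  X <- rand_block(20, 4, "X", seed = 34)
  X2 <- X; X2$name <- "X2"
  X3 <- X; X3$name <- "X3"
  Y <- rand_block(20, 2, "Y", seed = 35, role = "predictee")
  fit <- fit_mbpls(list(X, X2, X3), Y, 2)
  expect_equal(unname(bip(fit)), rep(1, 3), tolerance = 1e-6)
})

test_that("a lone relevant variable in an orthogonal design gets
           VIP sqrt(n)", {
  set.seed(36)
  M <- scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)
  U <- svd(M)$u
  X <- data_block(U, "X1")
  Y <- data_block(cbind(y = U[, 1]), "Y", role = "predictee")
  fit <- fit_mbplspm(X, NULL, NULL, Y, 1)
  v <- vip(fit)
  expect_equal(unname(v[1]), sqrt(5), tolerance = 1e-6)
  expect_lt(max(v[-1]), 0.01)
  # VIP identity survives appending a noise variable (n -> n + 1)
  set.seed(37)
  colnames(U) <- paste0("u", 1:5)
  X6 <- data_block(cbind(U, noise = rnorm(40)), "X1")
  fit6 <- fit_mbplspm(X6, NULL, NULL, Y, 1)
  expect_equal(sum(vip(fit6)^2), 6, tolerance = 1e-6)
})

test_that("exchangeable variables drive VIP toward 1 in the
           noise-free limit", {
  # orthogonal design with equal effects: perfectly exchangeable
  set.seed(38)
  M <- scale(matrix(rnorm(60 * 4), 60, 4), scale = FALSE)
  U <- svd(M)$u
  X <- data_block(U, "X1")
  Y <- data_block(cbind(y = rowSums(U)), "Y", role = "predictee")
  fit <- fit_mbplspm(X, NULL, NULL, Y, 1)
  expect_lt(max(abs(vip(fit) - 1)), 1e-6)
})

test_that("model comparison reports all three kinds, near-perfect on
           noiseless linear data", {
  # noiseless response consistent with the path topology (X3 driven
  # by X1); all three model kinds then explain essentially all of Y
  set.seed(40)
  n <- 30
  X1 <- rand_block(n, 4, "X1", seed = 41)
  X2 <- rand_block(n, 3, "X2", seed = 42)
  X3v <- cbind(f = drop(X1$values %*% c(1, 0.5, 0, 0)),
               g = drop(X1$values %*% c(0, 0, 1, -0.5)))
  X3 <- data_block(X3v, "X3", role = "interior")
  Y <- data_block(cbind(y = X3v[, "f"] - X3v[, "g"] +
                          0.5 * X2$values[, 1]),
                  "Y", role = "predictee")
  tab <- compare_models(X1, X2, X3, Y, 3, cv = FALSE)
  expect_identical(tab$model, c("pls", "mbpls", "mbplspm"))
  expect_true(all(tab$r2y_cum >= 99))
})

test_that("path model explains more predictor variance than MBPLS on
           case-shaped data", {
  wins <- vapply(1:20, function(s) {
    cs <- case_study(seed = 8000 + s)
    pm <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3,
                      cs$blocks$Y, 3)
    mb <- fit_mbpls(list(cs$X1, cs$blocks$X2, cs$blocks$X3),
                    cs$blocks$Y, 3)
    pm$r2x_cum[3] >= mb$r2x_cum[3]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
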