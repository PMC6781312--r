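test_that("degenerate topologies reduce to PLS and MBPLS exactly", {
  for (seed in c(1, 7, 33)) {
    n <- 24
    X1 <- rand_block(n, 5, "X1", seed = seed)
    X2 <- rand_block(n, 4, "X2", seed = seed + 50)
    X3 <- rand_block(n, 3, "X3", seed = seed + 90)
    set.seed(seed + 150)
    Y <- data_block(cbind(y1 = X1$values[, 1] + 0.3 * rnorm(n),
                          y2 = X2$values[, 1] + 0.3 * rnorm(n)),
                    "Y", role = "predictee")
    pm1 <- fit_mbplspm(X1, NULL, NULL, Y, 2, tol = 1e-12)
    pl <- fit_pls(X1, Y, 2)
    expect_equal(predict_y(pm1, X1), predict(pl, X1),
                 tolerance = 1e-8)
    pm2 <- fit_mbplspm(NULL, X2, X3, Y, 2, tol = 1e-12)
    mb <- fit_mbpls(list(X2, X3), Y, 2, tol = 1e-12)
    expect_equal(predict_y(pm2, x2 = X2, x3 = X3),
                 predict(mb, list(X2, X3)), tolerance = 1e-8)
  }
})

test_that("all weight vectors are unit norm and convergence is tight", {
  cs <- case_study(seed = 3)
  fit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
  for (b in fit$block_names) {
    expect_equal(unname(sqrt(colSums(fit$W[[b]]^2))), rep(1, 3),
                 tolerance = 1e-10)
  }
  expect_equal(unname(sqrt(colSums(fit$W_T^2))), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(sqrt(colSums(fit$C_U^2))), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(sqrt(colSums(fit$C_Y^2))), rep(1, 3),
               tolerance = 1e-10)
  expect_true(all(fit$iterations < 500))
})

test_that("residual split factors satisfy r^2 + s^2 = 1 and the
           three-term reconstruction", {
  cs <- case_study(seed = 4)
  fit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
  expect_equal(fit$r_X3^2 + fit$s_X3^2, rep(1, 3), tolerance = 1e-10)
  # accumulate the split deflation from the scaled X3 block forward
  X3s <- autoscale(cs$blocks$X3)$block$values / sqrt(2)
  for (a in 1:3) {
    u_hat <- fit$b_X1X3[a] * fit$T_b$X1[, a]
    X3s <- X3s - (fit$s_X3[a] * tcrossprod(fit$T_b$X3[, a],
                                           fit$P$X3[, a]) +
                    fit$r_X3[a] * tcrossprod(u_hat, fit$C_X3[, a]))
  }
  expect_equal(X3s, fit$E$X3, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("deflation shrinks every block's Frobenius norm", {
  cs <- case_study(seed = 6)
  fit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
  start <- list(X1 = cs$X1, X2 = cs$blocks$X2, X3 = cs$blocks$X3)
  for (b in names(start)) {
    p <- ncol(start[[b]]$values)
    X0 <- autoscale(start[[b]])$block$values / sqrt(p)
    expect_lte(sum(fit$E[[b]]^2), sum(X0^2) + 1e-10)
  }
  expect_lte(sum(fit$E_Y^2),
             sum(autoscale(cs$blocks$Y)$block$values^2) + 1e-10)
})

test_that("training prediction reproduces Y minus its residual", {
  cs <- case_study(seed = 8)
  fit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 3)
  yh <- predict_y(fit, cs$X1, cs$blocks$X2, cs$blocks$X3)
  ys <- autoscale(cs$blocks$Y)
  expected <- invert_scaling(ys$block$values - fit$E_Y, ys$state)
  expect_equal(yh, expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("mean process settings predict the training response mean", {
  cs <- case_study(seed = 9)
  fit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y, 2)
  at_mean <- function(b) {
    m <- b
    m$values <- matrix(rep(colMeans(b$values), each = 2), 2,
                       ncol(b$values),
                       dimnames = list(c("m1", "m2"), b$var_names))
    m$run_ids <- c("m1", "m2")
    m
  }
  yh <- predict_y(fit, at_mean(cs$X1), at_mean(cs$blocks$X2),
                  at_mean(cs$blocks$X3))
  expect_equal(unname(yh[1, ]),
               unname(colMeans(cs$blocks$Y$values)), tolerance = 1e-8)
})

test_that("super score and response score correlate strongly, with
           non-negative sign", {
  # exact-model limit: every block shares one latent factor and the
  # response is that factor, so the LV1 relationship is essentially
  # perfect
  set.seed(10)
  n <- 30
  f <- rnorm(n)
  mk <- function(p, name, role = "predictor") {
    vals <- f %o% runif(p, 0.5, 1) + 1e-6 * matrix(rnorm(n * p), n, p)
    colnames(vals) <- paste0(tolower(name), seq_len(p))
    data_block(vals, name, role = role)
  }
  X1 <- mk(4, "X1"); X2 <- mk(3, "X2")
  X3 <- mk(2, "X3", role = "interior")
  Y <- data_block(cbind(y = f + 1e-6 * rnorm(n)), "Y",
                  role = "predictee")
  fit <- fit_mbplspm(X1, X2, X3, Y, 2)
  rel <- score_relationship(fit)
  expect_gt(rel$correlation[1], 0.999)
  expect_true(all(rel$correlation >= 0))
  # on case-shaped data the leading two LVs carry a stronger
  # super-score/response relationship than the third
  drops <- vapply(1:30, function(s) {
    cs <- case_study(seed = 6000 + s)
    f <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3,
                     cs$blocks$Y, 3)
    r <- score_relationship(f)$correlation
    min(r[1], r[2]) >= r[3]
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("path model converges within the iteration cap on
           case-shaped data", {
  iters <- vapply(1:25, function(s) {
    cs <- case_study(seed = 7000 + s)
    f <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3,
                     cs$blocks$Y, 3)
    max(f$iterations)
  }, numeric(1))
  expect_true(all(iters < 500))
})

test_that("the literal index variant changes only the interior split", {
  cs <- case_study(seed = 11)
  f_def <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3,
                       cs$blocks$Y, 2)
  f_lit <- fit_mbplspm(cs$X1, cs$blocks$X2, cs$blocks$X3,
                       cs$blocks$Y, 2, wk_index_literal = TRUE)
  # first LV is identical up to the split; later LVs may drift through
  # the changed X3 deflation
  expect_equal(f_def$W_T[, 1], f_lit$W_T[, 1], tolerance = 1e-8)
  expect_equal(f_def$b_TY[1], f_lit$b_TY[1], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f_def$b_X3Y[1], f_lit$b_X3Y[1])))
})
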