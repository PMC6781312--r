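# Internal: subset a data_block by row index, keeping names.
block_rows <- function(block, idx) {
  out <- block
  out$values <- block$values[idx, , drop = FALSE]
  out$run_ids <- block$run_ids[idx]
  rownames(out$values) <- out$run_ids
  out
}

# Internal: deterministic NIPALS start vector = the column with the
# largest variance of the current (residual) matrix.
start_column <- function(M) {
  v <- apply(M, 2L, stats::var)
  M[, which.max(v)]
}

# Internal: normalize to unit length; error on degenerate zero vector.
unitize <- function(v, what = "weight") {
  nrm <- sqrt(sum(v^2))
  if (nrm < .Machine$double.eps) {
    stop("zero-norm ", what, " vector (degenerate block)")
  }
  v / nrm
}

#' Fit a two-matrix PLS model (NIPALS)
#'
#' Extracts `n_lvs` latent variables maximizing the covariance between
#' projections of `X` and `Y`. Scores `T = X W` (computed on deflated
#' matrices), loadings satisfy `X = T P' + E`, and the response is
#' reconstructed as `Y = T diag(b) Q' + F` with unit-norm y-loading
#' columns `Q` and inner coefficients `b`. `X` is deflated by `t p'` and
#' `Y` by its rank-one prediction after each component.
#'
#' Blocks are autoscaled internally and the preprocessing state is
#' stored, so [predict.pls_model()] accepts and returns original units.
#'
#' @param x Predictor [data_block()].
#' @param y Response [data_block()].
#' @param n_lvs Number of latent variables.
#' @param tol Relative convergence tolerance on the `u` score.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return Object of class `pls_model`: weights `W`, scores `T`,
#'   x-loadings `P`, unit-norm y-loadings `Q`, inner coefficients `b`,
#'   residuals `E`, `F`, cumulative `r2x`/`r2y` per LV, preprocessing
#'   states.
#' @export
fit_pls <- function(x, y, n_lvs, tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(x, "data_block"), inherits(y, "data_block"))
  stopifnot_same_runs(list(x, y))
  sx <- autoscale(x); sy <- autoscale(y)
  X <- sx$block$values; Y <- sy$block$values
  n <- nrow(X)
  if (n_lvs > min(n - 1L, ncol(X))) {
    stop("n_lvs must be <= min(n_runs - 1, n_vars_X)")
  }
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  p <- ncol(X); q <- ncol(Y)
  W <- P <- matrix(0, p, n_lvs)
  Q <- matrix(0, q, n_lvs)
  Tm <- U <- matrix(0, n, n_lvs)
  b <- numeric(n_lvs)
  r2x <- r2y <- numeric(n_lvs)
  iters <- integer(n_lvs)
  for (a in seq_len(n_lvs)) {
    u <- start_column(Y)
    it <- 0L
    repeat {
      it <- it + 1L
      w <- unitize(crossprod(X, u))
      tt <- drop(X %*% w)
      qv <- unitize(crossprod(Y, tt), "y-loading")
      u_new <- drop(Y %*% qv)
      delta <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)),
                                              .Machine$double.eps)
      u <- u_new
      if (delta < tol || ncol(Y) == 1L) break
      if (it >= max_iter) {
        stop("NIPALS did not converge for component ", a,
             " (last relative change ", signif(delta, 3), ")")
      }
    }
    s <- sign(w[which.max(abs(w))]); if (s == 0) s <- 1
    w <- s * w; tt <- s * tt
    tt2 <- sum(tt^2)
    pv <- drop(crossprod(X, tt)) / tt2
    cv <- drop(crossprod(Y, tt)) / tt2     # = b * q
    ba <- sqrt(sum(cv^2))
    qv <- if (ba > 0) cv / ba else qv
    X <- X - tcrossprod(tt, pv)
    Y <- Y - tcrossprod(tt, ba * qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv
    Tm[, a] <- tt; U[, a] <- u; b[a] <- ba
    iters[a] <- it
    r2x[a] <- 100 * (1 - sum(X^2) / ssx0)
    r2y[a] <- 100 * (1 - sum(Y^2) / ssy0)
  }
  dimnames(W) <- dimnames(P) <- list(x$var_names,
                                     paste0("LV", seq_len(n_lvs)))
  dimnames(Q) <- list(y$var_names, colnames(W))
  dimnames(Tm) <- list(x$run_ids, colnames(W))
  structure(list(W = W, T = Tm, P = P, Q = Q, U = U, b = b,
                 E = X, F = Y, r2x_cum = r2x, r2y_cum = r2y,
                 n_lvs = n_lvs, iterations = iters,
                 x_state = sx$state, y_state = sy$state,
                 x_vars = x$var_names, y_vars = y$var_names),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs, %d x-vars -> %d y-vars\n",
              x$n_lvs, nrow(x$W), nrow(x$Q)))
  cat(sprintf("  R2X_cum = %.1f%%, R2Y_cum = %.1f%%\n",
              x$r2x_cum[x$n_lvs], x$r2y_cum[x$n_lvs]))
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Predictor [data_block()] on original units with the
#'   training variables.
#' @param ... Unused.
#' @return Matrix of predictions on original response units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "data_block"))
  if (!identical(newdata$var_names, object$x_vars)) {
    stop("newdata variables do not match the training block")
  }
  Xs <- autoscale(newdata, state = object$x_state)$block$values
  Yh <- matrix(0, nrow(Xs), nrow(object$Q))
  for (a in seq_len(object$n_lvs)) {
    tt <- drop(Xs %*% object$W[, a])
    Yh <- Yh + tcrossprod(tt, object$b[a] * object$Q[, a])
    Xs <- Xs - tcrossprod(tt, object$P[, a])
  }
  out <- invert_scaling(Yh, object$y_state)
  dimnames(out) <- list(newdata$run_ids, object$y_vars)
  out
}

#' Leave-one-out cross-validated Q2
#'
#' Refits the chosen model `n` times, each with one run left out, and
#' accumulates the prediction error of the left-out run on the
#' autoscaled response scale (scaling statistics are recomputed inside
#' each fold, so no information leaks from the held-out run).
#' `Q2_cum = 100 (1 - PRESS / TSS)` with TSS the total sum of squares of
#' the full-data autoscaled response pooled over columns.
#'
#' @param x Predictors: a [data_block()] (`model = "pls"`), a list of
#'   blocks (`"mbpls"`), or a named list with elements `X1`, `X2`, `X3`
#'   (`"mbplspm"`, empties allowed as `NULL`).
#' @param y Response [data_block()].
#' @param n_lvs Number of latent variables.
#' @param model Model kind to cross-validate.
#' @param ... Further arguments passed to the fitter.
#' @return Object of class `fit_quality` with `r2x_cum`, `r2y_cum`,
#'   `q2y_cum` (percent) and `n_lvs`, all from the stated model kind.
#' @export
loo_q2 <- function(x, y, n_lvs, model = c("pls", "mbpls", "mbplspm"),
                   ...) {
  model <- match.arg(model)
  stopifnot(inherits(y, "data_block"))
  n <- nrow(y$values)
  if (n < 3L) stop("leave-one-out cross-validation needs >= 3 runs")
  fit_fun <- switch(model,
    pls = function(xb, yb, ...) fit_pls(xb, yb, n_lvs, ...),
    mbpls = function(xb, yb, ...) fit_mbpls(xb, yb, n_lvs, ...),
    mbplspm = function(xb, yb, ...)
      fit_mbplspm(xb$X1, xb$X2, xb$X3, yb, n_lvs, ...))
  pred_fun <- switch(model,
    pls = function(m, xb) predict(m, xb),
    mbpls = function(m, xb) predict(m, xb),
    mbplspm = function(m, xb) predict_y(m, xb$X1, xb$X2, xb$X3))
  subset_x <- function(idx) {
    if (inherits(x, "data_block")) return(block_rows(x, idx))
    lapply(x, function(b) if (is.null(b)) NULL else block_rows(b, idx))
  }
  full <- fit_fun(x, y, ...)
  ys <- autoscale(y)
  Ys <- ys$block$values
  press <- 0
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    m <- tryCatch(fit_fun(subset_x(keep), block_rows(y, keep), ...),
                  error = function(e) {
                    stop("cross-validation refit failed on fold ", i,
                         ": ", conditionMessage(e))
                  })
    yh <- pred_fun(m, subset_x(i))
    yh_s <- sweep(sweep(yh, 2L, ys$state$means, "-"),
                  2L, ys$state$sds, "/")
    press <- press + sum((Ys[i, ] - yh_s)^2)
  }
  tss <- sum(Ys^2)
  structure(list(model = model,
                 r2x_cum = full$r2x_cum[n_lvs],
                 r2y_cum = full$r2y_cum[n_lvs],
                 q2y_cum = 100 * (1 - press / tss),
                 n_lvs = n_lvs),
            class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("<fit_quality %s> LVs = %d  R2X = %.1f%%  R2Y = %.1f%%  Q2Y = %.1f%%\n",
              toupper(x$model), x$n_lvs, x$r2x_cum, x$r2y_cum, x$q2y_cum))
  invisible(x)
}
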