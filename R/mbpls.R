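#' Fit a super-score multi-block PLS model
#'
#' MBPLS extension of PLS in which each predictor block contributes a
#' block score per latent variable; the block scores are stacked into a
#' super matrix from which a single super score is extracted against the
#' response. The super-score variant is used throughout: loadings are
#' regressions of each block on the super score and all blocks are
#' deflated by the super score, `X_b = T_s P_b' + E_b`, `Y = T_s C' + F`.
#'
#' Per component the inner loop alternates (from a deterministic start,
#' the largest-variance response column):
#' block weights `w_b = X_b' u` (unit norm), block scores `t_b = X_b w_b`,
#' super weights `w_s = T_blocks' u` (unit norm), super score
#' `t_s = T_blocks w_s`, y-loading `q = Y' t_s` (unit norm), `u = Y q`.
#'
#' @param blocks List of predictor [data_block()]s sharing run ids
#'   (zero-width blocks are skipped).
#' @param y Response [data_block()].
#' @param n_lvs Number of latent variables.
#' @param tol Convergence tolerance on the relative change of the super
#'   score.
#' @param max_iter Maximum inner iterations per component.
#' @param block_scaling `"sqrt_nvars"` (default) or `"none"`: divide
#'   each autoscaled block by the square root of its variable count so
#'   wide blocks do not dominate the super level; without it the
#'   super-level weights track block width rather than response
#'   relevance.
#' @return Object of class `mbpls_model` with per-block weights `W_b`,
#'   block scores, loadings `P_b` and residuals `E_b`; super scores
#'   `T_s`, per-LV super-level block weights `W_s` (unit norm columns),
#'   y-loadings `Q`, inner coefficients `b`, residual `F`, cumulative
#'   `r2x`/`r2y`, block contribution percentages per LV.
#' @export
fit_mbpls <- function(blocks, y, n_lvs, tol = 1e-10, max_iter = 500L,
                      block_scaling = c("sqrt_nvars", "none")) {
  block_scaling <- match.arg(block_scaling)
  if (inherits(blocks, "data_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L, inherits(y, "data_block"))
  keep <- vapply(blocks, function(b) ncol(b$values) > 0L, logical(1L))
  blocks <- blocks[keep]
  if (!length(blocks)) stop("all predictor blocks are empty")
  stopifnot_same_runs(c(blocks, list(y)))
  scaled <- lapply(blocks, autoscale)
  states <- lapply(scaled, `[[`, "state")
  Xb <- lapply(scaled, function(s) {
    apply_block_scaling(s$block, block_scaling)$values
  })
  sy <- autoscale(y)
  Y <- sy$block$values
  n <- nrow(Y); B <- length(Xb)
  bnames <- vapply(blocks, `[[`, character(1L), "name")
  ssx0 <- sum(vapply(Xb, function(M) sum(M^2), numeric(1L)))
  ssy0 <- sum(Y^2)
  W_b <- lapply(Xb, function(M) matrix(0, ncol(M), n_lvs,
                                       dimnames = list(colnames(M),
                                                       NULL)))
  P_b <- W_b
  Tb <- lapply(Xb, function(M) matrix(0, n, n_lvs))
  W_s <- matrix(0, B, n_lvs, dimnames = list(bnames, NULL))
  Ts <- matrix(0, n, n_lvs, dimnames = list(y$run_ids, NULL))
  Q <- matrix(0, ncol(Y), n_lvs, dimnames = list(y$var_names, NULL))
  bcoef <- numeric(n_lvs)
  r2x <- r2y <- numeric(n_lvs)
  contrib <- matrix(0, B, n_lvs, dimnames = list(bnames, NULL))
  iters <- integer(n_lvs)
  for (a in seq_len(n_lvs)) {
    u <- start_column(Y)
    ts_old <- NULL
    it <- 0L
    repeat {
      it <- it + 1L
      wb <- lapply(Xb, function(M) unitize(crossprod(M, u)))
      tb <- mapply(function(M, w) drop(M %*% w), Xb, wb,
                   SIMPLIFY = FALSE)
      Tblk <- do.call(cbind, tb)
      ws <- unitize(crossprod(Tblk, u), "super weight")
      ts <- drop(Tblk %*% ws)
      qv <- unitize(crossprod(Y, ts), "y-loading")
      u <- drop(Y %*% qv)
      if (!is.null(ts_old)) {
        delta <- sqrt(sum((ts - ts_old)^2)) /
          max(sqrt(sum(ts_old^2)), .Machine$double.eps)
        if (delta < tol) break
        if (it >= max_iter) {
          stop("MBPLS did not converge for component ", a)
        }
      }
      ts_old <- ts
    }
    # sign fix: flip every block weight (hence t_b and t_s) together so
    # the identities t_b = X_b w_b and t_s = [t_b] w_s are preserved
    wcat <- unlist(wb)
    s <- sign(wcat[which.max(abs(wcat))]); if (s == 0) s <- 1
    wb <- lapply(wb, function(v) s * v)
    tb <- lapply(tb, function(v) s * v)
    ts <- s * ts
    ts2 <- sum(ts^2)
    pb <- lapply(Xb, function(M) drop(crossprod(M, ts)) / ts2)
    cv <- drop(crossprod(Y, ts)) / ts2
    ba <- sqrt(sum(cv^2))
    qv <- if (ba > 0) cv / ba else qv
    Xb <- mapply(function(M, p) M - tcrossprod(ts, p), Xb, pb,
                 SIMPLIFY = FALSE)
    Y <- Y - tcrossprod(ts, ba * qv)
    for (bi in seq_len(B)) {
      W_b[[bi]][, a] <- wb[[bi]]
      P_b[[bi]][, a] <- pb[[bi]]
      Tb[[bi]][, a] <- tb[[bi]]
    }
    W_s[, a] <- ws; Ts[, a] <- ts; Q[, a] <- qv; bcoef[a] <- ba
    contrib[, a] <- 100 * ws^2
    iters[a] <- it
    r2x[a] <- 100 * (1 - sum(vapply(Xb, function(M) sum(M^2),
                                    numeric(1L))) / ssx0)
    r2y[a] <- 100 * (1 - sum(Y^2) / ssy0)
  }
  structure(list(W_b = W_b, P_b = P_b, T_b = Tb, W_s = W_s, T_s = Ts,
                 Q = Q, b = bcoef, E_b = Xb, F = Y,
                 r2x_cum = r2x, r2y_cum = r2y,
                 block_contrib = contrib, n_lvs = n_lvs,
                 iterations = iters, block_names = bnames,
                 x_states = states, y_state = sy$state,
                 block_scaling = block_scaling,
                 x_vars = lapply(blocks, `[[`, "var_names"),
                 y_vars = y$var_names),
            class = "mbpls_model")
}

#' @export
print.mbpls_model <- function(x, ...) {
  cat(sprintf("<mbpls_model> %d LVs, blocks: %s\n", x$n_lvs,
              paste(x$block_names, collapse = ", ")))
  cat(sprintf("  R2X_cum = %.1f%%, R2Y_cum = %.1f%%\n",
              x$r2x_cum[x$n_lvs], x$r2y_cum[x$n_lvs]))
  invisible(x)
}

#' Predict responses from a fitted MBPLS model
#'
#' @param object An `mbpls_model`.
#' @param newdata List of predictor [data_block()]s matching the
#'   training blocks (a single `data_block` is accepted for one-block
#'   models).
#' @param ... Unused.
#' @return Matrix of predictions on original response units.
#' @export
predict.mbpls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "data_block")) newdata <- list(newdata)
  newdata <- newdata[vapply(newdata, function(b)
    !is.null(b) && ncol(b$values) > 0L, logical(1L))]
  if (length(newdata) != length(object$x_vars)) {
    stop("expected ", length(object$x_vars), " non-empty blocks")
  }
  for (bi in seq_along(newdata)) {
    if (!identical(newdata[[bi]]$var_names, object$x_vars[[bi]])) {
      stop("variables of block ", bi, " do not match training")
    }
  }
  Xb <- mapply(function(b, st) {
    apply_block_scaling(autoscale(b, state = st)$block,
                        object$block_scaling)$values
  }, newdata, object$x_states, SIMPLIFY = FALSE)
  n <- nrow(Xb[[1L]])
  Yh <- matrix(0, n, nrow(object$Q))
  for (a in seq_len(object$n_lvs)) {
    tb <- mapply(function(M, W) drop(M %*% W[, a]), Xb, object$W_b,
                 SIMPLIFY = FALSE)
    ts <- drop(do.call(cbind, tb) %*% object$W_s[, a])
    Yh <- Yh + tcrossprod(ts, object$b[a] * object$Q[, a])
    Xb <- mapply(function(M, P) M - tcrossprod(ts, P[, a]), Xb,
                 object$P_b, SIMPLIFY = FALSE)
  }
  out <- invert_scaling(Yh, object$y_state)
  dimnames(out) <- list(newdata[[1L]]$run_ids, object$y_vars)
  out
}
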