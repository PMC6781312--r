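#' Fit a multi-block PLS path model (MBPLSPM)
#'
#' Wangen-Kowalski alternating least squares for the fixed topology
#' `X1 -> {X3, Y}`, `X2 -> Y`, `X3 -> Y`, with `X3` the interior block
#' (it predicts the response and is itself predicted by `X1`). Per
#' latent variable the algorithm alternates a backward phase (block
#' weights and scores of the predictor side from the current predictee
#' scores) and a forward phase (predictee scores from the predictor
#' scores) until the response score `u_Y` converges:
#'
#' * backward: `w_X2 = X2' u_Y`, `t_X2 = X2 w_X2`; `w_X3 = X3' u_Y`,
#'   `t_X3 = X3 w_X3`; superblock `U = [u_X3, u_Y]` with weight
#'   `c_U = U' t_X1`, score `u_U = U c_U`; `w_X1 = X1' u_U`,
#'   `t_X1 = X1 w_X1` (all weights unit norm);
#' * forward: `c_X3 = X3' t_X1`, `u_X3 = X3 c_X3`; superblock
#'   `T = [t_X1, t_X2, t_X3]` with weight `w_T = T' u_Y`, super score
#'   `t_T = T w_T`; `c_Y = Y' t_T`, `u_Y = Y c_Y`.
#'
#' On convergence, loadings use the block-score update for `X1`
#' (`p_X1 = X1' t_X1 / t_X1' t_X1`) and the super-score update for `X2`
#' and `X3` (`p_X2 = X2' t_T / t_T' t_T`, likewise `p_X3`), plus
#' predictee loadings `q_X3`, `q_Y`. Path coefficients
#' `b_X1U = u_U' t_X1 / t_X1' t_X1` and `b_TY = u_Y' t_T / t_T' t_T`
#' split into the interior-block coefficients
#' `b_X1X3 = c_U[i3] b_X1U` and `b_X3Y = w_T[i3] b_TY` where `i3` indexes
#' the element corresponding to the interior block (see
#' `wk_index_literal`). Residuals: `E_X1 = X1 - t_X1 p_X1'`,
#' `E_X2 = X2 - t_T p_X2'` (the orthogonal super-score deflation the
#' update rule implies), `E_Y = Y - b_TY t_T c_Y'`, and the split
#' deflation `E_X3 = X3 - (s_X3 t_X3 p_X3' + r_X3 u_X3 c_X3')` with
#' `r_X3 = b_X1X3^2 / (b_X1X3^2 + b_X3Y^2)`, `s_X3^2 = 1 - r_X3^2` and
#' `u_X3 = b_X1X3 t_X1`. Subsequent latent variables operate on the
#' residual blocks.
#'
#' Empty blocks (`NULL` or zero columns) are allowed so degenerate
#' topologies reduce exactly to PLS (`X2`, `X3` empty) or MBPLS
#' (`X1` empty, in which case `X3` is a plain predictor).
#'
#' @param x1,x2,x3 Predictor-side [data_block()]s (raw units; autoscaled
#'   internally). `x3` is the interior block when `x1` is present.
#' @param y Response [data_block()].
#' @param n_lvs Number of latent variables.
#' @param tol Relative convergence tolerance on `u_Y`.
#' @param max_iter Maximum backward/forward cycles per latent variable.
#' @param block_scaling `"sqrt_nvars"` (default) or `"none"` (see
#'   [fit_mbpls()]).
#' @param wk_index_literal If `TRUE`, the interior-block path
#'   coefficients use the literal first element of `c_U` and `w_T`; the
#'   default picks the element corresponding to `X3`'s position
#'   (position 1 in `U = [u_X3, u_Y]`, position 3 in
#'   `T = [t_X1, t_X2, t_X3]`).
#' @return Object of class `mbplspm_model`; see Details for the stored
#'   per-LV weights, scores, loadings, path coefficients, residual-split
#'   factors and residual blocks.
#' @seealso [predict_y()], [score_relationship()], [bip()], [vip()]
#' @export
fit_mbplspm <- function(x1, x2, x3, y, n_lvs, tol = 1e-8,
                        max_iter = 500L,
                        block_scaling = c("sqrt_nvars", "none"),
                        wk_index_literal = FALSE) {
  block_scaling <- match.arg(block_scaling)
  present <- function(b) !is.null(b) && ncol(b$values) > 0L
  has <- c(X1 = present(x1), X2 = present(x2), X3 = present(x3))
  if (!any(has)) stop("at least one predictor block is required")
  stopifnot(inherits(y, "data_block"))
  blocks <- list(X1 = x1, X2 = x2, X3 = x3)[has]
  stopifnot_same_runs(c(unname(blocks), list(y)))
  interior <- has[["X1"]] && has[["X3"]]

  scaled <- lapply(blocks, autoscale)
  states <- lapply(scaled, `[[`, "state")
  Xb <- lapply(scaled, function(s) {
    apply_block_scaling(s$block, block_scaling)$values
  })
  sy <- autoscale(y)
  Y <- sy$block$values
  n <- nrow(Y)
  ss0 <- vapply(Xb, function(M) sum(M^2), numeric(1L))
  ssy0 <- sum(Y^2)
  bn <- names(Xb)                      # present blocks, path order
  A <- n_lvs

  Wm <- lapply(Xb, function(M) matrix(0, ncol(M), A,
                                      dimnames = list(colnames(M), NULL)))
  Pm <- Wm
  Tm <- lapply(Xb, function(M) matrix(0, n, A))
  W_T <- matrix(0, length(bn), A, dimnames = list(bn, NULL))
  T_T <- U_Y <- matrix(0, n, A, dimnames = list(y$run_ids, NULL))
  C_Y <- Q_Y <- matrix(0, ncol(Y), A,
                       dimnames = list(y$var_names, NULL))
  b_TY <- numeric(A)
  r2x <- r2y <- numeric(A)
  iters <- integer(A)
  if (interior) {
    C_U <- matrix(0, 2L, A, dimnames = list(c("u_X3", "u_Y"), NULL))
    U_U <- U_X3 <- matrix(0, n, A)
    C_X3 <- Q_X3 <- matrix(0, ncol(Xb$X3), A,
                           dimnames = list(colnames(Xb$X3), NULL))
    b_X1U <- b_X1X3 <- b_X3Y <- r_X3 <- s_X3 <- numeric(A)
  }

  for (a in seq_len(A)) {
    u_Y <- start_column(Y)
    if (interior) u_X3 <- start_column(Xb$X3)
    if (has[["X1"]]) t_X1 <- start_column(Xb$X1)
    it <- 0L
    repeat {
      it <- it + 1L
      if (interior) u_X3_prev <- u_X3
      # --- backward phase: predictor-side weights and scores
      if (has[["X2"]]) {
        w_X2 <- unitize(crossprod(Xb$X2, u_Y))
        t_X2 <- drop(Xb$X2 %*% w_X2)
      }
      if (has[["X3"]]) {
        w_X3 <- unitize(crossprod(Xb$X3, u_Y))
        t_X3 <- drop(Xb$X3 %*% w_X3)
      }
      if (has[["X1"]]) {
        if (interior) {
          Umat <- cbind(u_X3, u_Y)
          c_U <- unitize(crossprod(Umat, t_X1), "superblock-U weight")
          u_U <- drop(Umat %*% c_U)
        } else {
          c_U <- 1
          u_U <- u_Y
        }
        w_X1 <- unitize(crossprod(Xb$X1, u_U))
        t_X1 <- drop(Xb$X1 %*% w_X1)
      }
      # --- forward phase: predictee-side scores
      if (interior) {
        c_X3 <- unitize(crossprod(Xb$X3, t_X1))
        u_X3 <- drop(Xb$X3 %*% c_X3)
      }
      Tmat <- do.call(cbind, mget(paste0("t_", bn)))
      w_T <- unitize(crossprod(Tmat, u_Y), "superblock-T weight")
      t_T <- drop(Tmat %*% w_T)
      c_Y <- unitize(crossprod(Y, t_T), "y weight")
      u_new <- drop(Y %*% c_Y)
      delta <- sqrt(sum((u_new - u_Y)^2)) / max(sqrt(sum(u_Y^2)),
                                                .Machine$double.eps)
      u_Y <- u_new
      # when the interior path is active the u_Y criterion alone can be
      # met before the X1 -> X3 relation settles (e.g. one-column Y),
      # so the interior score must be stationary too
      if (interior) {
        delta <- max(delta, sqrt(sum((u_X3 - u_X3_prev)^2)) /
                       max(sqrt(sum(u_X3_prev^2)),
                           .Machine$double.eps))
      }
      if (delta < tol) break
      if (it >= max_iter) {
        stop("MBPLSPM did not converge for latent variable ", a,
             " (last relative change ", signif(delta, 3), ")")
      }
    }
    # --- sign convention: largest-magnitude element of w_X1 (or of the
    # concatenated present block weights) positive; every sign-coupled
    # vector is flipped together so all bilinear identities survive
    wref <- if (has[["X1"]]) w_X1 else
      unlist(mget(paste0("w_", bn)))
    s <- sign(wref[which.max(abs(wref))]); if (s == 0) s <- 1
    if (s < 0) {
      if (has[["X1"]]) { w_X1 <- -w_X1; t_X1 <- -t_X1; u_U <- -u_U }
      if (has[["X2"]]) { w_X2 <- -w_X2; t_X2 <- -t_X2 }
      if (has[["X3"]]) { w_X3 <- -w_X3; t_X3 <- -t_X3 }
      if (interior) { c_X3 <- -c_X3; u_X3 <- -u_X3 }
      t_T <- -t_T; c_Y <- -c_Y; u_Y <- -u_Y
    }
    tT2 <- sum(t_T^2)
    # --- loadings: block-score update for X1, super-score for X2, X3
    if (has[["X1"]]) p_X1 <- drop(crossprod(Xb$X1, t_X1)) / sum(t_X1^2)
    if (has[["X2"]]) p_X2 <- drop(crossprod(Xb$X2, t_T)) / tT2
    if (has[["X3"]]) p_X3 <- drop(crossprod(Xb$X3, t_T)) / tT2
    if (interior) {
      q_X3 <- drop(crossprod(Xb$X3, u_X3)) / sum(u_X3^2)
    }
    q_Y <- drop(crossprod(Y, u_Y)) / sum(u_Y^2)
    # --- path coefficients
    bty <- drop(crossprod(u_Y, t_T)) / tT2
    if (interior) {
      b1u <- drop(crossprod(u_U, t_X1)) / sum(t_X1^2)
      i_u <- if (wk_index_literal) 1L else match("X3", c("X3", "Y"))
      i_t <- if (wk_index_literal) 1L else match("X3", bn)
      b13 <- c_U[i_u] * b1u / sum(c_U^2)
      b3y <- w_T[i_t] * bty / sum(w_T^2)
      r3 <- b13^2 / (b13^2 + b3y^2)
      s3 <- sqrt(1 - r3^2)
    }
    # --- residuals / deflation
    if (has[["X1"]]) Xb$X1 <- Xb$X1 - tcrossprod(t_X1, p_X1)
    if (has[["X2"]]) Xb$X2 <- Xb$X2 - tcrossprod(t_T, p_X2)
    if (has[["X3"]]) {
      if (interior) {
        u_hat <- b13 * t_X1
        Xb$X3 <- Xb$X3 - (s3 * tcrossprod(t_X3, p_X3) +
                            r3 * tcrossprod(u_hat, c_X3))
      } else {
        Xb$X3 <- Xb$X3 - tcrossprod(t_T, p_X3)
      }
    }
    Y <- Y - bty * tcrossprod(t_T, c_Y)
    # --- store
    for (b in bn) {
      Wm[[b]][, a] <- get(paste0("w_", b))
      Pm[[b]][, a] <- get(paste0("p_", b))
      Tm[[b]][, a] <- get(paste0("t_", b))
    }
    W_T[, a] <- w_T; T_T[, a] <- t_T
    C_Y[, a] <- c_Y; U_Y[, a] <- u_Y; Q_Y[, a] <- q_Y
    b_TY[a] <- bty
    if (interior) {
      C_U[, a] <- c_U; U_U[, a] <- u_U
      C_X3[, a] <- c_X3; U_X3[, a] <- u_X3; Q_X3[, a] <- q_X3
      b_X1U[a] <- b1u; b_X1X3[a] <- b13; b_X3Y[a] <- b3y
      r_X3[a] <- r3; s_X3[a] <- s3
    }
    iters[a] <- it
    r2x[a] <- 100 * (1 - sum(vapply(Xb, function(M) sum(M^2),
                                    numeric(1L))) / sum(ss0))
    r2y[a] <- 100 * (1 - sum(Y^2) / ssy0)
  }

  out <- list(W = Wm, P = Pm, T_b = Tm, W_T = W_T, T_T = T_T,
              C_Y = C_Y, U_Y = U_Y, Q_Y = Q_Y, b_TY = b_TY,
              E = Xb, E_Y = Y,
              r2x_cum = r2x, r2y_cum = r2y,
              r2y_per_lv = diff(c(0, r2y)),
              n_lvs = A, iterations = iters,
              blocks_present = has, interior = interior,
              block_names = bn,
              x_states = states, y_state = sy$state,
              block_scaling = block_scaling,
              wk_index_literal = wk_index_literal,
              x_vars = lapply(blocks, `[[`, "var_names"),
              y_vars = y$var_names)
  if (interior) {
    out <- c(out, list(C_U = C_U, U_U = U_U, C_X3 = C_X3, U_X3 = U_X3,
                       Q_X3 = Q_X3, b_X1U = b_X1U, b_X1X3 = b_X1X3,
                       b_X3Y = b_X3Y, r_X3 = r_X3, s_X3 = s_X3))
  }
  structure(out, class = "mbplspm_model")
}

#' @export
print.mbplspm_model <- function(x, ...) {
  cat(sprintf("<mbplspm_model> %d LVs, blocks: %s%s\n", x$n_lvs,
              paste(x$block_names, collapse = ", "),
              if (x$interior) " (X3 interior)" else ""))
  cat(sprintf("  R2X_cum = %.1f%%, R2Y_cum = %.1f%%, iterations: %s\n",
              x$r2x_cum[x$n_lvs], x$r2y_cum[x$n_lvs],
              paste(x$iterations, collapse = "/")))
  invisible(x)
}

#' Predict responses from a fitted path model
#'
#' Projects new runs through the fitted per-LV weights, accumulating the
#' response prediction `b_TY t_T c_Y'` and deflating each block exactly
#' as during fitting, then maps back to original response units.
#' Predicting the training blocks reproduces `Y - E_Y`.
#'
#' @param model An `mbplspm_model`.
#' @param x1,x2,x3 New predictor blocks (original units; the blocks
#'   absent at fit time must be absent here).
#' @return Matrix of predictions on original response units.
#' @export
predict_y <- function(model, x1 = NULL, x2 = NULL, x3 = NULL) {
  stopifnot(inherits(model, "mbplspm_model"))
  present <- function(b) !is.null(b) && ncol(b$values) > 0L
  newb <- list(X1 = x1, X2 = x2, X3 = x3)
  hasnew <- vapply(newb, present, logical(1L))
  if (!identical(unname(hasnew), unname(model$blocks_present))) {
    stop("new blocks must match the blocks present at fit time")
  }
  newb <- newb[hasnew]
  for (b in names(newb)) {
    if (!identical(newb[[b]]$var_names, model$x_vars[[b]])) {
      stop("variables of block ", b, " do not match training")
    }
  }
  Xb <- mapply(function(blk, st) {
    apply_block_scaling(autoscale(blk, state = st)$block,
                        model$block_scaling)$values
  }, newb, model$x_states, SIMPLIFY = FALSE)
  n <- nrow(Xb[[1L]])
  Yh <- matrix(0, n, length(model$y_vars))
  bn <- model$block_names
  for (a in seq_len(model$n_lvs)) {
    tb <- lapply(bn, function(b) drop(Xb[[b]] %*% model$W[[b]][, a]))
    names(tb) <- bn
    t_T <- drop(do.call(cbind, tb) %*% model$W_T[, a])
    Yh <- Yh + model$b_TY[a] * tcrossprod(t_T, model$C_Y[, a])
    if ("X1" %in% bn) {
      Xb$X1 <- Xb$X1 - tcrossprod(tb$X1, model$P$X1[, a])
    }
    if ("X2" %in% bn) {
      Xb$X2 <- Xb$X2 - tcrossprod(t_T, model$P$X2[, a])
    }
    if ("X3" %in% bn) {
      if (model$interior) {
        u_hat <- model$b_X1X3[a] * tb$X1
        Xb$X3 <- Xb$X3 -
          (model$s_X3[a] * tcrossprod(tb$X3, model$P$X3[, a]) +
             model$r_X3[a] * tcrossprod(u_hat, model$C_X3[, a]))
      } else {
        Xb$X3 <- Xb$X3 - tcrossprod(t_T, model$P$X3[, a])
      }
    }
  }
  out <- invert_scaling(Yh, model$y_state)
  dimnames(out) <- list(newb[[1L]]$run_ids, model$y_vars)
  out
}

#' Super-score versus response-score relationship
#'
#' Returns, per latent variable, the paired super score `t_T` and
#' response score `u_Y` together with their correlation. A strong,
#' declining correlation over successive latent variables indicates the
#' leading components carry most of the predictive structure. By the
#' fixed-point construction the correlation is non-negative.
#'
#' @param model An `mbplspm_model`.
#' @return Data frame with one row per LV (`lv`, `correlation`) and the
#'   score pairs as a list attribute `"pairs"`.
#' @export
score_relationship <- function(model) {
  stopifnot(inherits(model, "mbplspm_model"))
  pairs <- lapply(seq_len(model$n_lvs), function(a) {
    cbind(t_T = model$T_T[, a], u_Y = model$U_Y[, a])
  })
  corr <- vapply(pairs, function(p) stats::cor(p[, 1L], p[, 2L]),
                 numeric(1L))
  out <- data.frame(lv = seq_len(model$n_lvs), correlation = corr)
  attr(out, "pairs") <- pairs
  out
}
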