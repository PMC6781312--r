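#' Variance inflation factors within a data block
#'
#' `VIF_i = 1 / (1 - r_i^2)` where `r_i^2` is the coefficient of
#' determination of the ordinary least-squares regression of variable
#' `i` on all remaining variables of the same block (with intercept).
#' Values near 1 indicate orthogonal variables; values above ~10 signal
#' collinearity strong enough to rule out plain multiple regression.
#' The statistic is invariant under affine rescaling of any column.
#'
#' @param block A [data_block()] with at least two variables and more
#'   runs than variables.
#' @return Named numeric vector of VIFs (one per variable). Perfectly
#'   collinear variables yield `Inf` with a warning.
#' @export
#'
#' @examples
#' b <- data_block(matrix(rnorm(60), 20, 3), "toy")
#' vif(b)
vif <- function(block) {
  stopifnot(inherits(block, "data_block"))
  X <- block$values
  p <- ncol(X)
  if (p < 2L) stop("VIF needs at least two variables in the block")
  if (nrow(X) <= p) {
    stop("VIF needs more runs than variables for an exact regression")
  }
  out <- vapply(seq_len(p), function(i) {
    yi <- X[, i]
    Z <- cbind(1, X[, -i, drop = FALSE])
    fit <- stats::lm.fit(Z, yi)
    tss <- sum((yi - mean(yi))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) {
      warning("variable '", block$var_names[i],
              "' is perfectly collinear with the rest of block '",
              block$name, "'")
      return(Inf)
    }
    1 / (1 - r2)
  }, numeric(1L))
  names(out) <- block$var_names
  out
}

#' Block importance in the projection (BIP)
#'
#' Ranks the blocks of a fitted path model by how much they carry the
#' latent variables that explain the response:
#' `BIP_i = sqrt( m * sum_k R2_{Y,k} w_{i,k}^2 / sum_k R2_{Y,k} )`,
#' where `m` is the number of predictor blocks, `R2_{Y,k}` the response
#' variance explained by latent variable `k` and `w_{i,k}` the
#' superblock-level weight of block `i` on latent variable `k` (unit
#' norm across blocks per LV, so `sum(BIP^2) = m`). Blocks with
#' `BIP > 1` are the critical process units.
#'
#' @param model A fitted [fit_mbplspm()] model (an [fit_mbpls()] model
#'   also works, via its super-level weights).
#' @param squared If `TRUE` return the index without the square root
#'   (the literal rendering of the printed formula; the threshold-1
#'   criticality convention assumes the square-root form).
#' @return Named numeric vector of BIP values per block.
#' @export
bip <- function(model, squared = FALSE) {
  if (inherits(model, "mbplspm_model")) {
    Wsup <- model$W_T
    r2k <- model$r2y_per_lv
  } else if (inherits(model, "mbpls_model")) {
    Wsup <- model$W_s
    r2k <- diff(c(0, model$r2y_cum))
  } else {
    stop("`model` must be an mbplspm_model or mbpls_model")
  }
  tot <- sum(r2k)
  if (tot <= 0) stop("model explains no response variance")
  m <- nrow(Wsup)
  val <- m * drop(Wsup^2 %*% r2k) / tot
  if (!squared) val <- sqrt(val)
  names(val) <- rownames(Wsup)
  val
}

#' Variable importance in the projection (VIP)
#'
#' `VIP_i = sqrt( n * sum_k R2_{Y,k} w_{i,k}^2 / sum_k R2_{Y,k} )` over
#' all predictor variables, where `n` is the total predictor-variable
#' count and `w_{.,k}` is the concatenation of the per-block weight
#' vectors of latent variable `k`, renormalized to unit norm (so
#' `sum(VIP^2) = n`). Variables with `VIP > 1` are the critical
#' material attributes / process parameters.
#'
#' @inheritParams bip
#' @return Named numeric vector of VIP values over all predictor
#'   variables, in block order.
#' @export
vip <- function(model, squared = FALSE) {
  if (inherits(model, "mbplspm_model")) {
    Wlist <- model$W
    r2k <- model$r2y_per_lv
  } else if (inherits(model, "mbpls_model")) {
    Wlist <- model$W_b
    r2k <- diff(c(0, model$r2y_cum))
  } else {
    stop("`model` must be an mbplspm_model or mbpls_model")
  }
  tot <- sum(r2k)
  if (tot <= 0) stop("model explains no response variance")
  Wcat <- do.call(rbind, Wlist)
  Wcat <- apply(Wcat, 2L, function(w) w / sqrt(sum(w^2)))
  n <- nrow(Wcat)
  val <- n * drop(Wcat^2 %*% r2k) / tot
  if (!squared) val <- sqrt(val)
  names(val) <- unlist(lapply(Wlist, rownames), use.names = FALSE)
  val
}

#' Criticality calls at the threshold-1 convention
#'
#' Computes [bip()] and [vip()] for a fitted path model and flags the
#' blocks and variables whose index exceeds 1.
#'
#' @param model A fitted [fit_mbplspm()] (or [fit_mbpls()]) model.
#' @param threshold Criticality threshold (the standard convention
#'   is exactly 1).
#' @return Object of class `diagnostics_report`: list with `bip`,
#'   `vip`, `critical_blocks`, `critical_vars`, `threshold`.
#' @export
criticality <- function(model, threshold = 1) {
  b <- bip(model)
  v <- vip(model)
  structure(list(bip = b, vip = v,
                 critical_blocks = names(b)[b > threshold],
                 critical_vars = names(v)[v > threshold],
                 threshold = threshold),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report> threshold =", x$threshold, "\n")
  cat("BIP:\n"); print(round(x$bip, 3))
  cat("critical blocks:",
      paste(x$critical_blocks, collapse = ", "), "\n")
  cat("critical variables:",
      paste(x$critical_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Compare PLS, MBPLS and MBPLSPM fits on the same data
#'
#' Fits the three model kinds at a common number of latent variables and
#' reports training `R2X`/`R2Y` plus leave-one-out `Q2` for each: PLS on
#' the column-concatenation of all predictor blocks, MBPLS on the blocks
#' as given, and MBPLSPM on the path topology (with `x3` interior).
#'
#' @param x1,x2,x3 Predictor blocks as in [fit_mbplspm()].
#' @param y Response [data_block()].
#' @param n_lvs Number of latent variables (common to all models).
#' @param cv If `FALSE`, skip cross-validation (`q2y_cum = NA`).
#' @return Data frame with one row per model kind and columns `model`,
#'   `n_lvs`, `r2x_cum`, `r2y_cum`, `q2y_cum` (percent).
#' @export
compare_models <- function(x1, x2, x3, y, n_lvs, cv = TRUE) {
  present <- Filter(function(b) !is.null(b) && ncol(b$values) > 0L,
                    list(x1, x2, x3))
  xcat <- concat_blocks(present, name = "X")
  rows <- list()
  if (cv) {
    rows$pls <- loo_q2(xcat, y, n_lvs, model = "pls")
    rows$mbpls <- loo_q2(present, y, n_lvs, model = "mbpls")
    rows$mbplspm <- loo_q2(list(X1 = x1, X2 = x2, X3 = x3), y, n_lvs,
                           model = "mbplspm")
  } else {
    f1 <- fit_pls(xcat, y, n_lvs)
    f2 <- fit_mbpls(present, y, n_lvs)
    f3 <- fit_mbplspm(x1, x2, x3, y, n_lvs)
    rows <- list(
      pls = list(model = "pls", r2x_cum = f1$r2x_cum[n_lvs],
                 r2y_cum = f1$r2y_cum[n_lvs], q2y_cum = NA_real_,
                 n_lvs = n_lvs),
      mbpls = list(model = "mbpls", r2x_cum = f2$r2x_cum[n_lvs],
                   r2y_cum = f2$r2y_cum[n_lvs], q2y_cum = NA_real_,
                   n_lvs = n_lvs),
      mbplspm = list(model = "mbplspm", r2x_cum = f3$r2x_cum[n_lvs],
                     r2y_cum = f3$r2y_cum[n_lvs], q2y_cum = NA_real_,
                     n_lvs = n_lvs))
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(model = r$model, n_lvs = r$n_lvs,
               r2x_cum = r$r2x_cum, r2y_cum = r$r2y_cum,
               q2y_cum = r$q2y_cum)
  }))
  rownames(tab) <- NULL
  bad <- !is.na(tab$q2y_cum) & tab$q2y_cum > tab$r2y_cum + 5
  if (any(bad)) {
    warning("Q2Y exceeds R2Y by more than 5 points for: ",
            paste(tab$model[bad], collapse = ", "))
  }
  tab
}
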