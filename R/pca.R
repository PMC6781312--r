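#' Principal component analysis of a data block
#'
#' Deterministic PCA by singular value decomposition of the autoscaled
#' matrix. Eigenvalues are the squared singular values divided by
#' `n - 1`, i.e. the variances of the score columns; on autoscaled data
#' they sum to the number of variables. Each loading column's sign is
#' fixed so its largest-magnitude element is positive.
#'
#' @param block An autoscaled [data_block()] (see [autoscale()]).
#' @param max_components Number of components to retain,
#'   at most `min(n_runs - 1, n_vars)`. Requests beyond the numerical
#'   rank are truncated with a warning.
#'
#' @return Object of class `pca_model` with elements `scores`
#'   (`n_runs x A`), `loadings` (`n_vars x A`, orthonormal columns),
#'   `eigenvalues` (all `min(n-1, p)` of them), `r2_per_pc` and `r2_cum`
#'   (percent of total variance), `n_components_selected` (by the
#'   eigenvalue-greater-than-one rule), `n_runs`, `n_vars`.
#' @export
fit_pca <- function(block, max_components = NULL) {
  stopifnot(inherits(block, "data_block"))
  X <- block$values
  n <- nrow(X); p <- ncol(X)
  a_max <- min(n - 1L, p)
  if (is.null(max_components)) max_components <- a_max
  if (max_components > a_max) {
    stop("max_components must be <= min(n_runs - 1, n_vars) = ", a_max)
  }
  sv <- svd(X)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L])
  A <- max_components
  if (A > rank) {
    warning("requested ", A, " components but rank is ", rank,
            "; truncating")
    A <- rank
  }
  P <- sv$v[, seq_len(A), drop = FALSE]
  # sign convention: largest-magnitude loading element positive
  flip <- vapply(seq_len(A), function(a) {
    sign(P[which.max(abs(P[, a])), a])
  }, numeric(1L))
  P <- sweep(P, 2L, flip, "*")
  Tm <- X %*% P
  rownames(P) <- block$var_names
  rownames(Tm) <- block$run_ids
  colnames(P) <- colnames(Tm) <- paste0("PC", seq_len(A))
  eig_a <- eig[seq_len(a_max)]
  r2 <- 100 * eig_a / sum(eig)
  structure(list(scores = Tm, loadings = P, eigenvalues = eig_a,
                 r2_per_pc = r2, r2_cum = cumsum(r2),
                 n_components_selected = select_n_pcs(eig_a),
                 n_runs = n, n_vars = p, block_name = block$name),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model on '%s'> %d runs x %d variables\n",
              x$block_name, x$n_runs, x$n_vars))
  k <- min(length(x$eigenvalues), 10L)
  tab <- data.frame(PC = seq_len(k),
                    eigenvalue = round(x$eigenvalues[seq_len(k)], 3),
                    r2_pct = round(x$r2_per_pc[seq_len(k)], 1),
                    r2_cum_pct = round(x$r2_cum[seq_len(k)], 1))
  print(tab, row.names = FALSE)
  cat("selected (eigenvalue > 1):", x$n_components_selected, "PCs\n")
  invisible(x)
}

#' Eigenvalue-greater-than-one component selection
#'
#' On autoscaled data each original variable carries unit variance, so a
#' component with eigenvalue above one explains more than a single
#' variable does; components up to that point are retained.
#'
#' @param eigenvalues Non-increasing numeric vector of eigenvalues.
#' @return Integer count of eigenvalues strictly greater than 1.
#' @export
#'
#' @examples
#' select_n_pcs(c(5.65, 1.78, 0.967))  # 2
select_n_pcs <- function(eigenvalues) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue vector")
  if (is.unsorted(rev(eigenvalues) - 1e-12)) {
    stop("eigenvalues must be non-increasing")
  }
  sum(eigenvalues > 1)
}

#' Hotelling T-squared confidence limit
#'
#' F-based control limit for the T-squared of a new observation in an
#' `A`-component score space:
#' `A (n-1)(n+1) / (n (n-A)) * qf(confidence, A, n - A)`.
#'
#' @param n_runs Number of training runs `n`.
#' @param n_components Number of components `A` (with `n > A >= 1`).
#' @param confidence Confidence level in (0, 1), e.g. 0.95 for outlier
#'   screening or 0.99 for score-plot ellipses.
#' @return Positive scalar limit.
#' @export
hotelling_t2_limit <- function(n_runs, n_components, confidence = 0.95) {
  n <- n_runs; A <- n_components
  stopifnot(A >= 1L, confidence > 0, confidence < 1)
  if (n <= A) stop("n_runs must exceed n_components")
  A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(confidence, A, n - A)
}

#' Per-run Hotelling T-squared scores
#'
#' T-squared of each run in the first `n_components` score dimensions,
#' i.e. the sum over components of squared score divided by the
#' component eigenvalue.
#'
#' @param model A [fit_pca()] model.
#' @param n_components Number of leading components to use.
#' @return Numeric vector, one non-negative value per run.
#' @export
t2_scores <- function(model, n_components) {
  stopifnot(inherits(model, "pca_model"))
  A <- n_components
  if (A > ncol(model$scores)) {
    stop("n_components exceeds the number of fitted components")
  }
  lam <- model$eigenvalues[seq_len(A)]
  if (any(lam <= .Machine$double.eps)) {
    stop("zero eigenvalue among the first ", A, " components")
  }
  T2 <- model$scores[, seq_len(A), drop = FALSE]^2
  drop(T2 %*% (1 / lam))
}

#' Screen a set of blocks for outlying runs
#'
#' Concatenates the given blocks, autoscales, fits a PCA and flags runs
#' whose Hotelling T-squared exceeds the F-based limit. This is the
#' pre-modeling outlier screen applied to all available data jointly.
#'
#' @param blocks List of [data_block()]s sharing runs.
#' @param n_components Components used for the screen (default: the
#'   eigenvalue-greater-than-one count).
#' @param confidence Confidence level of the limit (default 0.95).
#' @return A list with `t2` (per-run values), `limit`, `outliers`
#'   (run ids beyond the limit), `pca` (the fitted model).
#' @export
screen_outliers <- function(blocks, n_components = NULL,
                            confidence = 0.95) {
  joint <- concat_blocks(blocks, name = "all")
  sc <- autoscale(joint)
  pc <- fit_pca(sc$block)
  A <- if (is.null(n_components)) pc$n_components_selected else n_components
  A <- max(1L, min(A, ncol(pc$scores)))
  t2 <- t2_scores(pc, A)
  lim <- hotelling_t2_limit(nrow(joint$values), A, confidence)
  list(t2 = t2, limit = lim,
       outliers = joint$run_ids[t2 > lim], n_components = A, pca = pc)
}
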