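#' Build a response-surface term expansion
#'
#' Terms are given in a small language: a bare factor name for a linear
#' term (`"C"`), `"A*B"` for a two-factor interaction, `"G^2"` for a
#' squared term.
#'
#' @param terms Character vector of term descriptors.
#' @param data Data frame or matrix with the factor columns.
#' @return Numeric model matrix (no intercept column), one column per
#'   term, named as the descriptors.
#' @keywords internal
expand_terms <- function(terms, data) {
  data <- as.data.frame(data)
  cols <- lapply(terms, function(tm) {
    if (grepl("\\*", tm)) {
      f <- trimws(strsplit(tm, "\\*")[[1L]])
      stopifnot(length(f) == 2L)
      data[[f[1L]]] * data[[f[2L]]]
    } else if (grepl("\\^2$", tm)) {
      f <- trimws(sub("\\^2$", "", tm))
      data[[f]]^2
    } else {
      v <- data[[trimws(tm)]]
      if (is.null(v)) stop("unknown factor in term: ", tm)
      v
    }
  })
  bad <- vapply(cols, is.null, logical(1L))
  if (any(bad)) stop("unknown factor(s) in terms: ",
                     paste(terms[bad], collapse = ", "))
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

#' Fit a response-surface model by ordinary least squares
#'
#' Regresses one critical quality attribute on an expansion of process
#' factors (linear, interaction and quadratic terms) and reports the
#' coefficient of determination, its adjusted version and the overall-F
#' analysis-of-variance p-value.
#'
#' @param design [data_block()] or data frame holding the factor
#'   settings per run.
#' @param response Numeric vector of the measured attribute, one value
#'   per run.
#' @param terms Character vector of term descriptors (see
#'   [expand_terms()]).
#' @param response_name Label for the response.
#' @return Object of class `response_surface`: `terms`, `coefficients`
#'   (intercept first), `r2`, `r2_adj`, `anova_p`, `fitted`,
#'   `residuals`.
#' @export
fit_response_surface <- function(design, response, terms,
                                 response_name = "response") {
  df <- if (inherits(design, "data_block")) {
    as.data.frame(design$values)
  } else {
    as.data.frame(design)
  }
  y <- as.numeric(response)
  stopifnot(length(y) == nrow(df))
  M <- expand_terms(terms, df)
  if (nrow(M) <= ncol(M) + 1L) {
    stop("need more runs than terms (plus intercept) for OLS")
  }
  qrM <- qr(cbind(1, M))
  if (qrM$rank < ncol(M) + 1L) {
    aliased <- colnames(M)[qrM$pivot[-seq_len(qrM$rank)] - 1L]
    stop("rank-deficient term expansion; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = data.frame(M, check.names = FALSE))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", terms)
  structure(list(response = response_name, terms = terms,
                 coefficients = cf, r2 = sm$r.squared,
                 r2_adj = sm$adj.r.squared, anova_p = unname(p),
                 sigma = sm$sigma,
                 std_errors = stats::setNames(sm$coefficients[, 2L],
                                              names(cf)),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit)),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface '%s'> R2 = %.3f, R2_adj = %.3f, ANOVA p = %.3g\n",
              x$response, x$r2, x$r2_adj, x$anova_p))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Evaluate a response-surface model at new factor settings
#'
#' @param object A `response_surface`.
#' @param newdata Data frame (or matrix) with the factor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.response_surface <- function(object, newdata, ...) {
  M <- expand_terms(object$terms, newdata)
  drop(cbind(1, M) %*% object$coefficients)
}

# The published case-study response surfaces: tablet tensile strength
# (TS, MPa) and disintegration time (DT, min) as functions of binder
# amount (%), lubrication time (min) and minimal punch tip separation
# distance (mm). Coefficients are packaged verbatim.
printed_model_coefs <- function() {
  list(
    TS = c("(Intercept)" = 31.086, binder = -0.292, lubrication = -0.065,
           distance = -6.333),
    DT = c("(Intercept)" = 584.813, binder = 0.885, lubrication = 0.540,
           distance = -376.339, "binder*lubrication" = -0.023,
           "distance^2" = 58.911)
  )
}

#' The packaged case-study response-surface models
#'
#' Returns the published tensile-strength and disintegration-time
#' regression models as `response_surface` objects with their exact
#' coefficients (TS in MPa; DT in minutes; factors: binder amount in %,
#' lubrication time in min, minimal punch tip separation distance in
#' mm).
#'
#' @return Named list of two `response_surface` objects, `TS` and `DT`.
#' @export
printed_models <- function() {
  cf <- printed_model_coefs()
  mk <- function(name, coefs) {
    structure(list(response = name, terms = names(coefs)[-1L],
                   coefficients = coefs, r2 = NA_real_,
                   r2_adj = NA_real_, anova_p = NA_real_),
              class = "response_surface")
  }
  list(TS = mk("TS", cf$TS), DT = mk("DT", cf$DT))
}

#' Evaluate the packaged case-study models at one operating point
#'
#' Exact arithmetic on the packaged tensile-strength and
#' disintegration-time coefficients. A warning is issued when a setting
#' lies outside the designed factor ranges (binder 20-24%, lubrication
#' 10-20 min, distance 3.0-3.2 mm).
#'
#' @param binder_pct Binder amount, percent.
#' @param lube_min Lubrication time, minutes.
#' @param distance_mm Minimal punch tip separation distance, mm.
#' @return Named numeric vector `c(TS = ..., DT = ...)` (MPa, minutes);
#'   vectorized over the inputs.
#' @export
#'
#' @examples
#' evaluate_printed_models(22, 15, 3.15)
evaluate_printed_models <- function(binder_pct, lube_min, distance_mm) {
  lo <- c(20, 10, 3.0); hi <- c(24, 20, 3.2)
  vals <- cbind(binder_pct, lube_min, distance_mm)
  out_of_range <- sweep(vals, 2L, lo, "<") | sweep(vals, 2L, hi, ">")
  if (any(out_of_range)) {
    warning("settings outside the designed factor ranges")
  }
  nd <- data.frame(binder = binder_pct, lubrication = lube_min,
                   distance = distance_mm)
  pm <- printed_models()
  ts <- predict(pm$TS, nd)
  dt <- predict(pm$DT, nd)
  if (length(ts) == 1L) c(TS = ts, DT = dt) else cbind(TS = ts, DT = dt)
}

#' Bounds on a critical quality attribute
#'
#' @param response Response name (must match a fitted model's name).
#' @param lower,upper Bounds; at least one must be finite, and
#'   `lower < upper` when both are given.
#' @param units Optional unit label.
#' @return Object of class `cqa_spec`.
#' @export
cqa_spec <- function(response, lower = -Inf, upper = Inf, units = "") {
  if (!is.finite(lower) && !is.finite(upper)) {
    stop("at least one bound must be finite")
  }
  if (lower >= upper) stop("lower bound must be below upper bound")
  structure(list(response = response, lower = lower, upper = upper,
                 units = units), class = "cqa_spec")
}

#' Default factor grids for the case-study design space
#'
#' Covers the designed ranges (binder 20-24%, lubrication 10-20 min,
#' distance 3.0-3.2 mm) at steps fine enough to resolve the published
#' 0.1-mm distance extent: 0.1%, 0.5 min and 0.005 mm.
#'
#' @return Named list of data frames with `min`, `max`, `step`.
#' @export
default_grids <- function() {
  list(binder = list(min = 20, max = 24, step = 0.1),
       lubrication = list(min = 10, max = 20, step = 0.5),
       distance = list(min = 3.0, max = 3.2, step = 0.005))
}

#' Overlapped feasible region across several quality attributes
#'
#' Evaluates each response-surface model on the full factorial grid of
#' factor settings, masks the grid points satisfying each attribute's
#' bounds, and intersects the per-attribute masks into the combined
#' (overlapped) design space. The bounding range of each factor over
#' the combined region is also reported.
#'
#' @param models Named list of `response_surface` models, one per
#'   attribute.
#' @param cqas List of [cqa_spec()]s; every spec must have a model of
#'   the same name.
#' @param grids Named list of `list(min, max, step)` per factor
#'   (default [default_grids()]).
#' @return Object of class `feasible_region`: `grid` (data frame of all
#'   grid points), `predictions` (matrix, one column per attribute),
#'   `mask_per_cqa` (logical matrix), `mask` (combined), `bounds`
#'   (per-factor range of the combined region), `grids`.
#' @export
feasible_region <- function(models, cqas, grids = default_grids()) {
  stopifnot(length(cqas) >= 1L)
  axes <- lapply(grids, function(g) seq(g$min, g$max, by = g$step))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  resp <- vapply(cqas, `[[`, character(1L), "response")
  if (!all(resp %in% names(models))) {
    stop("no model for attribute(s): ",
         paste(setdiff(resp, names(models)), collapse = ", "))
  }
  preds <- vapply(resp, function(r) predict(models[[r]], grid),
                  numeric(nrow(grid)))
  colnames(preds) <- resp
  mask_per <- vapply(seq_along(cqas), function(i) {
    preds[, i] >= cqas[[i]]$lower & preds[, i] <= cqas[[i]]$upper
  }, logical(nrow(grid)))
  colnames(mask_per) <- resp
  mask <- rowSums(mask_per) == length(cqas)
  if (!any(mask)) {
    warning("combined feasible region is empty")
    bounds <- lapply(grids, function(g) c(min = NA_real_,
                                          max = NA_real_))
  } else {
    bounds <- lapply(names(grids), function(f) {
      c(min = min(grid[mask, f]), max = max(grid[mask, f]))
    })
    names(bounds) <- names(grids)
  }
  structure(list(grid = grid, predictions = preds,
                 mask_per_cqa = mask_per, mask = mask,
                 bounds = bounds, grids = grids, cqas = cqas,
                 models = models[resp]),
            class = "feasible_region")
}

#' @export
print.feasible_region <- function(x, ...) {
  cat(sprintf("<feasible_region> %d of %d grid points feasible\n",
              sum(x$mask), length(x$mask)))
  for (f in names(x$bounds)) {
    cat(sprintf("  %s: [%s, %s]\n", f, format(x$bounds[[f]]["min"]),
                format(x$bounds[[f]]["max"])))
  }
  invisible(x)
}

#' Membership test for a feasible region
#'
#' Checks whether an operating point satisfies every attribute bound
#' under the region's models (evaluated exactly, not snapped to the
#' grid).
#'
#' @param region A [feasible_region()].
#' @param point Named list or vector of factor settings.
#' @return Logical scalar.
#' @export
in_region <- function(region, point) {
  nd <- as.data.frame(as.list(point))
  all(vapply(seq_along(region$cqas), function(i) {
    cq <- region$cqas[[i]]
    pr <- predict(region$models[[cq$response]], nd)
    pr >= cq$lower && pr <= cq$upper
  }, logical(1L)))
}

#' Gridded prediction surface for contour plotting
#'
#' Evaluates a response-surface model over a two-factor grid with the
#' remaining factors held fixed, returning the prediction matrix and
#' contour polylines ready for CSV export.
#'
#' @param model A `response_surface`.
#' @param fixed Named list of the fixed factor settings.
#' @param axes Character vector of exactly two free factor names.
#' @param grids Named list of `list(min, max, step)` for the two axes.
#' @param levels Contour levels (default: pretty levels over the
#'   surface range).
#' @return List with `x`, `y` (axis vectors), `z` (prediction matrix,
#'   rows follow `x`), `contours` (data frame `level`, `piece`, `x`,
#'   `y`).
#' @export
export_contours <- function(model, fixed, axes, grids = default_grids(),
                            levels = NULL) {
  if (length(axes) != 2L) stop("exactly two free axes are required")
  gx <- grids[[axes[1L]]]; gy <- grids[[axes[2L]]]
  xs <- seq(gx$min, gx$max, by = gx$step)
  ys <- seq(gy$min, gy$max, by = gy$step)
  grid <- expand.grid(xs, ys, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- axes
  for (f in names(fixed)) grid[[f]] <- fixed[[f]]
  z <- matrix(predict(model, grid), nrow = length(xs))
  if (is.null(levels)) levels <- pretty(range(z), 10L)
  cl <- grDevices::contourLines(xs, ys, z, levels = levels)
  contours <- if (length(cl)) {
    do.call(rbind, lapply(seq_along(cl), function(i) {
      data.frame(level = cl[[i]]$level, piece = i,
                 x = cl[[i]]$x, y = cl[[i]]$y)
    }))
  } else {
    data.frame(level = numeric(0), piece = integer(0),
               x = numeric(0), y = numeric(0))
  }
  list(x = xs, y = ys, z = z, contours = contours, axes = axes,
       fixed = fixed)
}
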