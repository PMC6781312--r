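#' Create a data block
#'
#' A data block is a named numeric matrix (runs in rows, variables in
#' columns) tagged with its role in the process path. Blocks belonging to
#' one analysis must share identical run identifiers in identical order.
#'
#' @param values Numeric matrix or data frame, `n_runs x n_vars`. Missing
#'   values are an error: measurements must be complete before modeling.
#' @param name Block identifier (e.g. `"P1"`, `"X2"`).
#' @param role Role of the block in the path topology: `"predictor"`
#'   (only predicts), `"interior"` (predicts and is predicted) or
#'   `"predictee"` (only predicted).
#' @param var_names Variable names; defaults to `colnames(values)`.
#' @param run_ids Run identifiers; defaults to `rownames(values)` or
#'   `1..n_runs`.
#'
#' @return An object of class `data_block`: a list with elements `name`,
#'   `role`, `values`, `var_names`, `run_ids`.
#' @export
#'
#' @examples
#' blk <- data_block(matrix(rnorm(20), 10, 2,
#'                          dimnames = list(NULL, c("a", "b"))), "demo")
#' dim(blk)
data_block <- function(values, name, role = c("predictor", "interior",
                                              "predictee"),
                       var_names = NULL, run_ids = NULL) {
  role <- match.arg(role)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (runs x variables)")
  }
  if (nrow(values) < 2L) stop("a data block needs at least 2 runs")
  if (is.null(var_names)) var_names <- colnames(values)
  if (is.null(var_names) && ncol(values) > 0L) {
    var_names <- paste0("v", seq_len(ncol(values)))
  }
  var_names <- as.character(var_names)
  if (length(var_names) != ncol(values)) {
    stop("`var_names` length must equal ncol(values)")
  }
  if (anyDuplicated(var_names)) {
    stop("duplicate variable names in block '", name, "': ",
         paste(unique(var_names[duplicated(var_names)]), collapse = ", "))
  }
  if (is.null(run_ids)) run_ids <- rownames(values)
  if (is.null(run_ids)) run_ids <- as.character(seq_len(nrow(values)))
  run_ids <- as.character(run_ids)
  if (length(run_ids) != nrow(values)) {
    stop("`run_ids` length must equal nrow(values)")
  }
  if (anyDuplicated(run_ids)) stop("duplicate run_ids in block '", name, "'")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value in block '", name, "' at run '",
         run_ids[idx[1L]], "', variable '", var_names[idx[2L]], "'")
  }
  dimnames(values) <- list(run_ids, var_names)
  structure(list(name = as.character(name), role = role, values = values,
                 var_names = var_names, run_ids = run_ids),
            class = "data_block")
}

#' @export
dim.data_block <- function(x) dim(x$values)

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block '%s'> %d runs x %d variables, role = %s\n",
              x$name, nrow(x$values), ncol(x$values), x$role))
  if (ncol(x$values) > 0L) {
    cat("  variables:", paste(x$var_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.data_block <- function(x, ...) x$values

stopifnot_same_runs <- function(blocks) {
  ids <- lapply(blocks, `[[`, "run_ids")
  ref <- ids[[1L]]
  for (i in seq_along(ids)[-1L]) {
    if (!identical(ids[[i]], ref)) {
      stop("blocks '", blocks[[1L]]$name, "' and '", blocks[[i]]$name,
           "' do not share identical run_ids in identical order")
    }
  }
  invisible(ref)
}

#' Autoscale a data block (mean centering and unit variance)
#'
#' Centers every column to mean zero and scales it to unit sample
#' standard deviation (the `n-1` denominator). This is the standard
#' chemometric preprocessing applied to all blocks before latent-variable
#' modeling, so that variables measured in different units contribute
#' comparably.
#'
#' @param block A [data_block()].
#' @param state Optional `preprocess_state` from a previous call: the
#'   block is scaled with the stored training means/sds instead of its
#'   own statistics (used when projecting new runs onto a fitted model).
#'
#' @return A list with `block` (the scaled [data_block()]) and `state`
#'   (a `preprocess_state` with per-variable `means` and `sds`).
#' @seealso [invert_scaling()]
#' @export
#'
#' @examples
#' b <- data_block(cbind(x = c(1, 2, 3), y = c(4, 6, 8)), "toy")
#' s <- autoscale(b)
#' colMeans(s$block$values)  # ~0
autoscale <- function(block, state = NULL) {
  stopifnot(inherits(block, "data_block"))
  X <- block$values
  if (ncol(X) == 0L) {
    return(list(block = block,
                state = preprocess_state(numeric(0), numeric(0),
                                         character(0))))
  }
  if (is.null(state)) {
    mu <- colMeans(X)
    sds <- apply(X, 2L, stats::sd)
    zero <- sds <= .Machine$double.eps * pmax(1, abs(mu))
    if (any(zero)) {
      stop("zero-variance column(s) in block '", block$name, "': ",
           paste(block$var_names[zero], collapse = ", "))
    }
    state <- preprocess_state(mu, sds, block$var_names)
  } else {
    stopifnot(inherits(state, "preprocess_state"))
    if (!identical(names(state$means), block$var_names)) {
      stop("preprocess_state variables do not match block '",
           block$name, "'")
    }
    mu <- state$means
    sds <- state$sds
  }
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")
  out <- block
  out$values <- Xs
  list(block = out, state = state)
}

#' Per-variable preprocessing state
#'
#' Stores the column means and sample standard deviations used to
#' autoscale a block, so that the transformation can be applied to new
#' runs and inverted exactly.
#'
#' @param means,sds Numeric vectors, one entry per variable.
#' @param var_names Variable names.
#' @return An object of class `preprocess_state`.
#' @export
preprocess_state <- function(means, sds, var_names = names(means)) {
  stopifnot(length(means) == length(sds))
  if (any(sds <= 0)) {
    stop("standard deviations must be strictly positive")
  }
  names(means) <- var_names
  names(sds) <- var_names
  structure(list(means = means, sds = sds), class = "preprocess_state")
}

#' Invert autoscaling
#'
#' Maps a scaled block (or plain matrix of predictions) back to original
#' units using a stored [preprocess_state()].
#'
#' @param x A `data_block` or numeric matrix on the autoscaled scale.
#' @param state The `preprocess_state` of the training data.
#' @return Object of the same kind as `x`, on original units.
#' @export
invert_scaling <- function(x, state) {
  stopifnot(inherits(state, "preprocess_state"))
  vals <- if (inherits(x, "data_block")) x$values else x
  out <- sweep(sweep(vals, 2L, state$sds, "*"), 2L, state$means, "+")
  if (inherits(x, "data_block")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Concatenate data blocks column-wise
#'
#' Joins several blocks sharing the same runs into a single wider block,
#' e.g. combining raw-material properties and granulation parameters into
#' one predictor block. On variable-name collision the colliding names
#' are prefixed with their source block name.
#'
#' @param blocks List of [data_block()]s with identical `run_ids`.
#' @param name Name of the combined block.
#' @param role Role of the combined block.
#' @return A [data_block()] whose columns are the input blocks' columns
#'   in order.
#' @export
concat_blocks <- function(blocks, name = NULL,
                          role = c("predictor", "interior", "predictee")) {
  role <- match.arg(role)
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1L), "data_block")))
  stopifnot_same_runs(blocks)
  if (is.null(name)) {
    name <- paste(vapply(blocks, `[[`, character(1L), "name"),
                  collapse = "+")
  }
  vn <- lapply(blocks, `[[`, "var_names")
  flat <- unlist(vn, use.names = FALSE)
  if (anyDuplicated(flat)) {
    dup <- unique(flat[duplicated(flat)])
    vn <- lapply(blocks, function(b) {
      ifelse(b$var_names %in% dup,
             paste(b$name, b$var_names, sep = "."), b$var_names)
    })
    flat <- unlist(vn, use.names = FALSE)
  }
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  colnames(values) <- flat
  data_block(values, name = name, role = role,
             run_ids = blocks[[1L]]$run_ids)
}

#' Expand a per-lot material block to per-run rows
#'
#' Material properties are measured once per raw-material lot, but the
#' designed experiment runs each lot several times. This repeats each
#' lot's property row for every run that used it, aligning the material
#' block with the run-indexed blocks.
#'
#' @param material [data_block()] whose `run_ids` are lot labels
#'   (one row per lot).
#' @param lot_of_run Character vector mapping each run (names = run ids,
#'   values = lot labels), in the desired run order.
#' @param aliases Named character vector of lot-label aliases applied
#'   before lookup (see [lot_aliases()]); use `character(0)` to disable.
#' @return A [data_block()] with `length(lot_of_run)` rows.
#' @export
expand_lot_block <- function(material, lot_of_run,
                             aliases = lot_aliases()) {
  stopifnot(inherits(material, "data_block"))
  lots <- as.character(lot_of_run)
  run_ids <- names(lot_of_run)
  if (is.null(run_ids)) run_ids <- as.character(seq_along(lots))
  if (length(aliases)) {
    hit <- lots %in% names(aliases)
    lots[hit] <- unname(aliases[lots[hit]])
  }
  idx <- match(lots, material$run_ids)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("run '", run_ids[bad], "' references lot '", lots[bad],
         "' which is not present in material block '", material$name, "'")
  }
  out <- material$values[idx, , drop = FALSE]
  rownames(out) <- run_ids
  data_block(out, name = material$name, role = material$role,
             run_ids = run_ids)
}

#' Lot-label alias map for the packaged design
#'
#' The packaged 52-run design table carries two lot labels that do not
#' match the lot list used elsewhere in the source material
#' (apparent typos): `"YNZZ"` for `"YNZW"` and `"SXAS"` for `"SSAS"`.
#' This map is applied by default when resolving lots and can be
#' overridden or disabled.
#'
#' @return Named character vector `c(YNZZ = "YNZW", SXAS = "SSAS")`.
#' @export
lot_aliases <- function() c(YNZZ = "YNZW", SXAS = "SSAS")

# Optional block-level scaling: divide a (scaled) block by sqrt(n_vars)
# so blocks of very different widths contribute comparably. Off by
# default; the multi-block fitters expose it as `block_scaling`.
apply_block_scaling <- function(block, block_scaling = c("none",
                                                         "sqrt_nvars")) {
  block_scaling <- match.arg(block_scaling)
  if (block_scaling == "sqrt_nvars" && ncol(block$values) > 0L) {
    block$values <- block$values / sqrt(ncol(block$values))
  }
  block
}

#' Path specification for a block set
#'
#' Declares the block ordering and directed edges of the path model.
#' Predictor blocks have no incoming edges, predictee blocks no outgoing
#' edges, interior blocks both; the graph must be acyclic.
#'
#' @param block_order Character vector of block names, left to right.
#' @param edges Two-column character matrix (or list of length-2 vectors)
#'   of `(source, target)` edges.
#' @return Object of class `path_spec`.
#' @export
#'
#' @examples
#' path_spec(c("X1", "X2", "X3", "Y"),
#'           list(c("X1", "X3"), c("X1", "Y"), c("X2", "Y"), c("X3", "Y")))
path_spec <- function(block_order, edges) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  stopifnot(is.character(block_order), ncol(edges) == 2L)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("source", "target")))
  if (!all(edges %in% block_order)) {
    stop("edge endpoints must appear in block_order")
  }
  # Kahn topological check for acyclicity
  nodes <- block_order
  incoming <- table(factor(edges[, 2L], levels = nodes))
  left <- edges
  active <- nodes[incoming == 0L]
  seen <- character(0)
  while (length(active)) {
    n <- active[1L]; active <- active[-1L]; seen <- c(seen, n)
    out <- which(left[, 1L] == n)
    for (e in out) {
      tgt <- left[e, 2L]
      incoming[tgt] <- incoming[tgt] - 1L
      if (incoming[tgt] == 0L) active <- c(active, tgt)
    }
    if (length(out)) left <- left[-out, , drop = FALSE]
  }
  if (length(seen) != length(nodes)) stop("path specification is cyclic")
  roles <- vapply(nodes, function(n) {
    has_in <- any(edges[, 2L] == n)
    has_out <- any(edges[, 1L] == n)
    if (has_in && has_out) "interior"
    else if (has_out) "predictor"
    else if (has_in) "predictee"
    else "isolated"
  }, character(1L))
  if (any(roles == "isolated")) {
    stop("block(s) with no edges: ",
         paste(nodes[roles == "isolated"], collapse = ", "))
  }
  structure(list(block_order = block_order, edges = edges, roles = roles),
            class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat("<path_spec>", paste(x$block_order, collapse = " -> "), "\n")
  apply(x$edges, 1L, function(e) cat(" ", e[1L], "->", e[2L], "\n"))
  invisible(x)
}
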