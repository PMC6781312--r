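# Random-block fixtures built in code; every test sets its own seed.

rand_block <- function(n, p, name = "B", seed = NULL,
                       role = "predictor", prefix = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prefix)) prefix <- tolower(name)
  vals <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0(prefix, seq_len(p))))
  data_block(vals, name = name, role = role)
}

# A small linked system: Y depends linearly on X1's first columns,
# through X3, with controllable noise. Used for path-model behavior.
linked_system <- function(n = 30, seed = 1, noise = 0.1) {
  set.seed(seed)
  X1 <- rand_block(n, 5, "X1")
  X2 <- rand_block(n, 4, "X2")
  X3v <- cbind(f = X1$values[, 1] + noise * rnorm(n),
               g = rnorm(n))
  X3 <- data_block(X3v, "X3", role = "interior")
  Yv <- cbind(y1 = X3v[, "f"] + 0.5 * X2$values[, 1] + noise * rnorm(n),
              y2 = X3v[, "g"] - 0.5 * X2$values[, 2] + noise * rnorm(n))
  Y <- data_block(Yv, "Y", role = "predictee")
  list(X1 = X1, X2 = X2, X3 = X3, Y = Y)
}

# Case-study generation with the packaged design (memoised per seed to
# keep the suite fast).
.case_cache <- new.env(parent = emptyenv())
case_study <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.case_cache[[key]])) {
    cs <- generate_case_study(generator_config(seed = seed, ...))
    cs$X1 <- concat_blocks(list(cs$blocks$M_expanded, cs$blocks$P1),
                           name = "X1")
    .case_cache[[key]] <- cs
  }
  .case_cache[[key]]
}
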