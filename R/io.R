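# md5 digests of the packaged fixture tables, frozen at build time; a
# mismatch means the installation is corrupted.
fixture_checksums <- c(
  table1_factor_levels.csv = "47a631c27109362871d38a5e8e47d5c7",
  table2_design.csv = "fcfbbd930d7c1fa8bafbb2b29ea66c3c"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "blockpath")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Load the packaged D-optimal design tables
#'
#' Returns the designed factor ranges (7 factors with printed units)
#' and the 52-run D-optimal experiment: raw-material lot per run plus
#' the settings of pre-mixing time (A, min), impeller rate (B, rpm),
#' binder amount (C, %), liquid additive rate (D, mL/min), granulation
#' time (E, min), lubrication time (F, min) and minimal punch tip
#' separation distance (G, mm). A few interior (non-vertex) settings
#' are present, as D-optimal candidate exchange admits them.
#'
#' @param apply_aliases Apply the documented lot-label alias map
#'   ([lot_aliases()]) to the design's lot column.
#' @return List with `table1` (factor levels data frame) and `table2`
#'   (52-row design data frame with `run_id`, `lot`, `A`..`G`).
#' @export
load_fixture_design <- function(apply_aliases = FALSE) {
  paths <- vapply(names(fixture_checksums), fixture_path, character(1L))
  sums <- tools::md5sum(paths)
  expected <- fixture_checksums[names(fixture_checksums)]
  if (any(nzchar(expected) & sums != expected)) {
    stop("packaged fixture checksum mismatch; installation corrupted")
  }
  t1 <- utils::read.csv(paths[[1L]], stringsAsFactors = FALSE)
  t2 <- utils::read.csv(paths[[2L]], stringsAsFactors = FALSE)
  if (apply_aliases) {
    al <- lot_aliases()
    hit <- t2$lot %in% names(al)
    t2$lot[hit] <- unname(al[t2$lot[hit]])
  }
  list(table1 = t1, table2 = t2)
}

#' Assemble the designed process blocks from the packaged tables
#'
#' Splits the 52-run design into the granulation-parameter block
#' (`P1`: A-E) and the compaction-parameter block (`X3`: F, G), and
#' returns the per-run lot assignment used to expand a material block.
#'
#' @return List with `P1` and `X3` [data_block()]s and `lot_of_run`
#'   (named character vector, run id -> lot label, aliases applied).
#' @export
design_blocks <- function() {
  fx <- load_fixture_design(apply_aliases = TRUE)
  t2 <- fx$table2
  run_ids <- as.character(t2$run_id)
  P1 <- data_block(as.matrix(t2[, c("A", "B", "C", "D", "E")]),
                   name = "P1", role = "predictor", run_ids = run_ids)
  X3 <- data_block(as.matrix(t2[, c("F", "G")]),
                   name = "X3", role = "interior", run_ids = run_ids)
  list(P1 = P1, X3 = X3,
       lot_of_run = stats::setNames(t2$lot, run_ids))
}

#' Read a data block from CSV
#'
#' Expects a header row, a first column `run_id` and numeric remaining
#' columns (comma separator, `.` decimal).
#'
#' @param path CSV file path.
#' @param name Block name (default: file name without extension).
#' @param role Block role.
#' @return A [data_block()].
#' @export
read_block_csv <- function(path, name = NULL,
                           role = c("predictor", "interior",
                                    "predictee")) {
  role <- match.arg(role)
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#"),
    error = function(e) {
      stop("empty or malformed block CSV: ", path, " (",
           conditionMessage(e), ")")
    })
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty or malformed block CSV: ", path)
  }
  if (names(df)[1L] != "run_id") {
    stop("first column of a block CSV must be 'run_id': ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate run_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric cell in ", path, " at row ", bad[1L],
             ", column '", names(body)[j], "'")
      }
      body[[j]] <- num
    }
  }
  data_block(as.matrix(body), name = name, role = role, run_ids = ids)
}

#' Write a data block to CSV
#'
#' Inverse of [read_block_csv()]: full-precision round trip.
#'
#' @param block A [data_block()].
#' @param path Output CSV path.
#' @param header_comment Optional provenance comment line written with a
#'   leading `#`.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(block, path, header_comment = NULL) {
  stopifnot(inherits(block, "data_block"))
  df <- data.frame(run_id = block$run_ids,
                   format(block$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; list values
#' are comma-separated. Numeric-looking values are converted.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
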