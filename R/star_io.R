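# Minimal STAR-dialect reader/writer: exactly one data block, loop_ style,
# whitespace-delimited values, '#' comments. This is the subset RELION emits
# for particle tables; multi-block files and quoted strings are out of scope.

#' Construct a STAR table
#'
#' @param block_name Block name without the `data_` prefix (e.g.
#'   `"particles"`).
#' @param data A data.frame; column names must be STAR tags starting with
#'   `_` and be unique.
#' @return Object of class `pcc_star_table` (list with `block_name`,
#'   `columns`, `data`).
#' @export
star_table <- function(block_name, data) {
  stopifnot(is.character(block_name), length(block_name) == 1L, is.data.frame(data))
  tags <- names(data)
  if (length(tags) == 0L || !all(startsWith(tags, "_"))) {
    stop("all column names must be STAR tags starting with '_'")
  }
  if (anyDuplicated(tags)) stop("duplicate STAR tags")
  structure(list(block_name = block_name, columns = tags, data = data),
            class = "pcc_star_table")
}

#' Write a STAR table
#'
#' Deterministic byte output: fixed column order, single spaces, `\n`
#' newlines, no locale-dependent formatting. Header comments (prefixed
#' `# `) carry provenance (seed, config).
#'
#' @param table A `pcc_star_table`.
#' @param path Output file path.
#' @param comments Character vector written as `# ` comment lines at the top.
#' @export
write_star <- function(table, path, comments = character(0)) {
  stopifnot(inherits(table, "pcc_star_table"))
  df <- table$data
  cells <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      format(col, trim = TRUE, scientific = FALSE, digits = 15)
    } else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- if (nrow(df) > 0L) apply(cells, 1L, paste, collapse = " ") else character(0)
  lines <- c(
    if (length(comments)) paste("#", comments) else character(0),
    "",
    paste0("data_", table$block_name),
    "",
    "loop_",
    paste0(table$columns, " #", seq_along(table$columns)),
    body,
    ""
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a STAR table
#'
#' Parses one `data_` block with a `loop_` header; tolerates comments and
#' blank lines; preserves row order. All values are returned as character
#' columns — callers coerce types.
#'
#' @param path File path.
#' @return A `pcc_star_table`.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_blank <- grepl("^\\s*$", raw)
  is_comment <- grepl("^\\s*#", raw)
  keep <- which(!is_blank & !is_comment)
  i <- 1L
  get <- function() {
    if (i > length(keep)) stop("unexpected end of file in ", path)
    trimws(raw[keep[i]])
  }
  line_no <- function() keep[i]
  tok <- get()
  if (!startsWith(tok, "data_")) {
    stop(path, ":", line_no(), ": expected a data_ block, found: ", tok)
  }
  block_name <- sub("^data_", "", tok)
  i <- i + 1L
  if (i > length(keep) || get() != "loop_") {
    stop(path, ":", if (i <= length(keep)) line_no() else NA,
         ": expected loop_ after data block header")
  }
  i <- i + 1L
  tags <- character(0)
  while (i <= length(keep) && startsWith(get(), "_")) {
    tag <- strsplit(get(), "\\s+")[[1L]][1L]  # drop trailing '#N'
    if (tag %in% tags) stop(path, ":", line_no(), ": duplicate tag ", tag)
    tags <- c(tags, tag)
    i <- i + 1L
  }
  if (length(tags) == 0L) stop(path, ": loop_ with no tags")
  rows <- vector("list", 0L)
  row_lines <- integer(0)
  while (i <= length(keep)) {
    fields <- strsplit(get(), "\\s+")[[1L]]
    if (length(fields) != length(tags)) {
      stop(path, ":", line_no(), ": row has ", length(fields),
           " fields, expected ", length(tags))
    }
    rows[[length(rows) + 1L]] <- fields
    row_lines <- c(row_lines, line_no())
    i <- i + 1L
  }
  df <- if (length(rows) > 0L) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix(character(0), 0L, length(tags)), stringsAsFactors = FALSE)
  }
  names(df) <- tags
  star_table(block_name, df)
}

#' Convert expanded particle records to/from the STAR dialect
#'
#' The particle table uses one `data_particles` block with loop columns
#' `_pccParticleId`, `_pccCopyIndex`, `_pccClassLabel`
#' (values `present`/`missing`). Real RELION symmetry-expanded star files
#' can be adapted by grouping duplicated image names into `_pccParticleId`.
#'
#' @param records A `pcc_records` data.frame.
#' @return `records_to_star()`: a `pcc_star_table`; `star_to_records()`:
#'   a `pcc_records` data.frame.
#' @export
records_to_star <- function(records) {
  star_table("particles", data.frame(
    `_pccParticleId` = as.integer(records$particle_id),
    `_pccCopyIndex` = as.integer(records$copy_index),
    `_pccClassLabel` = as.character(records$class_label),
    check.names = FALSE
  ))
}

#' @rdname records_to_star
#' @param table A `pcc_star_table` with the particle columns.
#' @export
star_to_records <- function(table) {
  stopifnot(inherits(table, "pcc_star_table"))
  need <- c("_pccParticleId", "_pccCopyIndex", "_pccClassLabel")
  if (!all(need %in% table$columns)) {
    stop("particle table must have columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    particle_id = as.integer(table$data[["_pccParticleId"]]),
    copy_index = as.integer(table$data[["_pccCopyIndex"]]),
    class_label = as.character(table$data[["_pccClassLabel"]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pcc_records", "data.frame")
  out
}

#' Write/read a formula distribution as TSV
#'
#' Columns: `formula_n`, `count`, `fraction`; `# ` comment lines carry
#' provenance.
#'
#' @param dist A `pcc_formula_dist`.
#' @param path File path.
#' @param comments Comment lines for the header.
#' @export
write_distribution_tsv <- function(dist, path, comments = character(0)) {
  stopifnot(inherits(dist, "pcc_formula_dist"))
  df <- data.frame(
    formula_n = 0:6,
    count = dist$counts,
    fraction = if (dist$total > 0) dist$counts / dist$total else rep(NA_real_, 7)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con, sep = "\n", useBytes = TRUE)
  writeLines(paste(c("formula_n", "count", "fraction"), collapse = "\t"), con,
             sep = "\n", useBytes = TRUE)
  writeLines(paste(df$formula_n,
                   format(df$count, trim = TRUE, scientific = FALSE, digits = 15),
                   format(df$fraction, trim = TRUE, scientific = FALSE, digits = 15),
                   sep = "\t"),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_distribution_tsv
#' @export
read_distribution_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("formula_n", "count") %in% names(df))) {
    stop("distribution TSV must have columns formula_n, count")
  }
  counts <- numeric(7L)
  counts[df$formula_n + 1L] <- df$count
  new_formula_dist(counts)
}

#' Write ground truth as TSV (`particle_id`, `bits`)
#'
#' @param truth A `pcc_truth` data.frame.
#' @param path File path.
#' @param comments Comment lines for the header.
#' @export
write_truth_tsv <- function(truth, path, comments = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con, sep = "\n", useBytes = TRUE)
  writeLines("particle_id\tbits", con, sep = "\n", useBytes = TRUE)
  writeLines(paste(truth$particle_id, truth$bits, sep = "\t"), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}
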