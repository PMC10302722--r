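#' Per-run response measurements
#'
#' A thin wrapper around a data frame of measured critical method
#' attributes aligned to design runs.  Missing measurements (for example a
#' plate count that cannot be read off a co-migrating peak pair) are held
#' as `NA` and tracked in a missing-value mask.
#'
#' @param df Data frame with a `run_id` column and one numeric column per
#'   response.
#' @return An object of class `"aqbd_responses"` (still a data frame).
#' @export
response_table <- function(df) {
  stopifnot(is.data.frame(df), "run_id" %in% names(df))
  resp <- setdiff(names(df), "run_id")
  for (v in resp) {
    if (!is.numeric(df[[v]]))
      stop("response column is not numeric: ", v)
    if (any(is.infinite(df[[v]])))
      stop("non-finite response value in column ", v)
  }
  attr(df, "responses") <- resp
  attr(df, "missing") <- is.na(as.matrix(df[resp]))
  class(df) <- c("aqbd_responses", "data.frame")
  df
}

#' @export
print.aqbd_responses <- function(x, ...) {
  cat(sprintf("response table: %d runs, responses: %s (%d missing cells)\n",
              nrow(x), paste(attr(x, "responses"), collapse = ", "),
              sum(attr(x, "missing"))))
  print(as.data.frame(x), ...)
  invisible(x)
}

num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

#' Read a delimited design/response table
#'
#' Comma-separated text with one header row; lines starting with `#` are
#' metadata comments (for example `#coding=physical`).  Empty cells and
#' the token `n.d.` (not determined) are read as missing.  Any other cell
#' that is not a plain decimal-point numeral -- including locale-style
#' decimals such as `1,48`, which would silently shift columns -- is a
#' hard error reported with its line number.
#'
#' @param path File path.
#' @return A data frame; the `#coding=` comment, if present, is attached
#'   as attribute `"coding"`.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  coding <- sub("^#coding=", "", grep("^#coding=", lines, value = TRUE))
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 2L)
    stop(sprintf("%s: no data rows found", path))
  header <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  cols <- sub("\\[.*\\]$", "", trimws(header))
  units <- ifelse(grepl("\\[.*\\]$", header),
                  sub("^.*\\[(.*)\\]$", "\\1", header), "")
  rows <- lapply(body_idx[-1], function(i) {
    cells <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(cells) != length(cols))
      stop(sprintf("%s line %d: expected %d cells, found %d", path, i,
                   length(cols), length(cells)))
    vapply(cells, function(cell) {
      if (cell == "" || cell == "n.d.") return(NA_real_)
      if (!grepl(num_re, cell))
        stop(sprintf("%s line %d: malformed numeric cell '%s'", path, i,
                     cell))
      as.numeric(cell)
    }, numeric(1), USE.NAMES = FALSE)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  if ("run_id" %in% cols) out$run_id <- as.integer(out$run_id)
  text <- do.call(rbind, lapply(body_idx[-1], function(i)
    trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])))
  colnames(text) <- cols
  attr(out, "units") <- stats::setNames(units, cols)
  attr(out, "text") <- text
  if (length(coding)) attr(out, "coding") <- coding[1]
  out
}

#' Write a design/response table
#'
#' Inverse of [read_table()]: comma-separated, `NA` written as `n.d.`,
#' unit strings restored into the header brackets, and the coding comment
#' (if any) on the first line.  `write_table(read_table(p), q)` reproduces
#' the fixture files byte for byte.
#'
#' @param x Data frame (possibly from [read_table()] or
#'   [physical_design()]).
#' @param path Output path.
#' @param coding Optional `"coded"`/`"physical"` tag; defaults to the
#'   attribute carried by `x`.
#' @param digits Significant digits for free-form numeric formatting of
#'   columns without a recorded text representation.
#' @export
write_table <- function(x, path, coding = attr(x, "coding"), digits = 15) {
  units <- attr(x, "units")
  header <- vapply(names(x), function(nm) {
    u <- if (!is.null(units) && nzchar(units[[nm]] %||% "")) units[[nm]] else ""
    if (nzchar(u)) paste0(nm, "[", u, "]") else nm
  }, "")
  fmt_cell <- function(v) {
    if (is.na(v)) return("n.d.")
    format(v, digits = digits, scientific = FALSE, trim = TRUE)
  }
  ## reuse the verbatim cell text captured at read time whenever the value
  ## is unchanged, so fixture round-trips are byte-exact
  text <- attr(x, "text")
  cells <- matrix("", nrow(x), ncol(x))
  for (j in seq_along(x)) {
    cells[, j] <- vapply(x[[j]], fmt_cell, "")
    if (!is.null(text) && nrow(text) == nrow(x) &&
        names(x)[j] %in% colnames(text)) {
      orig <- text[, names(x)[j]]
      same <- ifelse(orig %in% c("", "n.d."), is.na(x[[j]]),
                     suppressWarnings(as.numeric(orig)) == x[[j]])
      same[is.na(same)] <- FALSE
      cells[same, j] <- orig[same]
    }
  }
  body <- apply(cells, 1, paste, collapse = ",")
  lines <- c(if (!is.null(coding)) paste0("#coding=", coding),
             paste(header, collapse = ","), body)
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
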