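#' Write a delimited data table with metadata header
#'
#' Tab-separated text with '#'-prefixed `key: value` metadata lines before
#' the column header; values are printed with 17 significant digits so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param df Data frame of numeric columns.
#' @param path Output path.
#' @param meta Named list of metadata scalars.
#' @return `path`, invisibly.
#' @export
write_oct_table <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  }
  fmt <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }), check.names = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(fmt) > 0L) {
    writeLines(do.call(paste, c(unname(fmt), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a delimited data table written by [write_oct_table()]
#'
#' Validates the declared schema and reports non-numeric cells with their
#' row and column. Metadata comment lines are returned in the `meta`
#' attribute.
#'
#' @param path Input path.
#' @param required Character vector of required column names.
#' @return Data frame with attribute `meta` (named character vector).
#' @export
read_oct_table <- function(path, required = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  }
  is_meta <- startsWith(lines, "#")
  meta <- character(0)
  if (any(is_meta)) {
    kv <- sub("^#\\s*", "", lines[is_meta])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- setNames(vals, trimws(keys))
  }
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop(sprintf("empty input file: %s", path), call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!is.null(required)) {
    missing_cols <- setdiff(required, header)
    if (length(missing_cols) > 0L) {
      stop(sprintf("schema error in %s: missing column(s) %s", path,
        paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(body) == 1L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(header)),
      header))
    attr(df, "meta") <- meta
    return(df)
  }
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  bad_len <- which(vapply(cells, length, integer(1)) != length(header))
  if (length(bad_len) > 0L) {
    stop(sprintf("row %d of %s has %d fields, expected %d", bad_len[1L],
      path, length(cells[[bad_len[1L]]]), length(header)), call. = FALSE)
  }
  mat <- do.call(rbind, cells)
  df <- as.data.frame(setNames(lapply(seq_along(header), function(j) {
    col <- mat[, j]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("NA", "NaN")))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
        col[bad[1L]], bad[1L], header[j], path), call. = FALSE)
    }
    num
  }), header), check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write / read an A-scan
#'
#' A-scan files carry columns `k0_per_um` and `signal`; B-scan files add
#' `x1_um` (long format, one row per sample). Grid geometry travels in the
#' metadata header.
#'
#' @param ascan An `oct_ascan`.
#' @param path File path.
#' @param meta Extra metadata entries.
#' @return `path` (writers) or the reconstructed object (readers).
#' @export
write_ascan <- function(ascan, path, meta = list()) {
  stopifnot(inherits(ascan, "oct_ascan"))
  write_oct_table(
    data.frame(k0_per_um = ascan$grid$k, signal = ascan$signal),
    path,
    meta = c(list(kind = "ascan", x1_um = ascan$x1_um), meta)
  )
}

#' @rdname write_ascan
#' @export
read_ascan <- function(path) {
  df <- read_oct_table(path, required = c("k0_per_um", "signal"))
  meta <- attr(df, "meta")
  k <- df$k0_per_um
  grid <- wavenumber_grid(min(k), max(k), length(k))
  x1 <- if ("x1_um" %in% names(meta)) as.numeric(meta[["x1_um"]]) else 0
  structure(list(grid = grid, signal = df$signal, x1_um = x1),
    class = "oct_ascan")
}

#' @rdname write_ascan
#' @param bscan An `oct_bscan`.
#' @export
write_bscan <- function(bscan, path, meta = list()) {
  stopifnot(inherits(bscan, "oct_bscan"))
  n <- nrow(bscan$signals)
  df <- data.frame(
    x1_um = rep(bscan$x1_um, each = n),
    k0_per_um = rep(bscan$grid$k, times = ncol(bscan$signals)),
    signal = as.vector(bscan$signals)
  )
  write_oct_table(df, path, meta = c(list(kind = "bscan"), meta))
}

#' @rdname write_ascan
#' @export
read_bscan <- function(path) {
  df <- read_oct_table(path, required = c("x1_um", "k0_per_um", "signal"))
  x1 <- unique(df$x1_um)
  k <- sort(unique(df$k0_per_um))
  grid <- wavenumber_grid(min(k), max(k), length(k))
  sigs <- matrix(df$signal, nrow = length(k))
  structure(
    list(grid = grid, x1_um = x1, signals = sigs,
      surface_x3_um = rep(NA_real_, length(x1))),
    class = "oct_bscan"
  )
}
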