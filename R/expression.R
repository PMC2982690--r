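#' Construct an expression time-series profile
#'
#' An `expression_profile` holds a log2-ratio expression matrix (genes in
#' rows, time points in columns) on a strictly increasing, equally spaced
#' time grid in hours. It is the raw material of every pairwise metric in
#' the package.
#'
#' @param gene_ids Character vector of unique gene identifiers (row labels).
#' @param time_points_h Numeric vector of sampling times in hours; must be
#'   strictly increasing and equally spaced (to a relative tolerance of
#'   `1e-6` of the sampling interval).
#' @param values Numeric matrix, `length(gene_ids)` rows by
#'   `length(time_points_h)` columns, of log2 expression ratios. No missing
#'   values are permitted.
#'
#' @return An object of class `expression_profile`: a list with elements
#'   `gene_ids`, `time_points_h` and `values` (the matrix carries the gene
#'   ids as rownames).
#' @seealso [read_expression_table()], [average_replicates()]
#' @export
expression_profile <- function(gene_ids, time_points_h, values) {
  gene_ids <- as.character(gene_ids)
  time_points_h <- as.numeric(time_points_h)
  values <- as.matrix(values)
  storage.mode(values) <- "double"

  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("duplicate gene id: '", dup, "'", call. = FALSE)
  }
  if (nrow(values) != length(gene_ids))
    stop("values has ", nrow(values), " rows but there are ",
         length(gene_ids), " gene ids", call. = FALSE)
  if (ncol(values) != length(time_points_h))
    stop("values has ", ncol(values), " columns but there are ",
         length(time_points_h), " time points", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or drop them ",
         "before constructing a profile", call. = FALSE)
  if (anyNA(time_points_h))
    stop("time points contain missing values", call. = FALSE)
  if (length(time_points_h) > 1L) {
    dt <- diff(time_points_h)
    if (any(dt <= 0))
      stop("time points must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("time points must be equally spaced (max deviation ",
           signif(max(dt) - min(dt), 3), " h)", call. = FALSE)
  }
  rownames(values) <- gene_ids
  colnames(values) <- format(time_points_h, trim = TRUE)
  structure(list(gene_ids = gene_ids,
                 time_points_h = time_points_h,
                 values = values),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  span <- range(x$time_points_h)
  cat("Expression profile: ", length(x$gene_ids), " genes x ",
      length(x$time_points_h), " time points (",
      span[1], "-", span[2], " h)\n", sep = "")
  invisible(x)
}

#' Read a delimited expression time-series table
#'
#' Reads a text table whose header row holds time labels (hours) and whose
#' first column holds gene identifiers. The delimiter (tab or comma) is
#' auto-detected from the header line unless given. Time labels may carry a
#' `t`/`T` prefix or an `h`/`hr`/`hrs` suffix.
#'
#' Values are assumed to be log2-normalized already; set `log2_transform`
#' to take log2 at load time. Missing cells are rejected by default; with
#' `impute_missing = TRUE` interior gaps in a gene's series are filled by
#' linear interpolation (boundary gaps remain errors: a 7-14-point series
#' cannot absorb silent extrapolation).
#'
#' @param path Path to the table.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab vs
#'   comma from the header line.
#' @param impute_missing Logical; linearly interpolate interior missing
#'   values instead of failing.
#' @param log2_transform Logical; apply `log2()` to the values after load.
#' @return An [expression_profile].
#' @export
read_expression_table <- function(path, delimiter = NULL,
                                  impute_missing = FALSE,
                                  log2_transform = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("table needs a header row and at least one gene row", call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[1L])) "\t" else ","
  }
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(cells[[1L]])
  # header may or may not carry a label above the id column
  body <- cells[-1L]
  widths <- lengths(body)
  n_time <- if (length(header) == widths[1L]) length(header) - 1L
            else length(header)
  ragged <- which(widths != n_time + 1L)
  if (length(ragged))
    stop("ragged row ", ragged[1L] + 1L, ": expected ", n_time + 1L,
         " fields, found ", widths[ragged[1L]], call. = FALSE)

  time_labels <- header[(length(header) - n_time + 1L):length(header)]
  time_points <- parse_time_labels(time_labels)

  gene_ids <- vapply(body, function(r) trimws(r[1L]), character(1))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: '", gene_ids[duplicated(gene_ids)][1L], "'",
         call. = FALSE)

  vals <- matrix(NA_real_, length(gene_ids), n_time)
  for (i in seq_along(body)) {
    raw <- trimws(body[[i]][-1L])
    empty <- !nzchar(raw) | toupper(raw) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop("non-numeric cell '", raw[bad[1L]], "' at row ", i + 1L,
           ", column ", bad[1L] + 1L, call. = FALSE)
    vals[i, ] <- num
  }

  if (anyNA(vals)) {
    if (!impute_missing) {
      idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value for gene '", gene_ids[idx[1L]], "' at time ",
           time_points[idx[2L]], " h (set impute_missing = TRUE to ",
           "interpolate interior gaps)", call. = FALSE)
    }
    vals <- t(apply(vals, 1L, impute_interior, times = time_points))
    if (anyNA(vals))
      stop("missing values at the series boundary cannot be interpolated",
           call. = FALSE)
  }
  if (log2_transform) {
    if (any(vals <= 0))
      stop("log2 transform requested but table holds non-positive values",
           call. = FALSE)
    vals <- log2(vals)
  }
  expression_profile(gene_ids, time_points, vals)
}

parse_time_labels <- function(labels) {
  cleaned <- sub("^[tT]", "", trimws(labels))
  cleaned <- sub("(h|hr|hrs|H)$", "", cleaned)
  t <- suppressWarnings(as.numeric(cleaned))
  if (anyNA(t))
    stop("cannot parse time label '", labels[which(is.na(t))[1L]],
         "' as hours", call. = FALSE)
  t
}

impute_interior <- function(row, times) {
  ok <- !is.na(row)
  if (sum(ok) < 2L) return(row)
  interior <- seq_along(row) > which(ok)[1L] &
    seq_along(row) < which(ok)[sum(ok)]
  fill <- !ok & interior
  if (any(fill))
    row[fill] <- stats::approx(times[ok], row[ok], xout = times[fill])$y
  row
}

#' Write an expression profile as a delimited table
#'
#' Inverse of [read_expression_table()]; a read/write/read cycle of a
#' well-formed table reproduces the profile exactly.
#'
#' @param profile An [expression_profile].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(profile, path, delimiter = "\t") {
  stopifnot(inherits(profile, "expression_profile"))
  header <- paste(c("gene", fmt_num(profile$time_points_h)),
                  collapse = delimiter)
  rows <- vapply(seq_along(profile$gene_ids), function(i) {
    paste(c(profile$gene_ids[i], fmt_num(profile$values[i, ])),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# %.15g is a fixed point under parse/deparse for doubles, so text
# round-trips are byte-stable after the first write.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Average replicate expression profiles
#'
#' Element-wise arithmetic mean of replicate experiments, e.g. triplicate
#' arrays measured on the same genes and time grid. All profiles must agree
#' exactly in gene order and time grid.
#'
#' @param profiles List of [expression_profile] objects.
#' @return An [expression_profile] of the same shape.
#' @export
average_replicates <- function(profiles) {
  if (!length(profiles)) stop("no profiles to average", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "expression_profile")))
  ref <- profiles[[1L]]
  for (p in profiles[-1L]) {
    if (!identical(p$gene_ids, ref$gene_ids))
      stop("replicates disagree in gene ids or gene order", call. = FALSE)
    if (!isTRUE(all.equal(p$time_points_h, ref$time_points_h,
                          tolerance = 1e-9)))
      stop("replicates disagree in time grid", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(profiles, `[[`, "values")) / length(profiles)
  expression_profile(ref$gene_ids, ref$time_points_h, avg)
}
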