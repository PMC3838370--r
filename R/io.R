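# Matrix file layout: TSV (CSV sniffed on read), first column = variable id,
# one column per sample; a "group" row directly under the header assigns each
# sample to C or D.  An optional truth sidecar maps variable id -> pattern.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Write a two-group expression matrix (TSV with a group-label row)
#'
#' Writes variables x samples values with the sample->group assignment as a
#' second header row named `group`, losslessly at 15 significant digits.
#'
#' @param x numeric matrix, variables x samples (rownames = variable ids).
#' @param group per-column `"C"`/`"D"` labels.
#' @param path output file.
#' @param truth optional per-row pattern labels (`"H0a"`, `"H0b"`, `"H1"`)
#'   written to `truth_path`.
#' @param truth_path sidecar file for `truth` (default: `path` +
#'   `".truth.tsv"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, group, path, truth = NULL,
                             truth_path = paste0(path, ".truth.tsv")) {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("var%04d", seq_len(nrow(x)))
  samples <- colnames(x)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", samples), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(group)), collapse = "\t"), con)
  body <- apply(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                1, paste, collapse = "\t")
  writeLines(paste(ids, body, sep = "\t"), con)
  if (!is.null(truth)) {
    stopifnot(length(truth) == nrow(x))
    utils::write.table(data.frame(id = ids, truth = truth),
                       truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a two-group expression matrix
#'
#' Reads the format written by [write_matrix_tsv()] (TSV or CSV, sniffed):
#' header of sample names, a `group` row of `"C"`/`"D"` labels (or a
#' two-column sidecar `group_path` mapping sample -> label), then one
#' numeric row per variable.
#'
#' @param path matrix file.
#' @param group_path optional sidecar with columns sample, group; used when
#'   the matrix file has no embedded `group` row.
#' @return List with `x` (numeric matrix) and `group` (character vector).
#' @export
read_matrix_tsv <- function(path, group_path = NULL) {
  sep <- sniff_sep(path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file too short", call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  samples <- header[-1]
  second <- strsplit(lines[2], sep, fixed = TRUE)[[1]]
  has_group_row <- identical(second[1], "group")
  if (has_group_row) {
    group <- second[-1]
    body <- lines[-(1:2)]
  } else {
    if (is.null(group_path))
      stop("no 'group' row in matrix file and no group_path sidecar",
           call. = FALSE)
    map <- utils::read.table(group_path, sep = sniff_sep(group_path),
                             header = TRUE, stringsAsFactors = FALSE)
    group <- map[[2]][match(samples, map[[1]])]
    if (anyNA(group))
      stop("group sidecar does not cover all samples", call. = FALSE)
    body <- lines[-1]
  }
  if (!all(group %in% c("C", "D")))
    stop("group labels must be 'C' or 'D'", call. = FALSE)
  parts <- strsplit(body, sep, fixed = TRUE)
  ncell <- lengths(parts)
  if (any(ncell != length(samples) + 1L))
    stop(sprintf("ragged matrix file: row %d has %d fields, expected %d",
                 which(ncell != length(samples) + 1L)[1],
                 ncell[ncell != length(samples) + 1L][1],
                 length(samples) + 1L), call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 1L)
  x <- matrix(NA_real_, length(parts), length(samples),
              dimnames = list(ids, samples))
  for (i in seq_along(parts)) {
    vals <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell in row %d ('%s'), column %d",
                   i, ids[i], which(is.na(vals))[1]), call. = FALSE)
    x[i, ] <- vals
  }
  if (!all(is.finite(x)))
    stop("matrix contains non-finite values", call. = FALSE)
  list(x = x, group = group)
}

#' Read a truth sidecar (variable id -> pattern)
#'
#' @param path two-column TSV/CSV with header, columns id and truth.
#' @return Named character vector of `"H0a"`/`"H0b"`/`"H1"` labels.
#' @export
read_truth_tsv <- function(path) {
  d <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(d[[2]] %in% c("H0a", "H0b", "H1")))
    stop("truth labels must be H0a/H0b/H1", call. = FALSE)
  stats::setNames(d[[2]], d[[1]])
}
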