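# Readers/writers for the tabular interchange formats:
#   - wide "prediction-by-submission" CSV: CHROM,END,<submission_1>,...  (0/1)
#   - long call TSV: caller,chrom,pos
#   - truth CSV: chrom,pos,truth (0/1)
#   - selection / metrics TSVs with stable column order
# The long form is the canonical internal representation.

strip_chr <- function(x) sub("^chr", "", x)

coord_columns <- function(cols) {
  if (all(c("CHROM", "END") %in% cols)) c("CHROM", "END")
  else if (all(c("chrom", "pos") %in% cols)) c("chrom", "pos")
  else stop("missing coordinate columns: need CHROM,END or chrom,pos",
            call. = FALSE)
}

#' Read a prediction-by-submission matrix
#'
#' Wide CSV with coordinate columns `CHROM`,`END` (or `chrom`,`pos`) followed
#' by one 0/1 membership column per submission, in file order. Rows claimed
#' by no submission are rejected, as are duplicate coordinates and non-binary
#' flags.
#'
#' @param path file path.
#' @param normalize_chrom strip a leading `"chr"` from chromosome labels, to
#'   reconcile dialect drift across VCF sources (`"chr1"` vs `"1"`). Default
#'   off: labels are compared as opaque strings.
#' @param sep field separator (`","`; use `"\t"` for TSV variants).
#' @return A `call_profile` whose callers are the submission column names.
#' @export
read_prediction_matrix <- function(path, normalize_chrom = FALSE, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  cc <- coord_columns(names(df))
  subs <- setdiff(names(df), cc)
  if (length(subs) == 0L) stop("no submission columns found", call. = FALSE)
  chrom <- as.character(df[[cc[1]]])
  if (normalize_chrom) chrom <- strip_chr(chrom)
  pos <- as.integer(df[[cc[2]]])
  if (anyDuplicated(vkey(chrom, pos)) > 0L)
    stop("duplicate (chromosome, position) rows", call. = FALSE)
  vals <- suppressWarnings(as.integer(as.matrix(df[subs])))
  if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
    stop("non-binary membership values (need 0/1)", call. = FALSE)
  flags <- matrix(vals, nrow = nrow(df), dimnames = list(NULL, subs))
  if (any(rowSums(flags) == 0L))
    stop("variant with no caller (all-zero membership row)", call. = FALSE)
  hit <- which(flags == 1L, arr.ind = TRUE)
  build_call_profile(
    data.frame(caller = subs[hit[, "col"]],
               chrom = chrom[hit[, "row"]],
               pos = pos[hit[, "row"]],
               stringsAsFactors = FALSE),
    callers = subs
  )
}

#' Write a prediction-by-submission matrix
#' @param profile a `call_profile`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_prediction_matrix <- function(profile, path, sep = ",") {
  flags <- vapply(profile$callers, function(j)
    as.integer(profile$variants$key %in% profile$calls_by_caller[[j]]),
    integer(nrow(profile$variants)))
  if (is.null(dim(flags)))
    flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, profile$callers))
  out <- data.frame(CHROM = profile$variants$chrom,
                    END = profile$variants$pos,
                    flags, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format call table
#'
#' TSV with header `caller`, `chrom`, `pos`; one row per (caller, variant)
#' call.
#'
#' @inheritParams read_prediction_matrix
#' @return A `call_profile`.
#' @export
read_long_calls <- function(path, normalize_chrom = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("caller", "chrom", "pos") %in% names(df)))
    stop("long call table needs columns caller, chrom, pos", call. = FALSE)
  if (normalize_chrom) df$chrom <- strip_chr(df$chrom)
  build_call_profile(df)
}

#' Write a long-format call table
#' @param profile a `call_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_calls <- function(profile, path) {
  write.table(profile$calls[, c("caller", "chrom", "pos")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a truth table
#'
#' CSV with header `chrom`, `pos`, `truth`, truth coded 0/1 (1 = verified
#' true mutation). Duplicate rows with identical labels collapse;
#' conflicting labels are an error.
#'
#' @inheritParams read_prediction_matrix
#' @return A `truth_table`.
#' @export
read_truth_table <- function(path, normalize_chrom = FALSE, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "truth") %in% names(df)))
    stop("truth table needs columns chrom, pos, truth", call. = FALSE)
  if (normalize_chrom) df$chrom <- strip_chr(df$chrom)
  if (!all(df$truth %in% c(0L, 1L)))
    stop("truth values outside {0,1}", call. = FALSE)
  truth_table(df$chrom, df$pos, df$truth)
}

#' Write a truth table
#' @param truth a `truth_table`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path, sep = ",") {
  out <- truth$table
  out$truth <- as.integer(out$truth)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a selection
#'
#' TSV with stable column order `chrom`, `pos`, `attribution`, `strategy`,
#' `seed`. An empty selection writes a header-only file.
#'
#' @param selection a `selection`.
#' @param path file path.
#' @return `write_selection()` returns `path` invisibly; `read_selection()`
#'   returns a `selection`.
#' @export
write_selection <- function(selection, path) {
  v <- selection$variants
  out <- data.frame(chrom = v$chrom, pos = v$pos,
                    attribution = v$attribution,
                    strategy = rep(selection$strategy, nrow(v)),
                    seed = rep(selection$seed, nrow(v)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "attribution", "strategy", "seed")
  if (!all(need %in% names(df)))
    stop("selection file needs columns chrom, pos, attribution, strategy, seed",
         call. = FALSE)
  v <- data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                  key = vkey(df$chrom, df$pos),
                  attribution = as.character(df$attribution),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(v$key) > 0L)
    stop("selection file contains duplicate variants", call. = FALSE)
  structure(list(variants = v,
                 strategy = if (nrow(df)) df$strategy[1L] else NA_character_,
                 seed = if (nrow(df)) as.integer(df$seed[1L]) else NA_integer_),
            class = "selection")
}

#' Write / read per-caller metrics
#'
#' TSV with columns `caller`, `mode`, `TP`, `FP`, `FN`, `precision`,
#' `recall`, `F1`. Undefined scores (no usable selected calls) are
#' serialized as the literal token `NA`.
#'
#' @param metrics data.frame as returned by [evaluate_callers()].
#' @param path file path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the metrics data.frame.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("caller", "mode", "TP", "FP", "FN", "precision", "recall", "F1")
  if (!all(cols %in% names(metrics)))
    stop("metrics must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  write.table(metrics[cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("TP", "FP", "FN")) df[[col]] <- as.integer(df[[col]])
  for (col in c("precision", "recall", "F1")) df[[col]] <- as.numeric(df[[col]])
  df
}
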