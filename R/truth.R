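#' Construct a truth table
#'
#' Maps variants to a boolean verification outcome: `TRUE` for a real
#' mutation, `FALSE` otherwise. Lookups of unlabelled variants are an error —
#' there is no silent default, since a missing label would otherwise be
#' indistinguishable from a verified false positive.
#'
#' Duplicate (chrom, pos) rows with identical labels collapse to one;
#' duplicates with conflicting labels are an error.
#'
#' @param chrom character chromosome labels.
#' @param pos integer 1-based positions.
#' @param truth logical (or 0/1) labels.
#' @return An object of class `truth_table` with elements `table`
#'   (data.frame chrom, pos, truth) and `labels` (named logical vector keyed
#'   by `"chrom:pos"`).
#' @export
truth_table <- function(chrom = character(), pos = integer(), truth = logical()) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) == 1L && length(pos) > 1L) chrom <- rep(chrom, length(pos))
  if (is.numeric(truth) && !all(truth %in% c(0, 1, NA)))
    stop("truth values must be 0/1", call. = FALSE)
  truth <- as.logical(truth)
  if (length(chrom) != length(pos) || length(pos) != length(truth))
    stop("chrom, pos and truth must have equal length", call. = FALSE)
  if (anyNA(chrom) || anyNA(pos) || anyNA(truth))
    stop("truth table contains missing values", call. = FALSE)
  df <- unique(data.frame(chrom = chrom, pos = pos, truth = truth,
                          stringsAsFactors = FALSE))
  key <- vkey(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    bad <- unique(key[duplicated(key)])
    stop(sprintf("conflicting truth labels for: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(list(table = df, labels = setNames(df$truth, key)),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d variants (%d true, %d false)\n",
              length(x$labels), sum(x$labels), sum(!x$labels)))
  invisible(x)
}

#' Look up truth labels for variant keys
#'
#' @param truth a `truth_table`.
#' @param keys character vector of variant keys (`"chrom:pos"`).
#' @return Logical vector; errors if any key is unlabelled.
#' @export
truth_lookup <- function(truth, keys) {
  out <- truth$labels[keys]
  if (anyNA(out)) {
    miss <- keys[is.na(out)]
    stop(sprintf("variant(s) missing from truth table: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Label unlisted profile variants as false
#'
#' Completes a truth table over every variant of a profile, labelling
#' variants absent from the table as `FALSE`. Only valid when absence from
#' the table is known to imply a false call — as in the synthetic generator,
#' whose construction keeps false-positive coordinates disjoint from the
#' true-mutation coordinates.
#'
#' @param truth a `truth_table` (typically the true mutations only).
#' @param profile a `call_profile`.
#' @return A `truth_table` covering all of `truth` plus all profile variants.
#' @export
complete_truth <- function(truth, profile) {
  extra <- !(profile$variants$key %in% names(truth$labels))
  truth_table(
    chrom = c(truth$table$chrom, profile$variants$chrom[extra]),
    pos   = c(truth$table$pos, profile$variants$pos[extra]),
    truth = c(truth$table$truth, rep(FALSE, sum(extra)))
  )
}
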