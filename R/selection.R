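#' Construct a selection of verification candidates
#'
#' A selection is an ordered, duplicate-free set of variants chosen for
#' verification, each annotated with the allocation unit (caller, overlap
#' level, or matrix cell) whose budget consumed it. Strategy functions build
#' selections internally; this constructor is exposed for assembling custom
#' selections (e.g. an externally chosen verification panel) for evaluation.
#'
#' @param profile the `call_profile` the variants come from.
#' @param keys character vector of distinct variant keys, all present in the
#'   profile.
#' @param attribution character vector parallel to `keys`; defaults to the
#'   first member caller of each variant.
#' @param strategy strategy name recorded with the selection.
#' @param seed integer RNG seed recorded with the selection (NA for manual
#'   selections).
#' @return An object of class `selection`: list with `variants` (data.frame
#'   chrom, pos, key, attribution), `strategy` and `seed`.
#' @export
selection_from_keys <- function(profile, keys, attribution = NULL,
                                strategy = "manual", seed = NA_integer_) {
  if (anyDuplicated(keys) > 0L)
    stop("selection contains duplicate variants", call. = FALSE)
  idx <- match(keys, profile$variants$key)
  if (anyNA(idx))
    stop("selection names variants absent from the profile", call. = FALSE)
  attribution <- attribution %||%
    vapply(profile$membership[keys], `[[`, "", 1L)
  df <- data.frame(
    chrom = profile$variants$chrom[idx],
    pos = profile$variants$pos[idx],
    key = profile$variants$key[idx],
    attribution = as.character(attribution),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  structure(list(variants = df, strategy = strategy, seed = seed),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection: %d variants (strategy '%s', seed %s)\n",
              nrow(x$variants), x$strategy, format(x$seed)))
  invisible(x)
}

#' Variant keys of a selection
#' @param selection a `selection`.
#' @return Character vector of `"chrom:pos"` keys in selection order.
#' @export
selection_keys <- function(selection) selection$variants$key

#' Number of selected variants
#' @param selection a `selection`.
#' @return Integer.
#' @export
selection_size <- function(selection) nrow(selection$variants)
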