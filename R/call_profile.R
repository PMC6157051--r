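#' Build a call profile from long-format call records
#'
#' A call profile is the union of variants predicted by an ensemble of
#' callers, with each variant mapped to the set of callers that predicted it
#' (its membership). The number of callers in that set is the variant's
#' overlap level: level 1 calls are unique to one caller, level N calls were
#' made by every caller. Variants are identified by (chromosome, position)
#' only; duplicate (caller, variant) records collapse to one.
#'
#' @param records data.frame with columns `caller`, `chrom`, `pos`
#'   (1-based integer positions).
#' @param callers optional character vector fixing caller identity and order;
#'   defaults to order of first appearance in `records`. May include callers
#'   with zero calls.
#' @return An object of class `call_profile` with elements `callers`,
#'   `calls` (deduplicated long table), `variants` (one row per distinct
#'   variant), `membership` (named list: variant key -> caller set) and
#'   `level` (named integer vector of overlap levels).
#' @examples
#' prof <- build_call_profile(data.frame(
#'   caller = c("A", "B", "A"),
#'   chrom  = c("chr1", "chr1", "chr1"),
#'   pos    = c(100, 100, 200)
#' ))
#' prof$level
#' @export
build_call_profile <- function(records, callers = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no calls: `records` must be a non-empty data.frame", call. = FALSE)
  need <- c("caller", "chrom", "pos")
  if (!all(need %in% names(records)))
    stop("`records` must have columns caller, chrom, pos", call. = FALSE)
  calls <- data.frame(
    caller = as.character(records$caller),
    chrom  = as.character(records$chrom),
    pos    = as.integer(records$pos),
    stringsAsFactors = FALSE
  )
  if (anyNA(calls)) stop("call records contain missing values", call. = FALSE)
  if (any(calls$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  calls <- unique(calls)
  callers <- callers %||% unique(calls$caller)
  if (!all(calls$caller %in% callers))
    stop("call records name callers absent from `callers`", call. = FALSE)
  calls$key <- vkey(calls$chrom, calls$pos)
  new_call_profile(calls, as.character(callers))
}

new_call_profile <- function(calls, callers) {
  first <- !duplicated(calls$key)
  variants <- calls[first, c("chrom", "pos", "key")]
  rownames(variants) <- NULL
  membership <- split(calls$caller, calls$key)
  # restore first-appearance order (split sorts keys)
  membership <- membership[variants$key]
  level <- setNames(lengths(membership), variants$key)
  calls_by_caller <- split(calls$key, factor(calls$caller, levels = callers))
  structure(
    list(
      callers = callers,
      calls = calls[, c("caller", "chrom", "pos", "key")],
      variants = variants,
      membership = membership,
      level = level,
      calls_by_caller = calls_by_caller
    ),
    class = "call_profile"
  )
}

#' @export
print.call_profile <- function(x, ...) {
  cat(sprintf(
    "call_profile: %d callers, %d distinct variants, %d calls\n",
    length(x$callers), nrow(x$variants), nrow(x$calls)
  ))
  lv <- table(factor(x$level, levels = seq_along(x$callers)))
  cat("variants per overlap level:",
      paste(sprintf("%s:%d", names(lv), as.integer(lv)), collapse = " "), "\n")
  invisible(x)
}

#' Number of callers in a profile
#' @param profile a `call_profile`.
#' @return Integer.
#' @export
n_callers <- function(profile) length(profile$callers)

#' Variant keys predicted by one caller
#' @param profile a `call_profile`.
#' @param caller caller identifier.
#' @return Character vector of variant keys (`"chrom:pos"`).
#' @export
caller_calls <- function(profile, caller) {
  if (!caller %in% profile$callers)
    stop(sprintf("unknown caller '%s'", caller), call. = FALSE)
  profile$calls_by_caller[[caller]]
}

#' Restrict a profile to a subset of callers
#'
#' Drops all calls by other callers; variants left with an empty membership
#' disappear from the profile.
#'
#' @param profile a `call_profile`.
#' @param keep character vector of caller ids to retain (order preserved).
#' @return A `call_profile` over `keep`.
#' @export
restrict_callers <- function(profile, keep) {
  keep <- as.character(keep)
  if (!all(keep %in% profile$callers))
    stop("`keep` names callers absent from the profile", call. = FALSE)
  if (length(keep) == 0L) stop("`keep` must retain at least one caller", call. = FALSE)
  calls <- profile$calls[profile$calls$caller %in% keep, , drop = FALSE]
  if (nrow(calls) == 0L)
    stop("no calls remain after restricting callers", call. = FALSE)
  new_call_profile(calls, keep)
}

#' Build the call overlap-by-caller matrix
#'
#' Cell (k, j) holds the variants with overlap level exactly k whose
#' membership includes caller j. A level-k variant therefore appears in
#' exactly k cells, all in row k; row 1 partitions the unique calls by
#' caller. This matrix drives the directed-sampling strategy.
#'
#' @param profile a `call_profile`.
#' @return An object of class `overlap_matrix`: list with `callers` and
#'   `cells`, where `cells[[k]][[j]]` is the character vector of variant keys
#'   in cell (k, j).
#' @export
build_overlap_matrix <- function(profile) {
  N <- length(profile$callers)
  cells <- lapply(seq_len(N), function(k)
    setNames(vector("list", N), profile$callers))
  for (j in profile$callers) {
    keys <- profile$calls_by_caller[[j]]
    by_level <- split(keys, factor(profile$level[keys], levels = seq_len(N)))
    for (k in seq_len(N)) cells[[k]][[j]] <- by_level[[k]]
  }
  structure(list(callers = profile$callers, cells = cells),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  N <- length(x$callers)
  sizes <- sapply(seq_len(N), function(k) sapply(x$cells[[k]], length))
  if (is.null(dim(sizes))) sizes <- matrix(sizes, nrow = 1)
  dimnames(sizes) <- list(x$callers, paste0("level", seq_len(N)))
  cat("overlap_matrix cell sizes (caller x overlap level):\n")
  print(t(sizes))
  invisible(x)
}
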