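## Alignment-site removal for phylogeny preparation: columns with gap fraction
## > 0.5 or homogeneity < 0.1 are removed. Homogeneity is the mean pairwise
## identity among the column's non-gap characters (a bounded [0,1] statistic;
## a substitution-matrix-weighted variant can be supplied via `hom_fun`).

.alnMatrix <- function(alignment) {
  if (is(alignment, "AAMultipleAlignment") ||
      is(alignment, "AAStringSet") || is(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (!is.character(alignment)) stop("alignment format error")
  if (length(alignment) < 1L) stop("alignment format error: empty alignment")
  w <- nchar(alignment)
  if (length(unique(w)) != 1L)
    stop("alignment format error: ragged alignment (unequal lengths)")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

.colHomogeneity <- function(col) {
  res <- col[!col %in% c("-", ".")]
  n <- length(res)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  cnt <- table(res)
  sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
}

#' Per-column alignment statistics
#'
#' Gap fraction counts `-` and `.` characters; homogeneity is the mean
#' pairwise identity among non-gap characters (1.0 when a single distinct
#' non-gap character is present; 0.0 by convention for an all-gap column).
#'
#' @param alignment Equal-length character vector, `AAStringSet` or
#'   `AAMultipleAlignment` (>= 2 sequences).
#' @param index 0-based column index.
#' @return List with `index`, `gap_fraction`, `homogeneity`.
#' @export
columnStats <- function(alignment, index) {
  m <- .alnMatrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  if (index < 0L || index >= ncol(m)) stop("column index out of range")
  col <- m[, index + 1L]
  list(index = as.integer(index),
       gap_fraction = mean(col %in% c("-", ".")),
       homogeneity = .colHomogeneity(col))
}

#' Filter alignment columns for phylogeny
#'
#' Removes the columns flagged by the gap and homogeneity criteria: with
#' `mode = "union"` (the default, standard trimming practice) a column is
#' removed when its gap fraction exceeds `gap_thresh` OR its homogeneity is
#' below `hom_thresh`; `mode = "intersection"` removes only columns flagged by
#' both. Sequence order and names are preserved. Filtering is idempotent.
#'
#' @param alignment Equal-length character vector, `AAStringSet` or
#'   `AAMultipleAlignment`.
#' @param gap_thresh Remove when gap fraction > this (default 0.5).
#' @param hom_thresh Remove when homogeneity < this (default 0.1).
#' @param mode `"union"` or `"intersection"`.
#' @param hom_fun Optional replacement homogeneity function
#'   (`function(column_characters) -> [0,1]`).
#' @return List with `alignment` (named character vector) and `removed`
#'   (0-based column indices).
#' @export
filterAlignment <- function(alignment, gap_thresh = 0.5, hom_thresh = 0.1,
                            mode = c("union", "intersection"),
                            hom_fun = NULL) {
  mode <- match.arg(mode)
  m <- .alnMatrix(alignment)
  if (ncol(m) == 0L) stop("alignment format error: zero columns")
  hf <- if (is.null(hom_fun)) .colHomogeneity else hom_fun
  gapf <- apply(m, 2L, function(col) mean(col %in% c("-", ".")))
  hom <- apply(m, 2L, hf)
  flag_gap <- gapf > gap_thresh
  flag_hom <- hom < hom_thresh
  removed <- if (mode == "union") flag_gap | flag_hom
             else flag_gap & flag_hom
  kept <- m[, !removed, drop = FALSE]
  out <- stats::setNames(apply(kept, 1L, paste, collapse = ""), rownames(m))
  list(alignment = out, removed = as.integer(which(removed) - 1L))
}

#' Read / write an aligned FASTA file
#'
#' @param path Aligned FASTA path.
#' @return `readAlignmentFasta`: named character vector of aligned sequences.
#' @export
readAlignmentFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname readAlignmentFasta
#' @param alignment Named character vector of equal-length sequences.
#' @return `writeAlignmentFasta`: `path`, invisibly.
#' @export
writeAlignmentFasta <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(alignment)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
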