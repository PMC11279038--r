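#' Construct a miRNA count matrix with sample group labels
#'
#' The central container of the pipeline: an integer matrix of read counts
#' with miRNAs as rows and samples as columns, plus a factor assigning each
#' sample to the `control` or `frozen` group.
#'
#' @param counts Non-negative integer matrix with unique row and column
#'   dimnames.
#' @param groups Factor (or character) of length `ncol(counts)` with levels
#'   `control` and `frozen`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `groups`.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  groups <- factor(as.character(groups), levels = c("control", "frozen"))
  stopifnot(
    "counts must have miRNA row names" =
      !is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
    "counts must have sample column names" =
      !is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
    "counts must be non-negative" = all(counts >= 0L, na.rm = FALSE),
    "one group label per sample" = length(groups) == ncol(counts),
    "group labels must be control/frozen with both present" =
      !anyNA(groups) && nlevels(droplevels(groups)) == 2L
  )
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples (%d control, %d frozen)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "control"), sum(x$groups == "frozen")))
  cat(sprintf("  library sizes: %s\n",
              paste(colSums(x$counts), collapse = " ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix and its group labels to tab-separated files
#'
#' @param cm A `count_matrix`.
#' @param counts_path Output path for the counts table (first column
#'   `mirna_id`).
#' @param groups_path Optional output path for the sample-to-group table.
#' @export
write_count_matrix <- function(cm, counts_path, groups_path = NULL) {
  df <- data.frame(mirna_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  if (!is.null(groups_path)) {
    write_tsv(data.frame(sample_id = names(cm$groups),
                         group = as.character(cm$groups)), groups_path)
  }
  invisible(counts_path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param counts_path Counts table path.
#' @param groups_path Sample-to-group table path.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, groups_path) {
  df <- read_tsv(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mirna_id
  g <- read_tsv(groups_path)
  count_matrix(m, g$group[match(colnames(m), g$sample_id)])
}

#' Drop miRNAs with low total read counts
#'
#' Retains miRNA rows whose total count across all samples is strictly
#' greater than `min_total` (the conventional "more than four reads" rule),
#' preserving row order.
#'
#' @param cm A `count_matrix`.
#' @param min_total Retain rows with total count > `min_total`.
#' @return A filtered `count_matrix`.
#' @export
apply_min_count <- function(cm, min_total = 4L) {
  stopifnot(inherits(cm, "count_matrix"), min_total >= 0)
  keep <- rowSums(cm$counts) > min_total
  if (!any(keep)) {
    stop("no miRNA exceeds the minimum total count of ", min_total,
         "; nothing to analyze")
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm$groups)
}
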