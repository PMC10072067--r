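#' Remove low-count genes before DEG calling
#'
#' Drops genes whose read sum across all replicates and conditions is
#' below 10 (strictly less than 10 removed; a sum of exactly 10 is kept),
#' the usual pre-filter applied before differential-expression testing.
#'
#' @param table DE result data frame with columns `gene_id`, `log2fc`,
#'   `padj`, `total_reads`.
#' @param min_total Minimum read sum to keep a gene (default 10).
#' @return The filtered table.
#' @export
low_count_prefilter <- function(table, min_total = 10) {
  if (!"total_reads" %in% names(table)) {
    stop("DE table has no total_reads column.", call. = FALSE)
  }
  table[!is.na(table$total_reads) & table$total_reads >= min_total, ,
        drop = FALSE]
}

#' Call differentially expressed gene sets by threshold
#'
#' Applies the standard effect-size/significance rule with inclusive
#' boundaries: up-regulated genes have `log2fc >= lfc` and `padj <= alpha`;
#' down-regulated genes have `log2fc <= -lfc` and `padj <= alpha`. Genes
#' with a missing `padj` (removed by independent filtering upstream) are
#' treated as untested: excluded from both sets and tallied.
#'
#' @param table A (prefiltered) DE result data frame with `gene_id`,
#'   `log2fc`, `padj`.
#' @param label Comparison label (used by [venn_counts()]).
#' @param lfc Absolute log2 fold-change threshold (default 1, inclusive).
#' @param alpha Adjusted-p threshold (default 0.05, inclusive).
#' @return An object of class `deg_sets`: `label`, `up` and `down`
#'   gene-id character vectors, `n_untested`, `n_tested`.
#' @export
filter_degs <- function(table, label = "comparison", lfc = 1, alpha = 0.05) {
  req <- c("gene_id", "log2fc", "padj")
  if (!all(req %in% names(table))) {
    stop("DE table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$gene_id)) {
    stop("Duplicate gene_id in DE table.", call. = FALSE)
  }
  tested <- !is.na(table$padj)
  sig <- tested & table$padj <= alpha
  up <- table$gene_id[sig & table$log2fc >= lfc]
  down <- table$gene_id[sig & table$log2fc <= -lfc]
  structure(
    list(label = label, up = as.character(up), down = as.character(down),
         n_untested = sum(!tested), n_tested = sum(tested)),
    class = "deg_sets"
  )
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("<deg_sets> %s: %d up, %d down (%d untested)\n",
              x$label, length(x$up), length(x$down), x$n_untested))
  invisible(x)
}

#' Venn region counts for 2 or 3 DEG comparisons
#'
#' Exact region cardinalities by set algebra, separately for up- and
#' down-regulated genes. For two comparisons A and B the regions are
#' `A_only`, `B_only`, `A_B` (with the labels substituted); for three,
#' all seven regions. The per-comparison totals always equal
#' `|up| + |down|`.
#'
#' @param sets List of 2 or 3 [filter_degs()] results with distinct
#'   labels.
#' @return A list with `up` and `down` (named region-count vectors),
#'   `totals` (per comparison, up + down), and `common` (genes in every
#'   comparison: `up`, `down`, `total`).
#' @export
venn_counts <- function(sets) {
  if (!length(sets) %in% c(2L, 3L)) {
    stop("venn_counts takes 2 or 3 comparisons.", call. = FALSE)
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "deg_sets")))
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("Duplicated comparison labels: ", labels[duplicated(labels)][1],
         call. = FALSE)
  }
  regions <- function(lists) {
    k <- length(lists)
    universe <- unique(unlist(lists))
    member <- vapply(lists, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
    counts <- apply(patterns, 1, function(p) {
      if (!length(universe)) return(0L)
      sum(apply(member, 1, function(m) all(m == p)))
    })
    names(counts) <- apply(patterns, 1, function(p) {
      paste(labels[as.logical(p)], collapse = "&")
    })
    counts
  }
  up <- regions(lapply(sets, `[[`, "up"))
  down <- regions(lapply(sets, `[[`, "down"))
  all_name <- paste(labels, collapse = "&")
  totals <- vapply(sets, function(s) length(s$up) + length(s$down),
                   integer(1))
  names(totals) <- labels
  list(
    up = up, down = down, totals = totals,
    common = list(up = unname(up[all_name]), down = unname(down[all_name]),
                  total = unname(up[all_name] + down[all_name]))
  )
}
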