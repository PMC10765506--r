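#' Encode one panelist's free-sorting sheet as a similarity matrix
#'
#' In a free-sorting task each panelist partitions the wines into as
#' many groups as they wish.  The sheet is encoded as a binary wines x
#' wines matrix: 1 when two wines were put in the same group, 0
#' otherwise, 1 on the diagonal.
#'
#' @param partition named vector mapping wine id to the panelist's
#'   (arbitrary) group label.
#' @param wines ordered character vector of wine ids the sheet must
#'   cover exactly.
#' @return a binary similarity matrix.
#' @export
individual_similarity <- function(partition, wines = names(partition)) {
  if (is.null(names(partition)))
    .oeno_stop("partition must be named by wine id", "oenotype_invalid_sheet")
  if (!setequal(names(partition), wines) ||
      length(partition) != length(wines))
    .oeno_stop("sheet does not cover exactly the listed wines",
               "oenotype_invalid_sheet")
  p <- partition[wines]
  S <- outer(p, p, `==`) * 1L
  dimnames(S) <- list(wines, wines)
  S
}

#' Aggregate sorting sheets into a co-occurrence matrix
#'
#' Individual binary similarity matrices are summed across panelists;
#' cell (i, j) counts the panelists who placed wines i and j in the same
#' group, so larger numbers mean higher global similarity.
#'
#' @param sheets list of named partitions (one per panelist), all over
#'   the same wine set.
#' @return an object of class `"cooccurrence"`: list with `wines`,
#'   integer matrix `counts` and `n_panelists`.
#' @export
aggregate_cooccurrence <- function(sheets) {
  if (length(sheets) < 1L)
    .oeno_stop("need at least one sorting sheet", "oenotype_invalid_sheet")
  wines <- sort(names(sheets[[1L]]))
  mats <- lapply(sheets, individual_similarity, wines = wines)
  counts <- Reduce(`+`, mats)
  structure(list(wines = wines, counts = counts,
                 n_panelists = length(sheets)),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("Free-sorting co-occurrence matrix: %d wines, %d panelists\n",
              length(x$wines), x$n_panelists))
  print(x$counts)
  invisible(x)
}

#' Read a long-format sorting CSV
#'
#' Columns `panelist_id, wine_id, group_label`, optionally `descriptor`
#' (free-text aroma tags).
#'
#' @param path CSV path.
#' @return list of named partitions, with any descriptors attached as
#'   attribute `"descriptors"` (data frame).
#' @export
read_sorting_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("panelist_id", "wine_id", "group_label") %in% names(df)))
  sheets <- lapply(split(df, df$panelist_id), function(d)
    setNames(as.character(d$group_label), d$wine_id))
  if ("descriptor" %in% names(df))
    attr(sheets, "descriptors") <- df[!is.na(df$descriptor) &
                                        nzchar(df$descriptor),
                                      c("wine_id", "descriptor")]
  sheets
}

#' Cluster wines into sensory groups from a co-occurrence matrix
#'
#' Co-occurrence counts are converted to distances (by default
#' `n_panelists - count`, so distance 0 means every panelist co-grouped
#' the pair) and submitted to hierarchical clustering with Ward's
#' method.  The number of groups is chosen by [select_k()] unless
#' fixed.  Groups are labelled `A`, `B`, ... in dendrogram order.
#'
#' @param cooc a `"cooccurrence"` object, or a list of sheets which is
#'   aggregated first.
#' @param k number of sensory groups or `"auto"`.
#' @param k_max bound for automatic selection.
#' @param linkage `"ward.D2"` (default) or `"average"` for a robustness
#'   check.
#' @param distance `"count"` for `m - count` or `"fraction"` for
#'   `1 - count/m`.
#' @param descriptors optional data frame (`wine_id`, `descriptor`) of
#'   free-text tags, summarized per cluster by frequency.
#' @return an object of class `"sortclust"` with `tree`, `k`,
#'   `assignment` (wine -> letter), `cooc` and `descriptor_summary`.
#' @examples
#' sheets <- gen_sorting_panel(seed = 1)
#' fit <- sensory_clusters(sheets)
#' fit$assignment
#' @export
sensory_clusters <- function(cooc, k = "auto", k_max = 10L,
                             linkage = c("ward.D2", "average"),
                             distance = c("count", "fraction"),
                             descriptors = NULL) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (!inherits(cooc, "cooccurrence")) {
    if (is.null(descriptors)) descriptors <- attr(cooc, "descriptors")
    cooc <- aggregate_cooccurrence(cooc)
  }
  m <- cooc$n_panelists
  D <- if (distance == "count") m - cooc$counts else 1 - cooc$counts / m
  tree <- hclust(as.dist(D), method = linkage)
  gap_profile <- NULL
  if (identical(k, "auto")) {
    ksel <- select_k(tree, k_max = k_max)
    gap_profile <- attr(ksel, "gaps")
    k <- as.integer(ksel)
  }
  raw <- cutree(tree, k)
  # letters in dendrogram (leaf) order: first leaf's cluster is A
  pos <- match(seq_len(k), raw[tree$order])
  lab <- integer(k)
  lab[order(pos)] <- seq_len(k)
  assignment <- setNames(LETTERS[lab[raw]], cooc$wines)
  ds <- NULL
  if (!is.null(descriptors) && nrow(descriptors)) {
    descriptors$group <- assignment[descriptors$wine_id]
    ds <- lapply(split(descriptors$descriptor, descriptors$group),
                 function(x) sort(table(x), decreasing = TRUE))
  }
  structure(list(tree = tree, k = k, assignment = assignment,
                 cooc = cooc, linkage = linkage, distance = distance,
                 gap_profile = gap_profile, descriptor_summary = ds),
            class = "sortclust")
}

#' @export
print.sortclust <- function(x, ...) {
  cat(sprintf("Sensory clustering of %d wines (%s on %s distances), k = %d\n",
              length(x$assignment), x$linkage,
              if (x$distance == "count") "m - count" else "1 - count/m", x$k))
  for (g in sort(unique(x$assignment)))
    cat(sprintf("  Group %s: %s\n", g,
                paste(names(x$assignment)[x$assignment == g], collapse = ", ")))
  if (!is.null(x$descriptor_summary)) {
    cat("Top descriptors per group:\n")
    for (g in names(x$descriptor_summary)) {
      tops <- utils::head(x$descriptor_summary[[g]], 3L)
      cat(sprintf("  %s: %s\n", g, paste(names(tops), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
plot.sortclust <- function(x, ...) {
  plot(x$tree, hang = -1, xlab = "wine", sub = "",
       main = sprintf("Free-sorting consensus (k = %d)", x$k), ...)
  if (x$k > 1L && x$k < length(x$assignment))
    stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}
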