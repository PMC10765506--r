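#' Dice similarity between band patterns
#'
#' PCR fingerprints (RAPD, interdelta) are compared as sets of scored
#' band positions: `2 * |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b character or integer vectors of band identifiers (each a
#'   set; duplicates are collapsed).
#' @return similarity in \[0, 1\].
#' @examples
#' dice_similarity(c(1, 2, 3), c(2, 3, 4))  # 0.667
#' @export
dice_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    .oeno_stop("band patterns must be nonempty", "oenotype_empty_pattern")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Dice similarity matrix
#'
#' @param patterns named list of band-identifier vectors, one per
#'   fingerprint pattern.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
dice_matrix <- function(patterns) {
  n <- length(patterns)
  if (is.null(names(patterns))) names(patterns) <- paste0("P", seq_len(n))
  S <- diag(1, n)
  dimnames(S) <- list(names(patterns), names(patterns))
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      S[i, j] <- S[j, i] <- dice_similarity(patterns[[i]], patterns[[j]])
  S
}

#' Read a band-presence table
#'
#' Wide format: one row per pattern, column `pattern_id` plus 0/1 band
#' columns.  Long format: columns `pattern_id` and `band`.
#'
#' @param path CSV path.
#' @param format `"wide"` or `"long"`.
#' @return named list of band-identifier vectors.
#' @export
read_band_csv <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    stopifnot(all(c("pattern_id", "band") %in% names(df)))
    return(split(as.character(df$band), df$pattern_id))
  }
  stopifnot("pattern_id" %in% names(df))
  bands <- setdiff(names(df), "pattern_id")
  out <- lapply(seq_len(nrow(df)), function(i)
    bands[as.logical(unlist(df[i, bands]))])
  names(out) <- df$pattern_id
  out
}

#' UPGMA clustering of a similarity matrix
#'
#' Average-linkage agglomeration on distances `1 - similarity`, the
#' standard grouping step for normalized fingerprint band tables.
#'
#' @param sim symmetric similarity matrix in \[0, 1\] with unit diagonal,
#'   e.g. from [dice_matrix()].
#' @return an [stats::hclust] tree (heights on the distance scale).
#' @export
upgma <- function(sim) {
  sim <- as.matrix(sim)
  if (nrow(sim) < 2L)
    .oeno_stop("need at least two patterns to cluster", "oenotype_not_enough_items")
  if (max(abs(sim - t(sim))) > 1e-8 || any(abs(diag(sim) - 1) > 1e-8) ||
      any(sim < -1e-8 | sim > 1 + 1e-8))
    .oeno_stop("not a valid similarity matrix", "oenotype_bad_input")
  hclust(as.dist(1 - sim), method = "average")
}

#' Cut a fingerprint tree at a similarity threshold
#'
#' Clusters are the connected groups whose members join below distance
#' `1 - threshold`; with the conventional threshold 0.90, patterns at
#' least 90% similar end up in the same cluster.
#'
#' @param tree an [stats::hclust] tree from [upgma()].
#' @param threshold similarity threshold in (0, 1); default 0.90.
#' @return named integer vector of cluster memberships.
#' @export
clusters_at_similarity <- function(tree, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  cutree(tree, h = 1 - threshold + 1e-12)
}

#' Pick representative patterns per cluster
#'
#' For downstream identification work a subset of each cluster is
#' carried forward: between `k_min` and `k_max` members (all members of
#' smaller clusters), sampled reproducibly under `seed`.
#'
#' @param partition named cluster membership vector, e.g. from
#'   [clusters_at_similarity()].
#' @param k_min,k_max bounds on the number of representatives.
#' @param seed integer seed for the sampled subset.
#' @return named list of pattern-id vectors, one per cluster.
#' @export
pick_representatives <- function(partition, k_min = 2L, k_max = 5L, seed = 1L) {
  if (length(partition) == 0L)
    .oeno_stop("empty partition", "oenotype_bad_input")
  set.seed(seed)
  lapply(split(names(partition), partition), function(members) {
    if (length(members) <= k_min) return(members)
    n <- sample(k_min:k_max, 1L)
    sort(sample(members, min(n, length(members))))
  })
}
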