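#' Weighted Euclidean distances between phenotype codes
#'
#' @param codes integer matrix of 5-digit codes (rows = phenotypes) or a
#'   data frame with `code_*` columns.
#' @param weights positive length-5 weight vector applied per digit;
#'   the default of all ones treats the assays symmetrically.
#' @return a [stats::dist] object,
#'   `d(x, y) = sqrt(sum_d w_d (x_d - y_d)^2)`.
#' @export
euclidean_code_dist <- function(codes, weights = rep(1, 5)) {
  codes <- .as_code_matrix(codes)
  if (nrow(codes) < 2L)
    .oeno_stop("need at least two codes", "oenotype_not_enough_items")
  stopifnot(length(weights) == 5L, all(weights > 0))
  dist(sweep(codes, 2L, sqrt(weights), "*"))
}

#' Ward agglomeration of a distance matrix
#'
#' Thin wrapper around [stats::hclust] with the `ward.D2` convention
#' (Lance--Williams on squared distances, merge heights reported on the
#' distance scale), optionally weighting each item by a multiplicity.
#'
#' @param d a [stats::dist] object.
#' @param members optional integer multiplicities, one per item; a
#'   distinct phenotype held by 30 isolates then weighs 30 times a
#'   singleton phenotype.
#' @return an [stats::hclust] tree.
#' @export
ward_linkage <- function(d, members = NULL) {
  hclust(d, method = "ward.D2", members = members)
}

#' Choose the number of groups by the largest dendrogram gap
#'
#' Scanning the ordered merge heights `h_1 <= ... <= h_(n-1)`, the rule
#' cuts where the increase between consecutive merges is largest:
#' cutting between `h_j` and `h_(j+1)` leaves `n - j` groups, and `k`
#' maximizes that gap over candidates `2 <= k <= k_max`.  Ties go to the
#' smaller `k`.  A degenerate tree with all merge heights equal returns
#' `k = 2` with a warning.
#'
#' @param tree an [stats::hclust] tree, or a numeric vector of merge
#'   heights.
#' @param k_max largest admissible number of groups.
#' @return integer `k`, with the per-candidate gap profile attached as
#'   attribute `"gaps"` (a data frame with columns `k` and `gap`).
#' @examples
#' select_k(c(0.5, 0.7, 0.9, 4.0))      # 2
#' select_k(c(1, 1.1, 5, 5.2, 5.4))     # 4
#' @export
select_k <- function(tree, k_max = 10L) {
  h <- if (inherits(tree, "hclust")) tree$height else as.numeric(tree)
  h <- sort(h)
  n <- length(h) + 1L
  if (length(h) < 2L)
    .oeno_stop("need a tree with at least two merges", "oenotype_not_enough_items")
  stopifnot(k_max >= 2L)
  gaps <- diff(h)                         # gap i sits between h_i and h_(i+1)
  kv <- n - seq_along(gaps)               # cutting in gap i leaves n - i groups
  keep <- kv >= 2L & kv <= k_max
  prof <- data.frame(k = kv[keep], gap = gaps[keep])
  if (all(gaps < 1e-12)) {
    warning("all merge heights equal; returning k = 2", call. = FALSE)
    k <- 2L
  } else {
    best <- prof$gap >= max(prof$gap) - 1e-12
    k <- min(prof$k[best])                # ties toward smaller k
  }
  structure(as.integer(k), gaps = prof[order(prof$k), , drop = FALSE])
}

# undesirability penalty per code: killer sensitivity is disqualifying,
# then H2S level, acetic production (digit 0) and weak SO2 resistance
.code_penalty <- function(codes) {
  codes <- .as_code_matrix(codes)
  3 * (codes[, 1L] == 2L) + codes[, 2L] + (codes[, 3L] == 0L) +
    (2L - codes[, 4L])
}

#' Phenotype clustering of a screened isolate collection
#'
#' The core fit of the preselection method.  Assay results are encoded
#' into five-digit ordinal phenotype codes, the *distinct* codes are
#' clustered by Ward's method on (weighted) Euclidean distances -- each
#' code weighted by how many isolates carry it -- the number of groups
#' is chosen by the largest dendrogram gap ([select_k()]), and every
#' isolate inherits the group of its phenotype.  Groups are labelled
#' `1..k` by descending desirability (group 1 = most promising starter
#' phenotype); the raw dendrogram order is kept in `$dendro_order`.
#'
#' @param x an assay data frame (see [read_assay_csv()]), a data frame
#'   already carrying `code_*` columns, or a bare integer matrix of
#'   codes (rows = isolates).
#' @param weights per-digit distance weights, see
#'   [euclidean_code_dist()].
#' @param count_weighted weight each distinct phenotype by its isolate
#'   multiplicity during clustering (the default).  `FALSE` clusters the
#'   distinct codes unweighted, exactly as a dendrogram over the
#'   phenotype list; rare noise phenotypes then count as much as
#'   dominant ones, which degrades group recovery on noisy panels.
#' @param k number of groups; `NULL` (default) selects it by
#'   [select_k()].
#' @param k_max bound passed to [select_k()].
#' @param policy,allow_killer_positive passed to the encoders when `x`
#'   is a raw assay table.
#' @return an object of class `"phenoclust"` with components
#'   `codes` (distinct code matrix), `counts`, `tree` ([stats::hclust]),
#'   `k`, `gap_profile`, `assignment` (group per distinct phenotype),
#'   `isolate_groups` (group per input row), `penalty` (mean
#'   undesirability per group), `profiles` (per-group digit summary) and
#'   `species_table` when a `species` column is present.
#' @examples
#' panel <- gen_isolate_panel(n = 60, seed = 1)
#' fit <- phenoclust(panel)
#' fit
#' table(fit$isolate_groups)
#' @export
phenoclust <- function(x, weights = rep(1, 5), count_weighted = TRUE,
                       k = NULL, k_max = 10L, policy = "day8",
                       allow_killer_positive = FALSE) {
  cl <- match.call()
  if (is.data.frame(x) && !all(paste0("code_", .digit_names) %in% names(x)))
    x <- phenotype_codes(x, policy, allow_killer_positive)
  iso_codes <- .as_code_matrix(x)
  ph <- distinct_phenotypes(iso_codes)            # lexicographic, canonical
  codes <- .as_code_matrix(ph)
  rownames(codes) <- ph$phenotype
  n_ph <- nrow(codes)
  if (n_ph < 2L)
    .oeno_stop("need at least two distinct phenotypes", "oenotype_not_enough_items")
  d <- euclidean_code_dist(codes, weights)
  tree <- ward_linkage(d, members = if (count_weighted) ph$count)
  if (is.null(k)) {
    ksel <- select_k(tree, k_max = k_max)
    gap_profile <- attr(ksel, "gaps")
    k <- as.integer(ksel)
    k_fixed <- FALSE
  } else {
    stopifnot(k >= 1L, k <= n_ph)
    gap_profile <- NULL
    k_fixed <- TRUE
  }
  raw <- cutree(tree, k)
  pen <- .code_penalty(codes)
  group_pen <- vapply(seq_len(k), function(g) {
    w <- ph$count[raw == g]
    sum(pen[raw == g] * w) / sum(w)
  }, numeric(1L))
  relabel <- match(seq_len(k), order(group_pen))  # 1 = most desirable
  assignment <- setNames(relabel[raw], ph$phenotype)
  key <- apply(iso_codes, 1L, paste, collapse = "")
  iso_groups <- assignment[key]
  names(iso_groups) <- if (is.data.frame(x) && "isolate_id" %in% names(x))
    x$isolate_id else rownames(iso_codes)
  fit <- structure(list(
    codes = codes, counts = setNames(ph$count, ph$phenotype),
    dist = d, tree = tree, k = k, k_fixed = k_fixed,
    gap_profile = gap_profile,
    assignment = assignment,
    dendro_order = setNames(raw, ph$phenotype),
    penalty = sort(setNames(group_pen[order(group_pen)],
                            seq_len(k))),
    isolate_groups = iso_groups,
    weights = weights, count_weighted = count_weighted,
    call = cl), class = "phenoclust")
  fit$profiles <- characterize_groups(fit)
  if (is.data.frame(x) && "species" %in% names(x))
    fit$species_table <- species_composition(fit, x$species)
  fit
}

#' @export
print.phenoclust <- function(x, ...) {
  cat("Phenotype clustering (Ward.D2 on 5-digit ordinal codes)\n")
  cat(sprintf("  %d isolates, %d distinct phenotypes, k = %d group%s%s\n",
              sum(x$counts), nrow(x$codes), x$k, if (x$k > 1) "s" else "",
              if (x$k_fixed) " (fixed)" else " (largest-gap rule)"))
  sizes <- table(x$isolate_groups)
  cat("  isolates per group:",
      paste(sprintf("%s:%d", names(sizes), sizes), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.phenoclust <- function(object, ...) {
  structure(list(fit = object), class = "summary.phenoclust")
}

#' @export
print.summary.phenoclust <- function(x, ...) {
  print(x$fit)
  cat("\nGroup profiles (modal digit [range]):\n")
  print(x$fit$profiles$table)
  cat("\nMean undesirability penalty per group (low = preferred):\n")
  print(round(x$fit$penalty, 2))
  if (!is.null(x$fit$gap_profile)) {
    cat("\nGap profile of the k selection:\n")
    print(x$fit$gap_profile, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.phenoclust <- function(x, ...) {
  plot(x$tree, hang = -1, xlab = "distinct phenotype", sub = "",
       main = sprintf("Ward clustering of phenotype codes (k = %d)", x$k), ...)
  if (x$k > 1L && x$k < nrow(x$codes))
    stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' Re-cut a fitted phenotype clustering at another k
#'
#' @param fit a `"phenoclust"` object.
#' @param k the number of groups.
#' @return a new `"phenoclust"` object cut at `k`.
#' @export
cut_phenoclust <- function(fit, k) {
  stopifnot(inherits(fit, "phenoclust"))
  n <- sum(fit$counts)
  iso <- fit$codes[rep(seq_len(nrow(fit$codes)), fit$counts), , drop = FALSE]
  phenoclust(iso, weights = fit$weights, count_weighted = fit$count_weighted,
             k = k)
}

#' Summarize the assay profile of each phenotype group
#'
#' For every group and every digit: the (count-weighted) modal value and
#' the observed range, plus a short text characterization of the group.
#'
#' @param fit a `"phenoclust"` object.
#' @return a list with a `table` (rows = groups) and a character vector
#'   `text` of one-line descriptions.
#' @export
characterize_groups <- function(fit) {
  stopifnot(inherits(fit, "phenoclust"))
  k <- fit$k
  codes <- fit$codes; counts <- fit$counts; asg <- fit$assignment
  modal <- matrix(NA_integer_, k, 5L, dimnames = list(seq_len(k), .digit_names))
  cells <- matrix("", k, 5L, dimnames = list(seq_len(k), .digit_names))
  for (g in seq_len(k)) {
    sub <- codes[asg == g, , drop = FALSE]
    w <- counts[asg == g]
    for (j in 1:5) {
      tab <- tapply(w, sub[, j], sum)
      m <- as.integer(names(tab)[which.max(tab)])
      modal[g, j] <- m
      rng <- range(sub[, j])
      cells[g, j] <- if (rng[1L] == rng[2L]) as.character(m) else
        sprintf("%d [%d-%d]", m, rng[1L], rng[2L])
    }
  }
  killer_txt <- c("neutral to killer toxin", "sensitive to killer toxin")
  h2s_txt <- c("no", "low", "high", "very high")
  so2_txt <- c("no SO2 resistance", "SO2 resistance up to 300 mg/L",
               "SO2 resistant at 400-500 mg/L")
  text <- vapply(seq_len(k), function(g) sprintf(
    "Group %d: %s, %s H2S production, %s, %s, beta-glucosidase %s",
    g, killer_txt[modal[g, 1L]], h2s_txt[modal[g, 2L] + 1L],
    if (modal[g, 3L] == 0L) "acetic acid producer" else "no acetic acid production",
    so2_txt[modal[g, 4L] + 1L],
    if (modal[g, 5L] == 0L) "positive" else "negative"), character(1L))
  list(table = as.data.frame(cells), text = text)
}

#' Species composition per phenotype group
#'
#' @param fit a `"phenoclust"` object.
#' @param species character vector of species, one per isolate, in the
#'   row order of the data `fit` was built from.
#' @return a group x species contingency table (rows sum to group
#'   sizes).
#' @export
species_composition <- function(fit, species) {
  stopifnot(inherits(fit, "phenoclust"),
            length(species) == length(fit$isolate_groups))
  table(group = fit$isolate_groups, species = species)
}

#' Export a clustering tree as Newick
#'
#' @param tree an [stats::hclust] tree.
#' @param file path to write to, or `NULL` to return the Newick string.
#' @return the Newick string, invisibly when written to file.
#' @export
export_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
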