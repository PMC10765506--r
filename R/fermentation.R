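#' Residual sugar at the end of a fermentation curve
#'
#' Glucose and fructose are monitored daily during the
#' micro-fermentations; residual sugar is their sum at the last
#' monitored day, averaged over replicates.
#'
#' @param curve data frame with columns `day`, `glucose`, `fructose`
#'   and optionally `replicate`, for a single strain.
#' @return residual sugar in g/L.
#' @examples
#' curve <- data.frame(day = c(0, 14), glucose = c(119.5, 2),
#'                     fructose = c(120.1, 6))
#' residual_sugar(curve)  # 8
#' @export
residual_sugar <- function(curve) {
  if (nrow(curve) == 0L)
    .oeno_stop("empty fermentation curve", "oenotype_bad_input")
  if (any(curve$glucose < 0 | curve$fructose < 0))
    .oeno_stop("negative sugar concentration", "oenotype_bad_input")
  last <- curve[curve$day == max(curve$day), , drop = FALSE]
  mean(last$glucose + last$fructose)
}

#' Classify fermentation capacity from residual sugar
#'
#' A strain has fermentation capacity when it leaves the wine dry:
#' residual sugar above `threshold` g/L (default 10) marks an
#' incomplete fermentation, exactly `threshold` still passes.
#'
#' @param curve a fermentation curve data frame, or a precomputed
#'   residual-sugar value.
#' @param threshold dryness threshold in g/L.
#' @return logical.
#' @export
fermentation_capacity <- function(curve, threshold = 10) {
  rs <- if (is.data.frame(curve)) residual_sugar(curve) else curve
  rs <= threshold
}

#' Read the per-strain fermentation CSV
#'
#' Columns `strain_id, day, glucose, fructose, replicate`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_fermentation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "day", "glucose", "fructose") %in% names(df)))
  df
}

#' Summarize residual sugar and capacity for every strain
#'
#' @param ferment long fermentation data frame (see
#'   [read_fermentation_csv()]).
#' @param threshold dryness threshold in g/L.
#' @return data frame with `strain_id`, `residual_sugar`, `capacity`.
#' @export
classify_fermentations <- function(ferment, threshold = 10) {
  rs <- vapply(split(ferment, ferment$strain_id), residual_sugar, numeric(1L))
  data.frame(strain_id = names(rs), residual_sugar = unname(rs),
             capacity = unname(rs <= threshold), row.names = NULL)
}

#' Read the strain-outcome table
#'
#' One row per strain with its fermentation capacity, sensory group and
#' preliminary phenotypic group: columns `strain_id`, `capacity`
#' (TRUE/FALSE), `sensory_group` (A/B/C/D or `none` for strains whose
#' wines never reached the sensory stage), `preliminary_group` (e.g.
#' `1-Yellow`), `validated` (TRUE/FALSE).  The shipped transcription of
#' the 20-strain validation table is at
#' `system.file("extdata", "table3_strains.csv", package = "oenotype")`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_outcomes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "capacity", "sensory_group", "preliminary_group",
            "validated")
  stopifnot(all(need %in% names(df)))
  df$capacity <- as.logical(df$capacity)
  df$validated <- as.logical(df$validated)
  if (any(!df$capacity & df$sensory_group != "none"))
    .oeno_stop("strains without capacity cannot have a sensory group",
               "oenotype_bad_input")
  df
}

#' Concordance summary of phenotypic groups vs fermentation outcome
#'
#' Reproduces the validation bookkeeping of the method: strains per
#' preliminary phenotypic group, fraction completing fermentation,
#' cross-tabulation of preliminary group against sensory group, and the
#' fraction of strains whose outcome is concordant with their group.
#'
#' @param outcomes outcome data frame, see [read_outcomes_csv()].
#' @return an object of class `"concordance"`.
#' @examples
#' tab3 <- read_outcomes_csv(system.file("extdata", "table3_strains.csv",
#'                                       package = "oenotype"))
#' concordance_table(tab3)
#' @export
concordance_table <- function(outcomes) {
  if (nrow(outcomes) == 0L)
    .oeno_stop("empty outcome table", "oenotype_empty_dataset")
  gsz <- table(outcomes$preliminary_group)
  xt <- table(preliminary = outcomes$preliminary_group,
              sensory = outcomes$sensory_group)
  structure(list(
    n_strains = nrow(outcomes),
    group_sizes = gsz,
    n_capable = sum(outcomes$capacity),
    capacity_rate = mean(outcomes$capacity),
    n_sensory = sum(outcomes$sensory_group != "none"),
    crosstab = xt,
    validation_rate = mean(outcomes$validated),
    outcomes = outcomes), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance summary: %d strains, %d (%.0f%%) with fermentation capacity\n",
              x$n_strains, x$n_capable, 100 * x$capacity_rate))
  cat(sprintf("  %d wines entered the sensory stage; validation rate %.0f%%\n",
              x$n_sensory, 100 * x$validation_rate))
  cat("  strains per preliminary group:\n")
  print(x$group_sizes)
  cat("  preliminary x sensory cross-tab:\n")
  print(x$crosstab)
  invisible(x)
}

#' Phenotypic groups whose wines sort into desirable sensory groups
#'
#' A preliminary group is favorable when the majority of its capable
#' strains produced wines falling in the desirable sensory groups
#' (by default A and B; C and D wines were deemed undesirable).
#' Groups with no capable strains are never favorable.
#'
#' @param conc a `"concordance"` object.
#' @param desirable character vector of desirable sensory group labels.
#' @return character vector of favorable preliminary group labels.
#' @export
favorable_groups <- function(conc, desirable = c("A", "B")) {
  stopifnot(inherits(conc, "concordance"))
  out <- conc$outcomes
  cap <- out[out$capacity, , drop = FALSE]
  if (nrow(cap) == 0L) {
    warning("no capable strains; no favorable group", call. = FALSE)
    return(character(0L))
  }
  ok <- vapply(split(cap, cap$preliminary_group),
               function(d) mean(d$sensory_group %in% desirable) > 0.5,
               logical(1L))
  sort(names(ok)[ok])
}

#' Read a strain incidence table
#'
#' One row per strain; logical columns per region plus `red` and
#' `white` for the wine types the strain was recovered from.
#'
#' @param path CSV path.
#' @return data frame with `strain_id` and logical columns.
#' @export
read_incidence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("strain_id" %in% names(df))
  for (cn in setdiff(names(df), "strain_id")) df[[cn]] <- as.logical(df[[cn]])
  if (any(rowSums(df[, setdiff(names(df), "strain_id"), drop = FALSE]) == 0))
    .oeno_stop("every strain must be present somewhere", "oenotype_bad_input")
  df
}

#' Region and wine-type sharing of strains
#'
#' @param incidence data frame with `strain_id`, one logical column per
#'   region, and optionally logical `red` / `white` columns.
#' @param regions names of the region columns; defaults to every
#'   column except `strain_id`, `red` and `white`.
#' @return list with per-region `exclusive` strain sets, the `in_all`
#'   set found in every region, and when wine types are present a
#'   `wine_type` list with `both`, `red_only`, `white_only`.
#' @details Shipped fixtures: `strain_wine_types.csv` (transcribed
#'   red/white recovery of the 20 strains) and
#'   `strain_regions_synthetic.csv`, whose region columns are a
#'   synthetic completion consistent with the reported exclusives and
#'   the single strain present in all four regions.
#' @export
region_sharing <- function(incidence,
                           regions = setdiff(names(incidence),
                                             c("strain_id", "red", "white"))) {
  M <- as.matrix(incidence[, regions, drop = FALSE])
  rownames(M) <- incidence$strain_id
  exclusive <- lapply(setNames(regions, regions), function(r)
    rownames(M)[M[, r] & rowSums(M) == 1L])
  in_all <- if (length(regions))
    rownames(M)[rowSums(M) == length(regions)] else character(0L)
  out <- list(exclusive = exclusive, in_all = in_all)
  if (all(c("red", "white") %in% names(incidence))) {
    red <- incidence$red; white <- incidence$white
    out$wine_type <- list(
      both = incidence$strain_id[red & white],
      red_only = incidence$strain_id[red & !white],
      white_only = incidence$strain_id[white & !red])
  }
  out
}

#' Classify the strain richness of a wine sample community
#'
#' Spontaneously fermented samples fall into three community types by
#' the number of distinct strains surviving to the end of fermentation:
#' type 1 up to 2 strains, type 2 for 3--4, type 3 for 5 or more.
#'
#' @param n_strains integer vector of distinct strain counts per
#'   sample (possibly named).
#' @param breaks upper bounds of types 1 and 2.
#' @return integer vector of community types.
#' @export
community_richness <- function(n_strains, breaks = c(2L, 4L)) {
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  out <- ifelse(n_strains <= breaks[1L], 1L,
                ifelse(n_strains <= breaks[2L], 2L, 3L))
  setNames(as.integer(out), names(n_strains))
}
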