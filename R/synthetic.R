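#' Default group prototypes for synthetic isolate panels
#'
#' Four phenotype-code prototypes emulating the qualitative profiles of
#' the four groups a screening study of this kind recovers: a
#' killer-sensitive group, a neutral low-SO2-resistance non-acetic
#' group, a neutral low-H2S acetic-producing resistant group, and a
#' high-H2S acetic-producing resistant group with beta-glucosidase
#' activity.  Rows are near-equidistant (pairwise Euclidean distance
#' 2.0--2.65) so planted structure is recoverable.
#'
#' @return a 4 x 5 integer matrix.
#' @export
default_prototypes <- function() {
  p <- rbind(c(2L, 1L, 1L, 1L, 0L),
             c(1L, 2L, 1L, 0L, 1L),
             c(1L, 1L, 0L, 2L, 1L),
             c(1L, 3L, 0L, 2L, 0L))
  dimnames(p) <- list(paste0("proto", 1:4), .digit_names)
  p
}

# default species mix per planted group, dominated by S. cerevisiae as
# in spontaneously fermented wines, with the minor species confined to
# particular groups
.default_species_mix <- function(n_groups) {
  sc <- "Saccharomyces cerevisiae"
  base <- list(
    c("Saccharomyces cerevisiae" = 0.95, "Zygosaccharomyces bailii" = 0.05),
    c("Saccharomyces cerevisiae" = 0.85, "Zygosaccharomyces bailii" = 0.05,
      "Pichia manshurica" = 0.10),
    c("Saccharomyces cerevisiae" = 0.95, "Zygosaccharomyces bailii" = 0.05),
    c("Saccharomyces cerevisiae" = 0.85, "Zygosaccharomyces bailii" = 0.05,
      "Brettanomyces bruxellensis" = 0.10))
  if (n_groups <= 4L) return(base[seq_len(n_groups)])
  c(base, rep(list(setNames(1, sc)), n_groups - 4L))
}

# decode a 5-digit code back into raw assay columns; the H2S series is
# a monotone ramp reaching the coded level at day 5
.code_to_assays <- function(code) {
  list(killer = c("neutral", "sensitive")[code[1L]],
       h2s_d2 = max(0L, code[2L] - 1L), h2s_d5 = code[2L], h2s_d8 = code[2L],
       acetic = if (code[3L] == 0L) "producer" else "non_producer",
       so2_100 = code[4L] >= 1L, so2_200 = code[4L] >= 1L,
       so2_300 = code[4L] >= 1L, so2_400 = code[4L] >= 2L,
       so2_500 = code[4L] >= 2L,
       bglu = if (code[5L] == 0L) "positive" else "negative")
}

#' Generate a synthetic isolate panel with planted phenotype groups
#'
#' Each isolate is drawn from one of the group prototypes; every digit
#' is then independently perturbed, with probability `flip_prob`, to an
#' adjacent legal ordinal value (assay-grading error moves scores by
#' one step, not arbitrarily).  The emitted table uses the assay CSV
#' dialect of [read_assay_csv()]; the planted truth is kept in columns
#' `true_group` and `true_code`.
#'
#' @param n number of isolates.
#' @param prototypes matrix of group prototype codes, one row per
#'   planted group.
#' @param flip_prob per-digit adjacent-flip probability.
#' @param species_mix list of named probability vectors, one per group.
#' @param seed integer seed; the generator is bit-reproducible.
#' @return a data frame of `n` isolate records.
#' @examples
#' panel <- gen_isolate_panel(n = 20, flip_prob = 0, seed = 1)
#' nrow(distinct_phenotypes(phenotype_codes(panel)))  # 4
#' @export
gen_isolate_panel <- function(n = 190L, prototypes = default_prototypes(),
                              flip_prob = 0.03,
                              species_mix = .default_species_mix(nrow(prototypes)),
                              seed = 1L) {
  prototypes <- .as_code_matrix(prototypes)  # errors on invariant-violating rows
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  set.seed(seed)
  n_g <- nrow(prototypes)
  g <- sample(rep(seq_len(n_g), length.out = n))
  X <- prototypes[g, , drop = FALSE]
  for (j in 1:5) {
    flip <- runif(n) < flip_prob
    for (i in which(flip)) {
      cand <- intersect(X[i, j] + c(-1L, 1L), .digit_lo[j]:.digit_hi[j])
      X[i, j] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
  }
  species <- vapply(g, function(gi) {
    mix <- species_mix[[gi]]
    sample(names(mix), 1L, prob = mix)
  }, character(1L))
  regions <- c("Santorini", "Pelion", "Nemea", "Goumenissa")
  region <- sample(regions, n, replace = TRUE, prob = c(0.10, 0.49, 0.33, 0.08))
  wine_type <- sample(c("red", "white"), n, replace = TRUE, prob = c(0.6, 0.4))
  assays <- do.call(rbind, lapply(seq_len(n), function(i)
    as.data.frame(.code_to_assays(X[i, ]))))
  out <- cbind(data.frame(
    isolate_id = sprintf("I%03d", seq_len(n)),
    sample_id = paste0("S", as.integer(factor(region))),
    region = region,
    variety = ifelse(wine_type == "red", "Xinomavro", "Assyrtiko"),
    wine_type = wine_type,
    vintage = sample(2018:2021, n, replace = TRUE),
    species = species), assays)
  out$true_group <- g
  out$true_code <- apply(X, 1L, paste, collapse = "")
  out
}

#' Generate synthetic free-sorting sheets with a planted consensus
#'
#' Every panelist starts from the consensus partition, then reassigns
#' each wine independently with probability `1 - agreement` to a
#' uniformly chosen other consensus group.
#'
#' @param n_panelists number of panelists.
#' @param consensus named vector mapping wine id to consensus group;
#'   default: 13 wines in four groups of sizes 5, 4, 2 and 2.
#' @param agreement per-wine probability of keeping the consensus
#'   assignment, in \[0, 1\].
#' @param seed integer seed.
#' @return list of named partitions (one per panelist), suitable for
#'   [aggregate_cooccurrence()] and [sensory_clusters()].
#' @export
gen_sorting_panel <- function(n_panelists = 10L,
                              consensus = setNames(rep(LETTERS[1:4], c(5L, 4L, 2L, 2L)),
                                                   sprintf("W%02d", 1:13)),
                              agreement = 0.9, seed = 1L) {
  stopifnot(agreement >= 0, agreement <= 1, !is.null(names(consensus)))
  set.seed(seed)
  labs <- unique(consensus)
  sheets <- lapply(seq_len(n_panelists), function(i) {
    p <- consensus
    move <- runif(length(p)) > agreement
    for (w in which(move))
      p[w] <- sample(setdiff(labs, p[w]), 1L)
    p
  })
  names(sheets) <- sprintf("panelist%02d", seq_len(n_panelists))
  sheets
}

#' Generate synthetic fermentation curves
#'
#' Glucose and fructose decay exponentially from the initial must
#' concentrations at a per-strain rate, with truncated Gaussian
#' measurement noise; slow strains plateau above the dryness threshold.
#'
#' @param rates named numeric vector of per-day decay rates, one per
#'   strain.
#' @param days integer vector of monitored days.
#' @param glucose0,fructose0 initial concentrations in g/L.
#' @param noise_sd measurement noise sd in g/L (truncated at 0).
#' @param replicates number of replicate fermentations per strain.
#' @param seed integer seed.
#' @return long data frame with `strain_id, replicate, day, glucose,
#'   fructose`.
#' @examples
#' fc <- gen_fermentation(c(F1 = 0.5, S1 = 0.05), noise_sd = 0, seed = 1)
#' classify_fermentations(fc)
#' @export
gen_fermentation <- function(rates, days = 0:14, glucose0 = 119.5,
                             fructose0 = 120.1, noise_sd = 1,
                             replicates = 2L, seed = 1L) {
  stopifnot(all(rates > 0), noise_sd >= 0)
  if (is.null(names(rates))) names(rates) <- sprintf("S%d", seq_along(rates))
  set.seed(seed)
  out <- do.call(rbind, lapply(names(rates), function(s) {
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      glc <- glucose0 * exp(-rates[[s]] * days)
      frc <- fructose0 * exp(-rates[[s]] * days)
      data.frame(strain_id = s, replicate = rep, day = days,
                 glucose = pmax(0, glc + stats::rnorm(length(days), 0, noise_sd)),
                 fructose = pmax(0, frc + stats::rnorm(length(days), 0, noise_sd)))
    }))
  }))
  rownames(out) <- NULL
  out
}
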