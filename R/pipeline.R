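#' Run the phenotype preselection workflow end to end
#'
#' Reads an assay CSV, encodes phenotypes, clusters them, selects the
#' number of groups, characterizes every group, and writes the report
#' bundle: `phenotypes.csv` (per-isolate codes), `groups.csv`
#' (phenotype, count, group, color), `dendrogram.nwk` and
#' `report.json`/`report.md`.
#'
#' @param assay_csv path to the assay CSV, see [read_assay_csv()].
#' @param out_dir output directory, created if missing.
#' @param config optional path to a YAML file or a named list overriding
#'   any of `policy`, `weights`, `count_weighted`, `k`, `k_max`,
#'   `allow_killer_positive`.
#' @return the fitted [phenoclust()] object, invisibly.
#' @export
run_preselection <- function(assay_csv, out_dir, config = NULL) {
  cfg <- .load_config(config,
                      defaults = list(policy = "day8", weights = rep(1, 5),
                                      count_weighted = TRUE, k = NULL,
                                      k_max = 10L,
                                      allow_killer_positive = FALSE))
  df <- read_assay_csv(assay_csv)
  coded <- phenotype_codes(df, cfg$policy, cfg$allow_killer_positive)
  fit <- phenoclust(coded, weights = cfg$weights,
                    count_weighted = cfg$count_weighted,
                    k = cfg$k, k_max = cfg$k_max)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(coded[, c("isolate_id", paste0("code_", .digit_names), "phenotype")],
            file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
  palette <- c("yellow", "grey", "green", "pink")
  groups <- data.frame(
    phenotype = names(fit$assignment),
    count = unname(fit$counts),
    group = unname(fit$assignment),
    color = ifelse(fit$assignment <= length(palette),
                   palette[fit$assignment], NA))
  write.csv(groups, file.path(out_dir, "groups.csv"), row.names = FALSE)
  export_newick(fit$tree, file.path(out_dir, "dendrogram.nwk"))
  report <- list(
    n_isolates = sum(fit$counts),
    n_phenotypes = nrow(fit$codes),
    k = fit$k,
    k_rule = if (fit$k_fixed) "fixed" else "largest-gap",
    gap_profile = fit$gap_profile,
    ward_variant = "ward.D2",
    count_weighted = fit$count_weighted,
    group_sizes = as.list(table(fit$isolate_groups)),
    group_profiles = fit$profiles$text,
    penalty = as.list(fit$penalty))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  md <- c("# Phenotype preselection report", "",
          sprintf("- isolates: %d", report$n_isolates),
          sprintf("- distinct phenotypes: %d", report$n_phenotypes),
          sprintf("- groups: k = %d (%s)", report$k, report$k_rule), "",
          "## Group profiles", "",
          paste0("- ", fit$profiles$text))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(fit)
}

#' Validate the phenotypic grouping against fermentation and sensory
#' outcome
#'
#' Reads a strain-outcome table, builds the concordance summary and the
#' favorable-group recommendation, and writes `validation.json` and
#' `validation.md`.
#'
#' @param outcomes_csv path to the outcome CSV, see
#'   [read_outcomes_csv()].
#' @param out_dir output directory.
#' @param desirable desirable sensory groups, see [favorable_groups()].
#' @return the `"concordance"` object, invisibly, with the
#'   recommendation attached as attribute `"favorable"`.
#' @export
run_validation <- function(outcomes_csv, out_dir, desirable = c("A", "B")) {
  outcomes <- read_outcomes_csv(outcomes_csv)
  conc <- concordance_table(outcomes)
  fav <- favorable_groups(conc, desirable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    n_strains = conc$n_strains,
    n_capable = conc$n_capable,
    capacity_rate = conc$capacity_rate,
    n_sensory = conc$n_sensory,
    group_sizes = as.list(conc$group_sizes),
    validation_rate = conc$validation_rate,
    favorable_groups = fav)
  jsonlite::write_json(report, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  md <- c("# Validation report", "",
          sprintf("- strains: %d, with fermentation capacity: %d (%.0f%%)",
                  conc$n_strains, conc$n_capable, 100 * conc$capacity_rate),
          sprintf("- wines in the sensory stage: %d", conc$n_sensory),
          sprintf("- validation rate: %.0f%%", 100 * conc$validation_rate),
          sprintf("- favorable groups: %s",
                  if (length(fav)) paste(fav, collapse = ", ") else "(none)"))
  writeLines(md, file.path(out_dir, "validation.md"))
  attr(conc, "favorable") <- fav
  invisible(conc)
}

.load_config <- function(config, defaults) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    .oeno_stop(paste("unknown config keys:", paste(unknown, collapse = ", ")),
               "oenotype_bad_input")
  utils::modifyList(defaults, config)
}
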