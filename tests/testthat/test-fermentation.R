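tab3_path <- system.file("extdata", "table3_strains.csv", package = "oenotype")

test_that("residual sugar sums the final-day sugars over replicates", {
  curve <- data.frame(day = c(0, 14), glucose = c(119.5, 2),
                      fructose = c(120.1, 6))
  expect_equal(residual_sugar(curve), 8)
  expect_equal(residual_sugar(curve[1, ]), 239.6)  # initial must total
  two_reps <- data.frame(day = c(14, 14), glucose = c(3, 4),
                         fructose = c(5, 6), replicate = 1:2)
  expect_equal(residual_sugar(two_reps), 9)
  expect_error(residual_sugar(curve[0, ]), class = "oenotype_bad_input")
})

test_that("the dryness rule is a monotone threshold with <= boundary", {
  expect_false(fermentation_capacity(12))
  expect_true(fermentation_capacity(8))
  expect_true(fermentation_capacity(10))     # boundary passes
  expect_false(fermentation_capacity(10.01))
  rs <- seq(0, 30, by = 0.5)
  caps <- vapply(rs, fermentation_capacity, logical(1))
  expect_true(all(diff(caps) <= 0))          # monotone in residual sugar
  expect_true(fermentation_capacity(12, threshold = 15))
})

test_that("fermentation curves classify strains by final residual sugar", {
  fc <- gen_fermentation(c(fast = 0.5, slow = 0.05), noise_sd = 0, seed = 1)
  cls <- classify_fermentations(fc)
  expect_equal(cls$capacity[cls$strain_id == "fast"], TRUE)
  expect_equal(cls$capacity[cls$strain_id == "slow"], FALSE)
  expect_equal(cls$residual_sugar[cls$strain_id == "fast"],
               239.6 * exp(-0.5 * 14), tolerance = 1e-10)
})

test_that("the 20-strain validation fixture reproduces every printed summary", {
  out <- read_outcomes_csv(tab3_path)
  conc <- concordance_table(out)
  expect_equal(conc$n_strains, 20L)
  expect_equal(conc$n_capable, 13L)
  expect_equal(conc$capacity_rate, 0.65)
  expect_equal(conc$n_sensory, 13L)
  expect_equal(as.vector(conc$group_sizes[c("1-Yellow", "2-Grey", "3-Green", "4-Pink")]),
               c(5L, 7L, 6L, 2L))
  expect_equal(conc$validation_rate, 1)
  # cross-tab row sums equal the group sizes
  expect_equal(unname(rowSums(conc$crosstab)),
               unname(as.vector(conc$group_sizes)))
})

test_that("favorable groups are those whose wines sort desirably", {
  conc <- concordance_table(read_outcomes_csv(tab3_path))
  expect_equal(favorable_groups(conc), c("2-Grey", "3-Green"))
  # all capable and desirable: the single group is favorable
  one <- data.frame(strain_id = c("X1", "X2"), capacity = TRUE,
                    sensory_group = c("A", "B"),
                    preliminary_group = "2-Grey", validated = TRUE)
  expect_equal(favorable_groups(concordance_table(one)), "2-Grey")
  # no capable strain anywhere: empty recommendation with a warning
  none <- data.frame(strain_id = c("X1", "X2"), capacity = FALSE,
                     sensory_group = "none",
                     preliminary_group = c("1-Yellow", "2-Grey"),
                     validated = TRUE)
  expect_warning(fav <- favorable_groups(concordance_table(none)))
  expect_length(fav, 0)
  # all-capable input has capacity rate 1
  expect_equal(concordance_table(one)$capacity_rate, 1)
})

test_that("region sharing recovers exclusive and ubiquitous strains", {
  inc <- read_incidence_csv(system.file("extdata", "strain_regions_synthetic.csv",
                                        package = "oenotype"))
  sh <- region_sharing(inc)
  expect_equal(sh$in_all, "S10")
  expect_setequal(sh$exclusive$Santorini, c("S15", "S17", "S18"))
  expect_setequal(sh$exclusive$Nemea, c("S11", "S12", "S13"))
  expect_setequal(sh$exclusive$Pelion, c("S1", "S2"))
  # exclusive vs shared partition each region's strains
  for (r in names(sh$exclusive)) {
    members <- inc$strain_id[inc[[r]]]
    shared <- setdiff(members, sh$exclusive[[r]])
    expect_true(all(rowSums(inc[match(shared, inc$strain_id), -1]) > 1))
  }
  # single region: everything is exclusive
  solo <- data.frame(strain_id = c("a", "b"), R1 = c(TRUE, TRUE))
  expect_setequal(region_sharing(solo, regions = "R1")$exclusive$R1, c("a", "b"))
})

test_that("wine-type incidence reproduces the printed strain lists", {
  wt <- read_incidence_csv(system.file("extdata", "strain_wine_types.csv",
                                       package = "oenotype"))
  sh <- region_sharing(wt, regions = character(0))
  expect_setequal(sh$wine_type$both,
                  c(paste0("S", 2:10), "S20"))
  expect_setequal(sh$wine_type$red_only,
                  c("S1", "S11", "S12", "S13", "S14", "S19"))
  expect_setequal(sh$wine_type$white_only, c("S15", "S16", "S17", "S18"))
})

test_that("community richness types follow the strain-count bands", {
  counts <- c(GB = 2, A9 = 1, K29 = 8, K32 = 7, X = 3, Y = 4, Z = 5)
  types <- community_richness(counts)
  expect_equal(unname(types), c(1L, 1L, 3L, 3L, 2L, 2L, 3L))
  expect_equal(names(types), names(counts))
  expect_equal(unname(community_richness(5, breaks = c(2, 5))), 2L)
})
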