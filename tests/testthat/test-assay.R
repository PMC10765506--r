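test_that("digit encoders follow the ordinal coding scheme", {
  expect_identical(encode_killer("neutral"), 1L)
  expect_identical(encode_killer("sensitive"), 2L)
  expect_error(encode_killer("killer_positive"),
               class = "oenotype_unsupported_phenotype")
  expect_identical(encode_killer("killer_positive",
                                 allow_killer_positive = TRUE), 3L)

  expect_identical(encode_acetic("producer"), 0L)
  expect_identical(encode_acetic("non_producer"), 1L)
  expect_identical(encode_bglu("positive"), 0L)
  expect_identical(encode_bglu("negative"), 1L)
  # the two binary digits decode back: bijection on two states
  for (a in c("producer", "non_producer"))
    expect_identical(decode_acetic(encode_acetic(a)), a)
  for (b in c("positive", "negative"))
    expect_identical(decode_bglu(encode_bglu(b)), b)
})

test_that("H2S series collapses by the selected policy", {
  scores <- c("2" = 1, "5" = 2, "8" = 3)
  expect_identical(encode_h2s(c("2" = 0, "5" = 0, "8" = 0)), 0L)
  expect_identical(encode_h2s(scores, policy = "day8"), 3L)
  expect_identical(encode_h2s(scores, policy = "max"), 3L)
  expect_identical(encode_h2s(c("2" = 0, "5" = 3, "8" = 1), policy = "max"), 3L)
  expect_identical(encode_h2s(scores, policy = "mean"), 2L)
  expect_error(encode_h2s(c("2" = 1, "5" = 2)),
               class = "oenotype_incomplete_assay")
  expect_error(encode_h2s(c("2" = 1, "5" = 2, "8" = 5)),
               class = "oenotype_incomplete_assay")
})

test_that("SO2 digit comes from the highest dose with growth", {
  doses <- c(0, 100, 200, 300, 400, 500)
  grow_to <- function(top) setNames(doses <= top, doses)
  expect_identical(encode_so2(grow_to(300)), 1L)
  expect_identical(encode_so2(grow_to(500)), 2L)
  expect_identical(encode_so2(grow_to(400)), 2L)
  expect_identical(encode_so2(grow_to(0)), 0L)
  expect_identical(encode_so2(grow_to(100)), 1L)
  # non-monotone plate artifact: warn, code from the highest growth dose
  odd <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), doses)
  expect_warning(d <- encode_so2(odd), "non-monotone")
  expect_identical(d, 2L)
  expect_error(encode_so2(setNames(c(FALSE, rep(TRUE, 5)), doses)),
               class = "oenotype_incomplete_assay")
})

test_that("whole panels encode digit-wise in priority order", {
  p1 <- example_panel(killer = "neutral", h2s = c(0, 1, 1),
                      acetic = "producer", so2_top = 500, bglu = "negative")
  expect_identical(unname(encode_phenotype(p1)), c(1L, 1L, 0L, 2L, 1L))
  p2 <- example_panel(killer = "sensitive", h2s = c(0, 0, 0),
                      acetic = "non_producer", so2_top = 0, bglu = "positive")
  expect_identical(unname(encode_phenotype(p2)), c(2L, 0L, 1L, 0L, 0L))
  # encoding is a pure function of the panel
  expect_identical(encode_phenotype(p1), encode_phenotype(p1))
})

test_that("encoded digits always satisfy the ordinal range invariants", {
  set.seed(42)
  doses <- c(0, 100, 200, 300, 400, 500)
  lo <- c(1, 0, 0, 0, 0); hi <- c(2, 3, 1, 2, 1)
  for (i in 1:50) {
    p <- example_panel(
      killer = sample(c("neutral", "sensitive"), 1),
      h2s = sort(sample(0:3, 3, replace = TRUE)),
      acetic = sample(c("producer", "non_producer"), 1),
      so2_top = sample(doses, 1),
      bglu = sample(c("positive", "negative"), 1))
    code <- encode_phenotype(p, policy = sample(c("day8", "max", "mean"), 1))
    expect_true(all(code >= lo & code <= hi))
  }
})

test_that("distinct phenotypes are counted with multiplicities", {
  codes <- rbind(c(1, 0, 0, 2, 1), c(1, 0, 0, 2, 1), c(2, 0, 0, 2, 1))
  ph <- distinct_phenotypes(codes)
  expect_equal(nrow(ph), 2L)
  expect_equal(sort(ph$count), c(1L, 2L))
  expect_equal(sum(ph$count), 3L)

  same <- matrix(rep(c(1, 1, 0, 2, 1), 5), ncol = 5, byrow = TRUE)
  expect_equal(nrow(distinct_phenotypes(same)), 1L)
  expect_error(distinct_phenotypes(matrix(integer(0), ncol = 5)),
               class = "oenotype_empty_dataset")

  # multiplicities always sum to input size, order independent
  set.seed(7)
  X <- default_prototypes()[sample(1:4, 40, replace = TRUE), ]
  ph <- distinct_phenotypes(X)
  expect_equal(sum(ph$count), 40L)
  ph2 <- distinct_phenotypes(X[sample(40), ])
  expect_identical(ph, ph2)

  # zero-noise panel from 4 prototypes holds exactly 4 phenotypes
  panel <- gen_isolate_panel(n = 60, flip_prob = 0, seed = 3)
  expect_equal(nrow(distinct_phenotypes(phenotype_codes(panel))), 4L)
})

test_that("the assay CSV dialect round-trips through encoding", {
  panel <- gen_isolate_panel(n = 25, seed = 11)
  tmp <- tempfile(fileext = ".csv")
  write.csv(panel[, setdiff(names(panel), c("true_group", "true_code"))],
            tmp, row.names = FALSE)
  df <- read_assay_csv(tmp)
  coded <- phenotype_codes(df)
  expect_equal(coded$phenotype, panel$true_code)
  # malformed input is rejected with diagnostics
  df2 <- df; df2$killer <- NULL
  tmp2 <- tempfile(fileext = ".csv")
  write.csv(df2, tmp2, row.names = FALSE)
  expect_error(read_assay_csv(tmp2), "killer",
               class = "oenotype_bad_input")
  df3 <- df; df3$isolate_id[2] <- df3$isolate_id[1]
  write.csv(df3, tmp2, row.names = FALSE)
  expect_error(read_assay_csv(tmp2), class = "oenotype_bad_input")
})
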