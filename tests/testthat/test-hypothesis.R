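test_that("predicted observables encode the discriminating facts", {
  py <- predict_observables("HY", "long_arm")
  cell <- function(tab, sex, km) tab[tab$sex == sex & tab$karyomorph == km, ]
  expect_false(cell(py, "female", "V")$realizable)
  expect_false(cell(py, "female", "III")$realizable)
  expect_true(cell(py, "female", "II")$realizable)
  px_short <- predict_observables("HX", "short_arm")
  expect_equal(cell(px_short, "female", "IV")$copy_numbers[[1]], 2L)
  expect_equal(cell(px_short, "male", "IV")$copy_numbers[[1]], 2L)
  px <- predict_observables("HX", "long_arm")
  expect_equal(cell(px, "male", "I")$distinct_counts[[1]], 2L)
  expect_equal(cell(px, "male", "I")$label_multisets[[1]], "Xn/Y")
})

test_that("a cohort scores perfectly against its generating candidate", {
  co <- simulate_cohort(locus_config(seed = 6), cohort_config(seed = 6))
  s <- consistency_score(co, "HX", "long_arm")
  expect_equal(s$score, 1)
  expect_equal(nrow(s$violations), 0L)
})

test_that("scoring an HX cohort against HY lists every rearranged female", {
  co <- simulate_cohort(locus_config(seed = 6), cohort_config(seed = 6))
  s <- consistency_score(co, "HY", "long_arm")
  expect_lt(s$score, 1)
  rf <- co$individuals$id[co$individuals$category == "rearranged_female"]
  expect_true(all(rf %in% s$violations$id))
  expect_gte(s$hard_violations, length(rf))
})

test_that("short-arm placement is penalized exactly for types II, III and V", {
  co <- simulate_cohort(locus_config(seed = 7), cohort_config(seed = 7))
  s <- consistency_score(co, "HX", "short_arm")
  ind <- co$individuals
  bad <- ind$id[ind$karyomorph %in% c("II", "III", "V")]
  ok <- ind$id[ind$karyomorph %in% c("I", "IV")]
  expect_setequal(s$violations$id, bad)
  expect_false(any(ok %in% s$violations$id))
})

test_that("a karyomorph-V female violates HY regardless of haplotypes", {
  row <- data.frame(id = "x1", sex = "female", karyomorph = "V",
                    hap1 = "Xn", hap2 = "Xn")
  s <- consistency_score(row, "HY", "long_arm")
  expect_equal(s$score, 0)
  expect_equal(s$violations$rule, "unrealizable_karyomorph")
})

test_that("the generating candidate uniquely wins discrimination", {
  co <- simulate_cohort(locus_config(seed = 8), cohort_config(seed = 8))
  r <- discriminate(co)
  expect_equal(r$winner, "HX:long_arm")
  expect_equal(r$table$score[1], 1)
  expect_true(all(r$table$score[-1] < 1))
})

test_that("adding a violating individual never increases a score", {
  co <- simulate_cohort(locus_config(seed = 9), cohort_config(seed = 9))
  base <- consistency_score(co, "HY", "long_arm")
  df <- karyotrans:::.as_scored_cohort(co)
  df2 <- rbind(df, data.frame(id = "extra", sex = "female",
                              karyomorph = "V", hap1 = "Xr", hap2 = "Xn"))
  worse <- consistency_score(df2, "HY", "long_arm")
  expect_lte(worse$score, base$score)
})

test_that("individuals with missing metadata are excluded and reported", {
  co <- simulate_cohort(locus_config(seed = 10), cohort_config(seed = 10))
  df <- karyotrans:::.as_scored_cohort(co)
  df$hap1[3] <- NA
  s <- consistency_score(df, "HX", "long_arm")
  expect_equal(s$excluded, df$id[3])
  expect_equal(s$n_total, nrow(df) - 1L)
})

test_that("an empty cohort produces an explicit empty report", {
  empty <- data.frame(id = character(0), sex = character(0),
                      karyomorph = character(0), hap1 = character(0),
                      hap2 = character(0))
  r <- discriminate(empty)
  expect_true(r$empty)
  expect_length(r$winner, 0L)
  expect_true(all(is.na(r$table$score)))
  expect_error(discriminate(empty, candidates = list()), "at least one")
})
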