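test_that("chromosome forms carry the fixed segment multisets", {
  expect_setequal(segments_of("M"), c("S1q", "S1p"))
  expect_equal(segments_of("T"), "S1q")
  expect_equal(segments_of("m"), "S6")
  expect_setequal(segments_of("St"), c("S6", "S1p"))
  expect_error(segments_of("Q"), "unknown chromosome form")
})

test_that("karyomorph classification covers all form combinations exactly once", {
  expect_equal(classify_karyomorph(geno_II_f), "II")
  expect_equal(classify_karyomorph(geno_V_m), "V")
  expect_equal(classify_karyomorph("T/T;St/St|X,X"), "OTHER")
  # totality: every chr1 pair x chr6 pair classifies into exactly one value
  chr1_pairs <- list(c("M", "M"), c("M", "T"), c("T", "T"))
  chr6_pairs <- list(c("m", "m"), c("m", "St"), c("St", "St"))
  seen <- character(0)
  for (p1 in chr1_pairs) for (p6 in chr6_pairs) {
    km <- classify_karyomorph(genotype(p1, c("X", "X"), p6))
    expect_true(km %in% c("I", "II", "III", "IV", "V", "OTHER"))
    seen <- c(seen, km)
  }
  expect_setequal(seen, c("I", "II", "III", "IV", "V", "OTHER"))
  expect_equal(sum(seen %in% c("I", "II", "III", "IV", "V")), 5L)
})

test_that("classification ignores within-pair order and sex alleles", {
  expect_equal(classify_karyomorph(genotype(c("T", "M"), c("X", "X"),
                                            c("St", "m"))), "IV")
  expect_equal(classify_karyomorph(genotype(c("M", "T"), c("Y", "X"),
                                            c("m", "St"))), "IV")
})

test_that("sex is determined by a dominant Y", {
  expect_equal(sex_of(geno_I_m), "male")
  expect_equal(sex_of("M/T;m/St|Xn,Xr"), "female")
  expect_equal(sex_of(genotype(c("M", "T"), c("X", "Y"), c("m", "St"))),
               "male")  # HY-style carrier: Y rides on T
})

test_that("genotype construction rejects malformed input", {
  expect_error(genotype(c("M", "m"), c("X", "X"), c("m", "m")),
               "chromosome-1 forms")
  expect_error(genotype(c("M", "M"), c("Y", "Y"), c("m", "m")),
               "at most one Y")
  expect_error(parse_genotype("M/T;m/St"), "malformed")
  expect_error(parse_genotype("M/T;m/St|X,Z"), "allele")
})

test_that("genotype strings round-trip", {
  for (s in c(geno_I_f, geno_I_m, geno_IV_f, geno_V_m)) {
    expect_identical(format_genotype(parse_genotype(s)), s)
  }
  # class labels map onto the underlying alleles
  g <- parse_genotype("M/T;m/St|Xn,Xr")
  expect_identical(format_genotype(g), "M/T;m/St|X,X")
})

test_that("a type-IV heterozygote makes four distinct gametes, homozygotes fewer", {
  g4 <- gametes(geno_IV_f)
  expect_length(g4, 4L)
  keys <- vapply(g4, function(g)
    paste0(g$chr1$form, "+", g$chr6$form), "")
  expect_setequal(keys, c("M+m", "M+St", "T+m", "T+St"))
  expect_length(gametes(geno_I_f), 1L)
  expect_length(gametes(geno_V_f), 2L)
})

test_that("alternate-only segregation keeps the balanced gametes of a full heterozygote", {
  g2 <- gametes(geno_IV_f, "alternate_only")
  keys <- vapply(g2, function(g) paste0(g$chr1$form, "+", g$chr6$form), "")
  expect_setequal(keys, c("M+m", "T+St"))
  # non-heterozygotes fall back to the default model
  expect_length(gametes(geno_V_f, "alternate_only"), 2L)
})

test_that("gamete segments are conserved", {
  # double heterozygote: distinct gametes sum to 2x the genotype's segments
  expect_equal(gamete_segment_counts(gametes(geno_IV_f)),
               2L * c(S1q = 2L, S1p = 2L, S6 = 2L))
  # homozygote: the single gamete carries half the genotype's segments
  expect_equal(gamete_segment_counts(gametes(geno_I_f)),
               c(S1q = 1L, S1p = 1L, S6 = 1L))
})

test_that("founders seed the translocation once, in the hypothesis-dependent sex", {
  fx <- make_founders("HX")
  expect_equal(sex_of(fx$translocation_carrier), "female")
  fy <- make_founders("HY")
  expect_equal(sex_of(fy$translocation_carrier), "male")
  for (f in list(fx, fy)) {
    expect_equal(classify_karyomorph(f$wildtype_female), "I")
    expect_equal(classify_karyomorph(f$wildtype_male), "I")
    expect_equal(classify_karyomorph(f$translocation_carrier), "IV")
    # the translocation is seeded exactly once, and both sexes are present
    n_T <- vapply(f, function(g)
      sum(vapply(g$chr1, `[[`, "", "form") == "T"), 0L)
    expect_equal(sum(n_T), 1L)
    sexes <- vapply(f, sex_of, "")
    expect_gte(sum(sexes == "male"), 1L)
    expect_gte(sum(sexes == "female"), 1L)
  }
  # under HX the single carrier is female, so the wild-type male is the
  # only male founder
  expect_equal(sum(vapply(fx, sex_of, "") == "male"), 1L)
})

test_that("nullisomy lethality flags genotypes missing a segment", {
  expect_false(is_viable("T/T;m/m|X,X"))          # S1p count 0
  expect_true(is_viable("M/M;St/St|X,X"))          # OTHER but no nullisomy
  expect_true(is_viable("T/T;m/m|X,X", "all_viable"))
  for (s in c(karyomorph_reps_female, geno_I_m, geno_V_m)) {
    expect_true(is_viable(s))
    expect_true(is_viable(s, "all_viable"))
  }
})
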