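test_that("wild-type crosses breed true with a 1:1 sex ratio", {
  cr <- cross(geno_I_f, geno_I_m)
  expect_true(all(cr$offspring$karyomorph == "I"))
  expect_equal(sum(cr$offspring$probability), 1)
  sex_p <- tapply(cr$offspring$probability, cr$offspring$sex, sum)
  expect_equal(as.numeric(sex_p[c("female", "male")]), c(0.5, 0.5))
})

test_that("carrier x wild-type crosses spread the rearrangement to both sexes", {
  # HX: type IV female x type I male
  cr <- cross(geno_IV_f, geno_I_m)
  expect_setequal(unique(cr$offspring$karyomorph), c("I", "II", "III", "IV"))
  for (km in c("I", "II", "III", "IV")) {
    sexes <- cr$offspring$sex[cr$offspring$karyomorph == km]
    expect_setequal(sexes, c("female", "male"))
  }
})

test_that("under HY daughters never inherit the translocated chromosome", {
  # HY: type I female x type IV male (T carries Y)
  hy_IV_m <- genotype(c("M", "T"), c("X", "Y"), c("m", "St"))
  cr <- cross(geno_I_f, hy_IV_m)
  dtr <- cr$offspring[cr$offspring$sex == "female", ]
  son <- cr$offspring[cr$offspring$sex == "male", ]
  expect_setequal(dtr$karyomorph, c("I", "II"))
  expect_setequal(son$karyomorph, c("III", "IV"))
  expect_false(any(grepl("T", dtr$genotype, fixed = TRUE)))
})

test_that("probabilities stay normalized through viability filtering", {
  cr <- cross(geno_IV_f, geno_IV_m)
  expect_gt(cr$dropped, 0)  # T/T;m/m offspring are nullisomic
  expect_equal(sum(cr$offspring$probability), 1)
  cr2 <- cross(geno_IV_f, geno_IV_m, viability_rule = "all_viable")
  expect_equal(cr2$dropped, 0)
  expect_equal(sum(cr2$offspring$probability), 1)
})

test_that("crosses reject same-sex parents and bad sample sizes", {
  expect_error(cross(geno_I_f, geno_I_f), "invalid cross")
  expect_error(cross(geno_I_m, geno_I_m), "invalid cross")
  expect_error(sample_progeny(geno_I_f, geno_I_m, 0), "n")
})

test_that("sampled progeny follow the exact cross distribution", {
  off <- sample_progeny(geno_I_f, geno_I_m, 50, seed = 1)
  expect_length(off, 50L)
  expect_true(all(vapply(off, classify_karyomorph, "") == "I"))
  # reproducibility
  off2 <- sample_progeny(geno_I_f, geno_I_m, 50, seed = 1)
  expect_identical(names(off), names(off2))
  # empirical frequencies vs exact probabilities (3 binomial SEs)
  n <- 4000L
  cr <- cross(geno_IV_f, geno_IV_m)
  off3 <- sample_progeny(geno_IV_f, geno_IV_m, n, seed = 7)
  freq <- table(factor(names(off3), levels = cr$offspring$genotype)) / n
  for (i in seq_len(nrow(cr$offspring))) {
    p <- cr$offspring$probability[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[[cr$offspring$genotype[i]]] - p), 3 * se + 1e-12)
  }
})

test_that("reachable karyomorph sets discriminate the hypotheses", {
  rx <- reachable_karyomorphs("HX")
  expect_setequal(rx$female_karyomorphs, c("I", "II", "III", "IV", "V"))
  expect_setequal(rx$male_karyomorphs, c("I", "II", "III", "IV", "V"))
  ry <- reachable_karyomorphs("HY")
  expect_setequal(ry$female_karyomorphs, c("I", "II"))
  expect_setequal(ry$male_karyomorphs, c("I", "II", "III", "IV", "V"))
  expect_lte(rx$generations_to_fixpoint, 4L)
  expect_lte(ry$generations_to_fixpoint, 4L)
})

test_that("reachable sets grow monotonically to the fixpoint", {
  for (hyp in c("HX", "HY")) {
    r <- reachable_karyomorphs(hyp)
    gens <- r$per_generation
    for (i in seq_len(length(gens) - 1L)) {
      expect_true(all(gens[[i]]$female %in% gens[[i + 1L]]$female))
      expect_true(all(gens[[i]]$male %in% gens[[i + 1L]]$male))
    }
  }
})

test_that("no female in the HY closure ever carries a T chromosome", {
  ry <- reachable_karyomorphs("HY")
  for (g in ry$genotypes) {
    if (sex_of(g) == "female") {
      forms <- vapply(g$chr1, `[[`, "", "form")
      expect_false("T" %in% forms)
    }
  }
})

test_that("under HX every reachable karyomorph is realized by both sexes", {
  rx <- reachable_karyomorphs("HX")
  km <- vapply(rx$genotypes, classify_karyomorph, "")
  sx <- vapply(rx$genotypes, sex_of, "")
  for (k in intersect(unique(km), c("I", "II", "III", "IV", "V"))) {
    expect_setequal(unique(sx[km == k]), c("female", "male"))
  }
})
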