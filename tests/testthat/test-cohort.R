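test_that("default references realize the configured lengths and variable sites", {
  refs <- build_reference_haplotypes(locus_config(seed = 1))
  len <- nchar(refs$sequences)
  expect_equal(abs(len[["Xn"]] - len[["Xr"]]), 6L)
  d_xy <- abs(len[["Xn"]] - len[["Y"]])
  expect_equal(d_xy, 31L)
  expect_gte(d_xy, 27L); expect_lte(d_xy, 35L)
  vs <- count_variable_sites(refs$alignment, refs$repeat_region)
  expect_equal(vs[["total"]], 47L)
  expect_gte(vs[["repeat_region"]], 4L); expect_lte(vs[["repeat_region"]], 6L)
  expect_gte(vs[["flanking"]], 41L); expect_lte(vs[["flanking"]], 43L)
})

test_that("the generator is constructive across seeds, not rejection-sampled", {
  for (s in c(2, 17, 99)) {
    refs <- build_reference_haplotypes(locus_config(seed = s))
    len <- nchar(refs$sequences)
    expect_equal(abs(len[["Xn"]] - len[["Xr"]]), 6L)
    expect_equal(abs(len[["Xn"]] - len[["Y"]]), 31L)
    vs <- count_variable_sites(refs$alignment, refs$repeat_region)
    expect_equal(vs[["total"]], 47L)
  }
  # same seed: byte-identical; different seed: different flanking sequence
  a <- build_reference_haplotypes(locus_config(seed = 5))
  b <- build_reference_haplotypes(locus_config(seed = 5))
  expect_identical(a$alignment, b$alignment)
  c <- build_reference_haplotypes(locus_config(seed = 6))
  expect_false(identical(a$alignment, c$alignment))
})

test_that("locus configuration rejects inconsistent settings", {
  expect_error(locus_config(xy_length_diff = 20), "27")
  expect_error(locus_config(xn_xr_length_diff = 5), "even")
  expect_error(locus_config(xr_substitutions = 42), "fewer")
  expect_error(locus_config(repeat_unit = "CAG"), "2 bp")
})

test_that("the default cohort matches the sampling design", {
  co <- simulate_cohort(locus_config(seed = 1), cohort_config(seed = 1))
  ind <- co$individuals
  expect_equal(nrow(ind), 74L)
  expect_equal(nrow(co$records), 148L)
  expect_equal(sum(ind$category == "normal_female"), 12L)
  expect_equal(sum(ind$category == "normal_male"), 12L)
  expect_equal(sum(ind$category == "rearranged_female"), 33L)
  expect_equal(sum(ind$category == "rearranged_male"), 17L)
  expect_equal(length(unique(ind$population)), 13L)
  # normal karyotype iff type I
  expect_true(all(ind$karyomorph[startsWith(ind$category, "normal")] == "I"))
  expect_true(all(ind$karyomorph[startsWith(ind$category, "rearranged")]
                  %in% c("III", "IV", "V")))
})

test_that("allele classes follow the marker model's haplotype profiles", {
  co <- simulate_cohort(locus_config(seed = 2), cohort_config(seed = 3))
  ind <- co$individuals
  for (i in seq_len(nrow(ind))) {
    prof <- haplotype_profile(ind$genotype[i], co$cohort_config$hypothesis)
    cls <- co$records$class[co$records$id == ind$id[i]]
    expect_setequal(cls, prof$classes)
  }
  # headline patterns: normal females one haplotype class, males two
  nf <- ind$id[ind$category == "normal_female"]
  for (id in nf)
    expect_equal(unique(co$records$class[co$records$id == id]), "Xn")
  males <- ind$id[ind$sex == "male"]
  for (id in males)
    expect_length(unique(co$records$class[co$records$id == id]), 2L)
  rf <- ind$id[ind$category == "rearranged_female"]
  for (id in rf)
    expect_length(unique(co$records$class[co$records$id == id]), 2L)
})

test_that("unrealizable categories error with the category named", {
  expect_error(
    simulate_cohort(locus_config(seed = 1),
                    cohort_config(rearranged_females = 2, hypothesis = "HY",
                                  seed = 1)),
    "rearranged_female")
  # type II females are realizable under HY
  co <- simulate_cohort(
    locus_config(seed = 1),
    cohort_config(rearranged_females = 3, rearranged_males = 2,
                  rearranged_karyomorph_weights = c(II = 1),
                  hypothesis = "HY", seed = 1))
  rf <- co$individuals[co$individuals$category == "rearranged_female", ]
  expect_true(all(rf$karyomorph == "II"))
})

test_that("FASTA output round-trips with schema-parsed headers", {
  co <- simulate_cohort(locus_config(seed = 1),
                        cohort_config(normal_females = 3, normal_males = 3,
                                      rearranged_females = 4,
                                      rearranged_males = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(co, path)
  back <- read_fasta(path)
  expect_equal(back$header, co$records$header)
  expect_equal(back$sequence, co$records$sequence)
  expect_equal(back$sex, co$records$sex)
  expect_equal(back$karyomorph, co$records$karyomorph)
  h <- parse_fasta_header("QB012_1_M_IV")
  expect_equal(h$id, "QB012")
  expect_equal(h$allele_index, 1L)
  expect_equal(h$sex, "male")
  expect_equal(h$karyomorph, "IV")
  expect_error(parse_fasta_header("QB012_1_M"), "malformed")
  expect_error(parse_fasta_header("QB012_3_M_IV"), "allele")
})

test_that("variable-site counting handles trivial and malformed alignments", {
  ident <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGT", "")[[1]])
  expect_equal(count_variable_sites(ident)[["total"]], 0L)
  # gap-only difference is not a variable site
  gapped <- rbind(a = c("A", "C", "G"), b = c("A", "-", "G"))
  expect_equal(count_variable_sites(gapped)[["total"]], 0L)
  expect_error(count_variable_sites(c("ACGT", "ACG")), "unequal")
})
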