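# A tiny alignment with three clearly separated haplotype groups and
# duplicated identical sequences inside each group.
tiny_alignment <- function() {
  base <- rep(c("A", "C"), 30)  # 60 columns
  g1 <- base
  g2 <- base; g2[seq(2, 30, by = 4)] <- "G"   # 8 diagnostic columns
  g3 <- base; g3[seq(31, 60, by = 2)] <- "T"  # 15 diagnostic columns
  aln <- rbind(g1, g1, g1, g2, g2, g3, g3, g3, g3)
  rownames(aln) <- c("n1", "n2", "n3", "r1", "r2", "y1", "y2", "y3", "y4")
  aln
}

test_that("duplicated identical sequences give full bootstrap support for their clade", {
  aln <- tiny_alignment()
  tree <- nj_tree(distance_matrix(aln))
  sup <- bootstrap_support(aln, tree, n_replicates = 50, seed = 1)
  part <- extract_k_clades(tree, 3, sup)
  expect_setequal(lapply(part$groups, sort),
                  list(c("n1", "n2", "n3"), c("r1", "r2"),
                       c("y1", "y2", "y3", "y4")))
  # every within-group pair is identical, so each group's bipartition is in
  # every replicate
  meta <- data.frame(leaf = rownames(aln),
                     sex = c("female", "female", "female", "female",
                             "female", "male", "male", "male", "male"),
                     category = c("normal", "normal", "normal",
                                  "rearranged", "rearranged", "normal",
                                  "normal", "rearranged", "rearranged"))
  fit <- infer_haplogroups(aln, meta, n_replicates = 50, seed = 1)
  expect_true(all(fit$clade_support == 1))
})

test_that("a single bootstrap replicate yields 0/1 supports", {
  aln <- tiny_alignment()
  sup <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  expect_true(all(sup$support %in% c(0, 1)))
})

test_that("bootstrap supports are invariant to leaf order", {
  aln <- tiny_alignment()
  meta <- data.frame(leaf = rownames(aln),
                     sex = rep(c("female", "male"), c(5, 4)),
                     category = rep(c("normal", "rearranged", "normal",
                                      "rearranged"), c(3, 2, 2, 2)))
  fit1 <- infer_haplogroups(aln, meta, n_replicates = 40, seed = 9)
  perm <- c(5, 9, 1, 7, 3, 2, 8, 4, 6)
  fit2 <- infer_haplogroups(aln[perm, ], meta, n_replicates = 40, seed = 9)
  expect_equal(fit1$clade_support, fit2$clade_support)
  a1 <- fit1$assignments[order(fit1$assignments$leaf), ]
  a2 <- fit2$assignments[order(fit2$assignments$leaf), ]
  expect_equal(a1$clade, a2$clade)
})

test_that("clade extraction on a designed caterpillar returns the designed groups", {
  tr <- ape::read.tree(
    text = "((a1:0.1,a2:0.1):1.0,(b1:0.1,b2:0.1):1.2,(c1:0.1,c2:0.1):1.4);")
  part <- extract_k_clades(tr, 3)
  expect_setequal(lapply(part$groups, sort),
                  list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")))
  # a pure star has no internal edges at all
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_error(extract_k_clades(star, 3), "partition failure")
})

test_that("composition labelling identifies Y, Xr and Xn and fails informatively", {
  co <- simulate_cohort(locus_config(seed = 4), cohort_config(seed = 4))
  fit <- infer_haplogroups(co$alignment, cohort_leaf_meta(co))
  meta <- cohort_leaf_meta(co)
  truth <- meta$class[match(fit$assignments$leaf, meta$leaf)]
  expect_equal(fit$assignments$clade, truth)
  # the Y clade must contain both normal and rearranged males; the Xn clade
  # contains no rearranged males (they all carry Y + Xr)
  ycat <- meta$category[match(fit$partition$groups$Y, meta$leaf)]
  expect_setequal(unique(ycat), c("normal", "rearranged"))
  xn_leaves <- fit$partition$groups$Xn
  xn_sex <- meta$sex[match(xn_leaves, meta$leaf)]
  xn_cat <- meta$category[match(xn_leaves, meta$leaf)]
  expect_false(any(xn_sex == "male" & xn_cat == "rearranged"))
  # normal-karyotype-only cohort: no rearranged-only group exists
  co2 <- simulate_cohort(locus_config(seed = 5),
                         cohort_config(normal_females = 6, normal_males = 6,
                                       rearranged_females = 0,
                                       rearranged_males = 0, seed = 5))
  expect_error(infer_haplogroups(co2$alignment, cohort_leaf_meta(co2)),
               "labelling failure")
})
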