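# Marker-dosage arm localization and per-genotype haplotype-class profiles.

#' Marker copy number under an arm placement
#'
#' Counts how many copies of the arm segment carrying the marker a genotype
#' has: `"long_arm"` counts `S1q` copies (where the sex-linked locus
#' resides), `"short_arm"` counts `S1p` copies (which the translocation
#' moves onto chromosome 6). Across karyomorphs I--V the short-arm counts
#' are 2, 3, 1, 2, 3 while the long-arm count is always 2 — the dosage
#' argument that places the sex-linked marker on the long arm.
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @param location `"long_arm"` or `"short_arm"`.
#' @return Integer copy number.
#' @examples
#' marker_copy_number("M/M;m/St|X,X", "short_arm")  # 3 (type II)
#' marker_copy_number("M/T;m/m|X,Y", "short_arm")   # 1 (type III)
#' @export
marker_copy_number <- function(genotype,
                               location = c("long_arm", "short_arm")) {
  location <- match.arg(location)
  seg <- if (location == "long_arm") "S1q" else "S1p"
  unname(segment_counts(genotype)[seg])
}

#' Haplotype-class profile at the sex-linked locus
#'
#' Each S1q-bearing chromosome contributes one haplotype class: under
#' `"HX"`, `M(X)` is `Xn`, `T(X)` is `Xr` and `M(Y)` is `Y`; under `"HY"`,
#' `M(X)` is `Xn`, `M(Y)` is `Yn` and `T(Y)` is `Yr`. Only the long-arm
#' placement supports class profiles (the short-arm argument is dosage
#' based; use [marker_copy_number()] there).
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @param hypothesis `"HX"` or `"HY"`.
#' @return List with `classes` (length-2 character, pair order), `labels`
#'   (the hypothesis-independent observable clade labels `Xn`/`Xr`/`Y`) and
#'   `distinct` (number of distinct classes).
#' @examples
#' haplotype_profile("M/T;m/St|X,X", "HX")$classes  # "Xn" "Xr"
#' @export
haplotype_profile <- function(genotype, hypothesis = c("HX", "HY")) {
  hypothesis <- match.arg(hypothesis)
  g <- as_genotype(genotype)
  classes <- vapply(g$chr1, function(ch)
    hap_class(ch$form, ch$allele, hypothesis), "")
  labels <- vapply(g$chr1, function(ch)
    observable_label(ch$form, ch$allele), "")
  list(classes = classes, labels = labels,
       distinct = length(unique(classes)))
}

#' Predicted distinct haplotype counts for a sex/karyomorph combination
#'
#' Enumerates all genotypes reachable under the hypothesis (via
#' [reachable_karyomorphs()]) with the given sex and karyomorph and returns
#' the set of distinct-haplotype counts they admit at the long-arm locus.
#'
#' @param sex `"female"` or `"male"`.
#' @param karyomorph One of `"I"` .. `"V"`.
#' @param hypothesis `"HX"` or `"HY"`.
#' @param viability_rule Passed to the closure.
#' @return Sorted integer vector of possible distinct counts. Errors for an
#'   unrealizable combination (e.g. female type V under `"HY"`).
#' @examples
#' expected_distinct_haplotypes("female", "I", "HX")   # 1
#' expected_distinct_haplotypes("male", "III", "HX")   # 2
#' @export
expected_distinct_haplotypes <- function(sex = c("female", "male"),
                                         karyomorph,
                                         hypothesis = c("HX", "HY"),
                                         viability_rule = "nullisomy_lethal") {
  sex <- match.arg(sex)
  hypothesis <- match.arg(hypothesis)
  if (!karyomorph %in% .KARYOMORPHS)
    stop("'karyomorph' must be one of ", paste(.KARYOMORPHS, collapse = ", "),
         call. = FALSE)
  gl <- reachable_genotypes(sex, karyomorph, hypothesis, viability_rule)
  sort(unique(vapply(gl, function(g)
    haplotype_profile(g, hypothesis)$distinct, 0L)))
}
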