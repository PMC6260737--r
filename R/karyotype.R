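# Chromosome forms of the chr1/chr6 reciprocal translocation system:
#   M  metacentric chromosome 1          {S1q, S1p}, centromere chr1
#   T  telocentric chromosome 1 derivate {S1q},      centromere chr1
#   m  normal chromosome 6               {S6},       centromere chr6
#   St sub-telocentric chr6 derivate     {S6, S1p},  centromere chr6
# S1q carries the sex-determining region and the sex-linked locus.

.FORMS <- list(
  M  = list(segments = c("S1q", "S1p"), centromere = "chr1"),
  T  = list(segments = "S1q",           centromere = "chr1"),
  m  = list(segments = "S6",            centromere = "chr6"),
  St = list(segments = c("S6", "S1p"),  centromere = "chr6")
)
.SEGMENTS <- c("S1q", "S1p", "S6")
.KARYOMORPHS <- c("I", "II", "III", "IV", "V")
.HYPOTHESES <- c("HX", "HY")

#' Segment content of a chromosome form
#'
#' Returns the translocation-segment multiset carried by one of the four
#' chromosome forms of the system: the metacentric chromosome 1 (`"M"`), the
#' telocentric translocated chromosome 1 (`"T"`), the normal chromosome 6
#' (`"m"`) and the sub-telocentric translocated chromosome 6 (`"St"`).
#'
#' @param form Character scalar, one of `"M"`, `"T"`, `"m"`, `"St"`.
#' @return Character vector of segment identifiers among `"S1q"` (long arm of
#'   chromosome 1 plus its centromere), `"S1p"` (short arm of chromosome 1)
#'   and `"S6"` (chromosome 6 material).
#' @examples
#' segments_of("M")
#' segments_of("St")
#' @export
segments_of <- function(form) {
  if (!is.character(form) || length(form) != 1L || !form %in% names(.FORMS))
    stop("unknown chromosome form; expected one of ",
         paste(names(.FORMS), collapse = ", "), call. = FALSE)
  .FORMS[[form]]$segments
}

#' Construct a diploid genotype of the translocation system
#'
#' A genotype holds two chromosome-1-centromere chromosomes (forms `M`/`T`,
#' each carrying a sex allele `X` or `Y` on its long arm) and two
#' chromosome-6-centromere chromosomes (forms `m`/`St`). At most one
#' chromosome may carry `Y` (XX/XY system).
#'
#' @param chr1_forms Length-2 character vector over `c("M","T")`.
#' @param chr1_alleles Length-2 character vector over `c("X","Y")`, the sex
#'   alleles riding on the corresponding chromosome-1 forms.
#' @param chr6_forms Length-2 character vector over `c("m","St")`.
#' @return An object of class `qb_genotype`.
#' @seealso [parse_genotype()], [classify_karyomorph()], [gametes()]
#' @examples
#' genotype(c("M", "T"), c("X", "X"), c("m", "St"))  # type IV female carrier
#' @export
genotype <- function(chr1_forms, chr1_alleles, chr6_forms) {
  if (length(chr1_forms) != 2L || length(chr1_alleles) != 2L ||
      length(chr6_forms) != 2L)
    stop("a genotype has exactly two chromosome-1 and two chromosome-6 ",
         "chromosomes", call. = FALSE)
  if (!all(chr1_forms %in% c("M", "T")))
    stop("chromosome-1 forms must be 'M' or 'T'", call. = FALSE)
  if (!all(chr6_forms %in% c("m", "St")))
    stop("chromosome-6 forms must be 'm' or 'St'", call. = FALSE)
  if (!all(chr1_alleles %in% c("X", "Y")))
    stop("sex alleles must be 'X' or 'Y'", call. = FALSE)
  if (sum(chr1_alleles == "Y") > 1L)
    stop("at most one Y-bearing chromosome is allowed (XX/XY system)",
         call. = FALSE)
  structure(list(
    chr1 = list(list(form = chr1_forms[1L], allele = chr1_alleles[1L]),
                list(form = chr1_forms[2L], allele = chr1_alleles[2L])),
    chr6 = list(list(form = chr6_forms[1L], allele = "none"),
                list(form = chr6_forms[2L], allele = "none"))
  ), class = "qb_genotype")
}

#' @export
print.qb_genotype <- function(x, ...) {
  cat("<genotype> ", format_genotype(x),
      "  [karyomorph ", classify_karyomorph(x), ", ", sex_of(x), "]\n",
      sep = "")
  invisible(x)
}

as_genotype <- function(x) {
  if (inherits(x, "qb_genotype")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_genotype(x))
  stop("expected a qb_genotype or a genotype string like \"M/T;m/St|X,X\"",
       call. = FALSE)
}

#' Parse and write compact genotype strings
#'
#' The compact form is `"M/T;m/St|X,X"`: the two chromosome-1 forms, the two
#' chromosome-6 forms, then the sex alleles of the chromosome-1 chromosomes
#' in pair order. The parser also accepts haplotype-class labels
#' (`Xn`, `Xr`, `Yn`, `Yr`) in the allele slot, mapping them to the
#' underlying `X`/`Y` allele; the writer always emits plain alleles, so
#' `format_genotype(parse_genotype(s))` is the canonical form of `s`.
#'
#' @param x Genotype string.
#' @return `parse_genotype()` returns a `qb_genotype`; `format_genotype()`
#'   returns a character scalar.
#' @examples
#' g <- parse_genotype("M/T;m/St|Xn,Xr")
#' format_genotype(g)
#' @export
parse_genotype <- function(x) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop("genotype string must be a single non-empty character value",
         call. = FALSE)
  halves <- strsplit(x, "|", fixed = TRUE)[[1L]]
  if (length(halves) != 2L)
    stop("malformed genotype string '", x,
         "': expected one '|' separating forms from alleles", call. = FALSE)
  pairs <- strsplit(halves[1L], ";", fixed = TRUE)[[1L]]
  if (length(pairs) != 2L)
    stop("malformed genotype string '", x,
         "': expected 'chr1pair;chr6pair' before '|'", call. = FALSE)
  f1 <- strsplit(pairs[1L], "/", fixed = TRUE)[[1L]]
  f6 <- strsplit(pairs[2L], "/", fixed = TRUE)[[1L]]
  al <- strsplit(halves[2L], ",", fixed = TRUE)[[1L]]
  if (length(f1) != 2L || length(f6) != 2L || length(al) != 2L)
    stop("malformed genotype string '", x, "'", call. = FALSE)
  allele_map <- c(X = "X", Xn = "X", Xr = "X", Y = "Y", Yn = "Y", Yr = "Y")
  if (!all(al %in% names(allele_map)))
    stop("unknown sex-allele label(s) in '", x, "'; expected X, Y or a ",
         "haplotype class (Xn, Xr, Yn, Yr)", call. = FALSE)
  genotype(f1, unname(allele_map[al]), f6)
}

#' @rdname parse_genotype
#' @export
format_genotype <- function(x) {
  g <- as_genotype(x)
  paste0(g$chr1[[1L]]$form, "/", g$chr1[[2L]]$form, ";",
         g$chr6[[1L]]$form, "/", g$chr6[[2L]]$form, "|",
         g$chr1[[1L]]$allele, ",", g$chr1[[2L]]$allele)
}

# Canonical identity key: genotypes are identical iff their (form, allele)
# pairs match, irrespective of within-pair order.
genotype_key <- function(x) {
  g <- as_genotype(x)
  c1 <- vapply(g$chr1, function(ch) paste0(ch$form, ch$allele), "")
  ord <- order(match(vapply(g$chr1, `[[`, "", "form"), c("M", "T")),
               vapply(g$chr1, `[[`, "", "allele"))
  f6 <- sort(match(vapply(g$chr6, `[[`, "", "form"), c("m", "St")))
  g2 <- genotype(vapply(g$chr1, `[[`, "", "form")[ord],
                 vapply(g$chr1, `[[`, "", "allele")[ord],
                 c("m", "St")[f6])
  format_genotype(g2)
}

# Segment copy numbers summed over all four chromosomes.
segment_counts <- function(x) {
  g <- as_genotype(x)
  segs <- unlist(lapply(c(g$chr1, g$chr6),
                        function(ch) .FORMS[[ch$form]]$segments))
  vapply(.SEGMENTS, function(s) sum(segs == s), 0L)
}

#' Classify a genotype into karyomorphs I--V
#'
#' Classification is a pure function of the chromosome forms (never of the
#' sex alleles): `MM|mm` is type I, `MM|mSt` type II, `MT|mm` type III,
#' `MT|mSt` type IV (the translocation heterozygote), `MT|StSt` type V, and
#' any other form combination is `"OTHER"`.
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @return Character scalar: `"I"` .. `"V"` or `"OTHER"`.
#' @examples
#' classify_karyomorph("M/M;m/St|X,X")  # "II"
#' classify_karyomorph("T/T;St/St|X,X") # "OTHER"
#' @export
classify_karyomorph <- function(genotype) {
  g <- as_genotype(genotype)
  nT  <- sum(vapply(g$chr1, `[[`, "", "form") == "T")
  nSt <- sum(vapply(g$chr6, `[[`, "", "form") == "St")
  switch(paste0(nT, nSt),
         "00" = "I", "01" = "II", "10" = "III", "11" = "IV", "12" = "V",
         "OTHER")
}

#' Sex of a genotype under the dominant-Y rule
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @return `"male"` if any chromosome carries the `Y` allele, else
#'   `"female"`. Errors if the genotype does not carry exactly two
#'   S1q-bearing chromosomes (inviable).
#' @export
sex_of <- function(genotype) {
  g <- as_genotype(genotype)
  n_s1q <- sum(vapply(c(g$chr1, g$chr6),
                      function(ch) "S1q" %in% .FORMS[[ch$form]]$segments,
                      NA))
  if (n_s1q != 2L)
    stop("inviable genotype: expected exactly two S1q-bearing chromosomes, ",
         "found ", n_s1q, call. = FALSE)
  if (any(vapply(g$chr1, `[[`, "", "allele") == "Y")) "male" else "female"
}

gamete_key <- function(gam)
  paste0(gam$chr1$form, "(", gam$chr1$allele, ")+", gam$chr6$form)

#' Meiotic gametes of a genotype
#'
#' Under the default segregation model each chromosome-1-centromere
#' chromosome pairs with each chromosome-6-centromere chromosome (alternate
#' plus adjacent-1 segregation with independent assortment; four gamete
#' types for a full translocation heterozygote). `"alternate_only"` keeps
#' only the two balanced combinations `(M,m)` and `(T,St)` for a full
#' heterozygote and falls back to the default otherwise.
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @param segregation_model `"fig3_default"` or `"alternate_only"`.
#' @return List of distinct gametes; each gamete is a list with elements
#'   `chr1` and `chr6` (each a list with `form` and `allele`).
#' @examples
#' length(gametes("M/T;m/St|X,X"))  # 4
#' @export
gametes <- function(genotype,
                    segregation_model = c("fig3_default", "alternate_only")) {
  g <- as_genotype(genotype)
  model <- match.arg(segregation_model)
  combos <- list()
  for (c1 in g$chr1) for (c6 in g$chr6)
    combos[[length(combos) + 1L]] <- list(chr1 = c1, chr6 = c6)
  full_het <- classify_karyomorph(g) == "IV"
  if (model == "alternate_only" && full_het) {
    keep <- vapply(combos, function(gm)
      (gm$chr1$form == "M" && gm$chr6$form == "m") ||
      (gm$chr1$form == "T" && gm$chr6$form == "St"), NA)
    combos <- combos[keep]
  }
  keys <- vapply(combos, gamete_key, "")
  combos[!duplicated(keys)]
}

# Gamete sampling distribution: each ordered chr1 x chr6 pick has mass 1/4
# (1/2 per balanced combination under alternate_only), collapsed over
# identical gametes; optional named weights (by gamete key) rescale and
# renormalize, e.g. to model meiotic drive.
gamete_distribution <- function(genotype,
                                segregation_model = "fig3_default",
                                gamete_weights = NULL) {
  g <- as_genotype(genotype)
  combos <- list()
  for (c1 in g$chr1) for (c6 in g$chr6)
    combos[[length(combos) + 1L]] <- list(chr1 = c1, chr6 = c6)
  prob <- rep(1 / 4, 4L)
  if (identical(segregation_model, "alternate_only") &&
      classify_karyomorph(g) == "IV") {
    keep <- vapply(combos, function(gm)
      (gm$chr1$form == "M" && gm$chr6$form == "m") ||
      (gm$chr1$form == "T" && gm$chr6$form == "St"), NA)
    combos <- combos[keep]
    prob <- rep(1 / 2, 2L)
  }
  keys <- vapply(combos, gamete_key, "")
  agg <- tapply(prob, keys, sum)
  gams <- combos[match(names(agg), keys)]
  p <- as.numeric(agg)
  if (!is.null(gamete_weights)) {
    w <- gamete_weights[names(agg)]
    w[is.na(w)] <- 1
    p <- p * as.numeric(w)
    if (sum(p) <= 0) stop("gamete weights removed all gametes", call. = FALSE)
    p <- p / sum(p)
  }
  list(gametes = gams, prob = p, keys = names(agg))
}

#' Founder genotypes under a translocation-origin hypothesis
#'
#' The founder set contains a wild-type female (`M/M;m/m|X,X`), a wild-type
#' male (`M/M;m/m|X,Y`) and a single type-IV translocation heterozygote in
#' which the translocation is seeded exactly once: a female carrying the
#' translocated X (`T` with allele `X`) under `"HX"`, or a male carrying the
#' translocated Y (`T` with allele `Y`) under `"HY"`.
#'
#' @param hypothesis `"HX"` (translocation arose on an X chromosome) or
#'   `"HY"` (on the Y chromosome).
#' @return Named list of three `qb_genotype` objects: `wildtype_female`,
#'   `wildtype_male`, `translocation_carrier`.
#' @export
make_founders <- function(hypothesis = c("HX", "HY")) {
  hypothesis <- match.arg(hypothesis)
  carrier <- if (hypothesis == "HX")
    genotype(c("M", "T"), c("X", "X"), c("m", "St"))
  else
    genotype(c("M", "T"), c("X", "Y"), c("m", "St"))
  list(wildtype_female = genotype(c("M", "M"), c("X", "X"), c("m", "m")),
       wildtype_male   = genotype(c("M", "M"), c("X", "Y"), c("m", "m")),
       translocation_carrier = carrier)
}

#' Zygote viability
#'
#' Under `"nullisomy_lethal"` (the default used throughout the package) a
#' genotype is inviable iff some translocation segment has copy number zero
#' across all four chromosomes; `"all_viable"` accepts everything.
#'
#' @param genotype A `qb_genotype` or genotype string.
#' @param viability_rule `"nullisomy_lethal"` or `"all_viable"`.
#' @return Logical scalar.
#' @examples
#' is_viable("T/T;m/m|X,X")    # FALSE: no S1p copy anywhere
#' is_viable("M/M;St/St|X,X")  # TRUE: karyomorph OTHER but no nullisomy
#' @export
is_viable <- function(genotype,
                      viability_rule = c("nullisomy_lethal", "all_viable")) {
  viability_rule <- match.arg(viability_rule)
  if (viability_rule == "all_viable") return(TRUE)
  all(segment_counts(genotype) > 0L)
}

# Haplotype class of one chromosome at the sex-linked (long-arm) locus.
hap_class <- function(form, allele, hypothesis) {
  if (!"S1q" %in% .FORMS[[form]]$segments) return("absent")
  if (hypothesis == "HX") {
    if (form == "M" && allele == "X") return("Xn")
    if (form == "T" && allele == "X") return("Xr")
    if (form == "M" && allele == "Y") return("Y")
    stop("inconsistent chromosome under HX: the translocated chromosome ",
         "carries an X allele under this hypothesis", call. = FALSE)
  }
  if (form == "M" && allele == "X") return("Xn")
  if (form == "M" && allele == "Y") return("Yn")
  if (form == "T" && allele == "Y") return("Yr")
  stop("inconsistent chromosome under HY: the translocated chromosome ",
       "carries the Y allele under this hypothesis", call. = FALSE)
}

# Observable clade label of one chromosome: what the composition-based clade
# labeller would call its haplotype, independent of hypothesis. M(X) -> Xn
# (normal-X lineage), M(Y) -> Y (male-specific lineage), T(.) -> Xr
# (rearranged lineage).
observable_label <- function(form, allele) {
  if (form == "T") return("Xr")
  if (allele == "Y") return("Y")
  "Xn"
}
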