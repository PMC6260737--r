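# Exact cross distributions and karyomorph reachability closures.

#' Exact offspring distribution of a cross
#'
#' The offspring distribution is the product of the two parental gamete
#' distributions, collapsed over identical genotypes (identity by
#' (form, allele) pairs), then filtered by the viability rule and
#' renormalized.
#'
#' @param mother,father `qb_genotype` objects or genotype strings; `mother`
#'   must be female and `father` male (invalid-cross error otherwise).
#' @param viability_rule Passed to [is_viable()].
#' @param segregation_model Passed to [gametes()].
#' @param gamete_weights Optional named numeric vector of per-gamete-type
#'   weights (names as in `gamete_key`, e.g. `"T(X)+St"`), applied to both
#'   parents' gamete distributions for sensitivity analyses.
#' @return A `cross_result`: list with `offspring` (data frame with columns
#'   `genotype`, `karyomorph`, `sex`, `probability`), `genotypes` (named
#'   list of `qb_genotype`), `dropped` (probability mass removed as
#'   inviable) and `parents`.
#' @examples
#' cr <- cross("M/T;m/St|X,X", "M/M;m/m|X,Y")
#' cr$offspring
#' @export
cross <- function(mother, father,
                  viability_rule = c("nullisomy_lethal", "all_viable"),
                  segregation_model = c("fig3_default", "alternate_only"),
                  gamete_weights = NULL) {
  viability_rule <- match.arg(viability_rule)
  segregation_model <- match.arg(segregation_model)
  mo <- as_genotype(mother)
  fa <- as_genotype(father)
  if (sex_of(mo) != "female" || sex_of(fa) != "male")
    stop("invalid cross: 'mother' must be female and 'father' male",
         call. = FALSE)
  gm <- gamete_distribution(mo, segregation_model, gamete_weights)
  gf <- gamete_distribution(fa, segregation_model, gamete_weights)
  keys <- character(0); probs <- numeric(0); genos <- list()
  for (i in seq_along(gm$gametes)) {
    for (j in seq_along(gf$gametes)) {
      a <- gm$gametes[[i]]; b <- gf$gametes[[j]]
      child <- genotype(c(a$chr1$form, b$chr1$form),
                        c(a$chr1$allele, b$chr1$allele),
                        c(a$chr6$form, b$chr6$form))
      k <- genotype_key(child)
      pos <- match(k, keys)
      if (is.na(pos)) {
        keys <- c(keys, k)
        probs <- c(probs, gm$prob[i] * gf$prob[j])
        genos[[k]] <- child
      } else {
        probs[pos] <- probs[pos] + gm$prob[i] * gf$prob[j]
      }
    }
  }
  viable <- vapply(keys, function(k) is_viable(genos[[k]], viability_rule), NA)
  dropped <- sum(probs[!viable])
  keys <- keys[viable]; probs <- probs[viable]; genos <- genos[keys]
  if (length(keys) == 0L)
    stop("no viable offspring for this cross under rule '", viability_rule,
         "'", call. = FALSE)
  probs <- probs / sum(probs)
  off <- data.frame(
    genotype = keys,
    karyomorph = vapply(genos, classify_karyomorph, ""),
    sex = vapply(genos, sex_of, ""),
    probability = probs,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(offspring = off, genotypes = genos, dropped = dropped,
                 parents = c(mother = genotype_key(mo),
                             father = genotype_key(fa))),
            class = "cross_result")
}

#' @export
print.cross_result <- function(x, ...) {
  cat("<cross> ", x$parents[["mother"]], " x ", x$parents[["father"]], "\n",
      sep = "")
  if (x$dropped > 0)
    cat(sprintf("  inviable probability mass removed: %.4g\n", x$dropped))
  print(x$offspring, row.names = FALSE)
  invisible(x)
}

#' Sample progeny genotypes from a cross
#'
#' Draws `n` independent offspring from the exact [cross()] distribution.
#'
#' @inheritParams cross
#' @param n Number of offspring (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List of `n` `qb_genotype` objects (names are genotype keys).
#' @export
sample_progeny <- function(mother, father, n, seed = NULL,
                           viability_rule = "nullisomy_lethal",
                           segregation_model = "fig3_default",
                           gamete_weights = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cr <- cross(mother, father, viability_rule = viability_rule,
              segregation_model = segregation_model,
              gamete_weights = gamete_weights)
  idx <- sample.int(nrow(cr$offspring), size = n, replace = TRUE,
                    prob = cr$offspring$probability)
  out <- cr$genotypes[cr$offspring$genotype[idx]]
  names(out) <- cr$offspring$genotype[idx]
  out
}

#' Per-sex reachable karyomorphs under a hypothesis
#'
#' Breadth-first closure of random mating: starting from [make_founders()],
#' every female genotype in the pool is crossed with every male genotype,
#' all viable offspring genotypes are added, and the process repeats until
#' the genotype pool stops growing (fixpoint) or `max_generations` is hit.
#' Genotype frequencies are ignored; the pool is a set.
#'
#' @param hypothesis `"HX"` or `"HY"`.
#' @param viability_rule Passed to [cross()].
#' @param max_generations Cap on the number of mating rounds (default
#'   unbounded; the default rules reach a fixpoint within 4).
#' @return A `reachability_report`: list with `female_karyomorphs` and
#'   `male_karyomorphs` (subsets of I..V), `other_genotypes_seen` (count of
#'   distinct viable genotypes classifying as OTHER), `generations_to_fixpoint`,
#'   `genotypes` (the closed pool, named list) and `per_generation` (the
#'   per-sex karyomorph sets after each round, for monotonicity checks).
#' @examples
#' reachable_karyomorphs("HY")$female_karyomorphs  # "I" "II"
#' @export
reachable_karyomorphs <- function(hypothesis = c("HX", "HY"),
                                  viability_rule = "nullisomy_lethal",
                                  max_generations = Inf) {
  hypothesis <- match.arg(hypothesis)
  cache_key <- paste(hypothesis, viability_rule, max_generations)
  cached <- get0(cache_key, envir = .closure_cache)
  if (!is.null(cached)) return(cached)
  pool <- list()
  for (g in make_founders(hypothesis)) pool[[genotype_key(g)]] <- g
  sets_of <- function(pl) {
    km <- vapply(pl, classify_karyomorph, "")
    sx <- vapply(pl, sex_of, "")
    list(female = intersect(.KARYOMORPHS, unique(km[sx == "female"])),
         male   = intersect(.KARYOMORPHS, unique(km[sx == "male"])))
  }
  per_gen <- list(sets_of(pool))
  gen <- 0L
  repeat {
    if (gen >= max_generations) break
    sx <- vapply(pool, sex_of, "")
    fem <- pool[sx == "female"]; mal <- pool[sx == "male"]
    added <- FALSE
    for (mo in fem) {
      for (fa in mal) {
        cr <- cross(mo, fa, viability_rule = viability_rule)
        for (k in cr$offspring$genotype) {
          if (is.null(pool[[k]])) {
            pool[[k]] <- cr$genotypes[[k]]
            added <- TRUE
          }
        }
      }
    }
    gen <- gen + 1L
    per_gen[[gen + 1L]] <- sets_of(pool)
    if (!added) break
  }
  sets <- sets_of(pool)
  km_all <- vapply(pool, classify_karyomorph, "")
  out <- structure(list(
    hypothesis = hypothesis,
    female_karyomorphs = sets$female[order(match(sets$female, .KARYOMORPHS))],
    male_karyomorphs   = sets$male[order(match(sets$male, .KARYOMORPHS))],
    other_genotypes_seen = sum(km_all == "OTHER"),
    generations_to_fixpoint = gen,
    genotypes = pool,
    per_generation = per_gen
  ), class = "reachability_report")
  assign(cache_key, out, envir = .closure_cache)
  out
}

# The closure is a pure function of (hypothesis, viability_rule,
# max_generations); memoized because scoring and cohort generation call it
# repeatedly.
.closure_cache <- new.env(parent = emptyenv())

#' @export
print.reachability_report <- function(x, ...) {
  cat("<reachability> hypothesis ", x$hypothesis, "\n",
      "  female karyomorphs: {", paste(x$female_karyomorphs, collapse = ", "),
      "}\n",
      "  male karyomorphs:   {", paste(x$male_karyomorphs, collapse = ", "),
      "}\n",
      "  OTHER genotypes in closure: ", x$other_genotypes_seen, "\n",
      "  generations to fixpoint: ", x$generations_to_fixpoint, "\n",
      sep = "")
  invisible(x)
}

# Genotypes in the closed pool with a given sex and karyomorph; errors if
# the combination is unrealizable under the hypothesis.
reachable_genotypes <- function(sex, karyomorph, hypothesis,
                                viability_rule = "nullisomy_lethal",
                                report = NULL) {
  if (is.null(report))
    report <- reachable_karyomorphs(hypothesis, viability_rule)
  pl <- report$genotypes
  hit <- vapply(pl, function(g)
    sex_of(g) == sex && classify_karyomorph(g) == karyomorph, NA)
  if (!any(hit))
    stop("unrealizable combination: no reachable ", sex, " genotype of ",
         "karyomorph ", karyomorph, " under ", report$hypothesis,
         call. = FALSE)
  pl[hit]
}
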