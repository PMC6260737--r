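# Scoring the competing hypotheses (translocation on X vs on Y; marker on
# the long vs short arm) against an observed or simulated cohort.

.CANDIDATES <- list(c("HX", "long_arm"), c("HY", "long_arm"),
                    c("HX", "short_arm"), c("HY", "short_arm"))

.ms_key <- function(labels) paste(sort(labels), collapse = "/")

#' Predicted observables per sex and karyomorph
#'
#' Assembles, from the reachability closure, what each (sex, karyomorph)
#' cell should look like under a hypothesis and marker placement:
#' realizability, marker copy numbers, distinct haplotype counts and
#' observable clade-label multisets (labels `Xn` = normal-X lineage on `M`,
#' `Y` = male-specific lineage on `M`, `Xr` = rearranged lineage on `T`,
#' whichever sex allele the hypothesis puts there).
#'
#' @param hypothesis `"HX"` or `"HY"`.
#' @param marker_location `"long_arm"` or `"short_arm"`.
#' @param viability_rule Passed to the closure.
#' @return Data frame with columns `sex`, `karyomorph`, `realizable`, and
#'   list-columns `copy_numbers`, `distinct_counts`, `label_multisets`.
#' @export
predict_observables <- function(hypothesis = c("HX", "HY"),
                                marker_location = c("long_arm", "short_arm"),
                                viability_rule = "nullisomy_lethal") {
  hypothesis <- match.arg(hypothesis)
  marker_location <- match.arg(marker_location)
  closure <- reachable_karyomorphs(hypothesis, viability_rule)
  pool <- closure$genotypes
  km <- vapply(pool, classify_karyomorph, "")
  sx <- vapply(pool, sex_of, "")
  grid <- expand.grid(sex = c("female", "male"), karyomorph = .KARYOMORPHS,
                      stringsAsFactors = FALSE)
  grid$realizable <- FALSE
  grid$copy_numbers <- vector("list", nrow(grid))
  grid$distinct_counts <- vector("list", nrow(grid))
  grid$label_multisets <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gl <- pool[sx == grid$sex[i] & km == grid$karyomorph[i]]
    if (length(gl) == 0L) next
    grid$realizable[i] <- TRUE
    grid$copy_numbers[[i]] <-
      sort(unique(vapply(gl, marker_copy_number, 0L,
                         location = marker_location)))
    profs <- lapply(gl, haplotype_profile, hypothesis = hypothesis)
    grid$distinct_counts[[i]] <-
      sort(unique(vapply(profs, `[[`, 0L, "distinct")))
    grid$label_multisets[[i]] <-
      sort(unique(vapply(profs, function(p) .ms_key(p$labels), "")))
  }
  attr(grid, "hypothesis") <- hypothesis
  attr(grid, "marker_location") <- marker_location
  grid
}

# Normalize a cohort-like input into the data frame the scorers expect:
# id, sex, karyomorph, hap1, hap2 (observed clade labels).
.as_scored_cohort <- function(cohort) {
  if (inherits(cohort, "qb_cohort")) {
    ind <- cohort$individuals
    lab <- t(vapply(seq_len(nrow(ind)), function(i)
      sort(cohort$records$class[cohort$records$id == ind$id[i]]),
      c("", "")))
    # generator classes are already observable labels under HX; map the HY
    # classes to the observable alphabet
    map <- c(Xn = "Xn", Xr = "Xr", Y = "Y", Yn = "Y", Yr = "Xr")
    cohort <- data.frame(id = ind$id, sex = ind$sex,
                         karyomorph = ind$karyomorph,
                         hap1 = unname(map[lab[, 1L]]),
                         hap2 = unname(map[lab[, 2L]]),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(cohort),
            all(c("id", "sex", "karyomorph", "hap1", "hap2") %in%
                  names(cohort)))
  cohort
}

#' Consistency of a cohort with a hypothesis/marker-placement candidate
#'
#' An individual is consistent iff its karyomorph is realizable for its sex
#' under the hypothesis and its observed haplotypes fit the marker
#' placement: for `"long_arm"`, its clade-label multiset must be among the
#' predicted multisets for its (sex, karyomorph) cell; for `"short_arm"`,
#' its number of distinct observed haplotypes must equal the short-arm
#' segment copy number (a lower observed count is accepted only as complete
#' homozygosity, i.e. one distinct haplotype). Individuals with missing
#' metadata are excluded from the denominator and reported.
#'
#' @param cohort A `qb_cohort`, or a data frame with columns `id`, `sex`,
#'   `karyomorph`, `hap1`, `hap2` (observed clade labels `Xn`/`Xr`/`Y`).
#' @param hypothesis `"HX"` or `"HY"`.
#' @param marker_location `"long_arm"` or `"short_arm"`.
#' @param viability_rule Passed to the closure.
#' @return A list of class `hypothesis_score`: `hypothesis`,
#'   `marker_location`, `n_consistent`, `n_total`, `score`, `violations`
#'   (data frame: `id`, `observed`, `predicted`, `rule`),
#'   `hard_violations` (count of unrealizable-karyomorph violations) and
#'   `excluded` (ids with missing metadata).
#' @export
consistency_score <- function(cohort, hypothesis = c("HX", "HY"),
                              marker_location = c("long_arm", "short_arm"),
                              viability_rule = "nullisomy_lethal") {
  hypothesis <- match.arg(hypothesis)
  marker_location <- match.arg(marker_location)
  cohort <- .as_scored_cohort(cohort)
  pred <- predict_observables(hypothesis, marker_location, viability_rule)
  incomplete <- !stats::complete.cases(
    cohort[, c("sex", "karyomorph", "hap1", "hap2")])
  excluded <- cohort$id[incomplete]
  cohort <- cohort[!incomplete, , drop = FALSE]
  n_total <- nrow(cohort)
  viol <- list()
  n_consistent <- 0L
  for (i in seq_len(nrow(cohort))) {
    sex <- cohort$sex[i]; km <- cohort$karyomorph[i]
    obs <- .ms_key(c(cohort$hap1[i], cohort$hap2[i]))
    cell <- pred[pred$sex == sex & pred$karyomorph == km, ]
    if (nrow(cell) == 0L || !cell$realizable[1L]) {
      viol[[length(viol) + 1L]] <- data.frame(
        id = cohort$id[i], observed = obs,
        predicted = "(karyomorph unrealizable for this sex)",
        rule = "unrealizable_karyomorph", stringsAsFactors = FALSE)
      next
    }
    if (marker_location == "long_arm") {
      ok <- obs %in% cell$label_multisets[[1L]]
      predicted <- paste(cell$label_multisets[[1L]], collapse = " | ")
      rule <- "haplotype_mismatch"
    } else {
      n_obs <- length(unique(c(cohort$hap1[i], cohort$hap2[i])))
      cn <- cell$copy_numbers[[1L]]
      ok <- any(n_obs == cn | (n_obs == 1L & n_obs < cn))
      predicted <- paste0("copy number ", paste(cn, collapse = "/"))
      rule <- "copy_number_mismatch"
    }
    if (ok) n_consistent <- n_consistent + 1L
    else viol[[length(viol) + 1L]] <- data.frame(
      id = cohort$id[i], observed = obs, predicted = predicted,
      rule = rule, stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(0), observed = character(0),
               predicted = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  structure(list(
    hypothesis = hypothesis, marker_location = marker_location,
    n_consistent = n_consistent, n_total = n_total,
    score = if (n_total > 0L) n_consistent / n_total else NA_real_,
    violations = violations,
    hard_violations = sum(violations$rule == "unrealizable_karyomorph"),
    excluded = excluded
  ), class = "hypothesis_score")
}

#' @export
print.hypothesis_score <- function(x, ...) {
  cat("<hypothesis score> ", x$hypothesis, " / ", x$marker_location, "\n",
      "  consistent: ", x$n_consistent, "/", x$n_total,
      sprintf(" (score %.3f)", x$score), "\n", sep = "")
  if (nrow(x$violations) > 0L)
    cat("  violations: ", nrow(x$violations), " (",
        x$hard_violations, " unrealizable karyomorphs)\n", sep = "")
  if (length(x$excluded) > 0L)
    cat("  excluded for missing metadata: ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank hypothesis/marker-placement candidates against a cohort
#'
#' Scores every candidate with [consistency_score()] and ranks by score
#' (descending), breaking ties by fewer hard (unrealizable-karyomorph)
#' violations.
#'
#' @param cohort As in [consistency_score()].
#' @param candidates List of `c(hypothesis, marker_location)` pairs;
#'   default all four combinations.
#' @param viability_rule Passed through.
#' @return A list of class `hypothesis_ranking`: `table` (data frame with
#'   `hypothesis`, `location`, `score`, `n_consistent`, `n_total`,
#'   `hard_violations`, `rank`), `scores` (the full `hypothesis_score`
#'   objects) and `winner` (character vector; length > 1 on a tie, empty
#'   for an empty cohort).
#' @export
discriminate <- function(cohort, candidates = NULL,
                         viability_rule = "nullisomy_lethal") {
  if (is.null(candidates)) candidates <- .CANDIDATES
  if (length(candidates) < 1L)
    stop("at least one candidate is required", call. = FALSE)
  scores <- lapply(candidates, function(cd)
    consistency_score(cohort, cd[1L], cd[2L], viability_rule))
  tab <- data.frame(
    hypothesis = vapply(scores, `[[`, "", "hypothesis"),
    location = vapply(scores, `[[`, "", "marker_location"),
    score = vapply(scores, `[[`, 0, "score"),
    n_consistent = vapply(scores, `[[`, 0L, "n_consistent"),
    n_total = vapply(scores, `[[`, 0L, "n_total"),
    hard_violations = vapply(scores, `[[`, 0L, "hard_violations"),
    stringsAsFactors = FALSE)
  empty <- all(tab$n_total == 0L)
  if (!empty) {
    ord <- order(-tab$score, tab$hard_violations)
    tab <- tab[ord, , drop = FALSE]
    scores <- scores[ord]
    tab$rank <- rank(-tab$score + tab$hard_violations * 1e-9,
                     ties.method = "min")
    top <- tab$score == tab$score[1L] &
      tab$hard_violations == tab$hard_violations[1L]
    winner <- paste(tab$hypothesis[top], tab$location[top], sep = ":")
  } else {
    tab$rank <- NA_integer_
    winner <- character(0)
  }
  rownames(tab) <- NULL
  structure(list(table = tab, scores = scores, winner = winner,
                 empty = empty),
            class = "hypothesis_ranking")
}

#' @export
print.hypothesis_ranking <- function(x, ...) {
  if (x$empty) {
    cat("<hypothesis ranking> empty cohort: no scores defined\n")
    return(invisible(x))
  }
  cat("<hypothesis ranking> winner: ", paste(x$winner, collapse = ", "),
      if (length(x$winner) > 1L) " (tie)", "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
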