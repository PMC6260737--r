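# Forward-time Wright-Fisher drift of the translocation polymorphism.

#' Configuration for the Wright--Fisher drift simulation
#'
#' Discrete generations, enforced 1:1 sex ratio, random mating. The default
#' initial state seeds the translocation exactly once: a single type-IV
#' heterozygote (female carrying the translocated X under `"HX"`, male
#' carrying the translocated Y under `"HY"`) in an otherwise wild-type
#' population.
#'
#' @param N Diploid population size (even, >= 2).
#' @param generations Number of generations to simulate.
#' @param replicates Number of independent replicate trajectories.
#' @param init_females,init_males Optional named integer vectors (names are
#'   genotype strings, values counts summing to `N/2` per sex) overriding
#'   the default initial state.
#' @param fertility_penalty Optional named numeric vector in \[0, 1\] of
#'   per-karyomorph offspring rejection probabilities (e.g.
#'   `c(IV = 0.3)`); default no penalty (neutral).
#' @param viability_rule Zygote viability rule used in crosses. Note that
#'   `"nullisomy_lethal"` renormalization is itself weak selection against
#'   unbalanced products; use `"all_viable"` for an exactly neutral model.
#' @param seed Integer seed.
#' @return A list of class `drift_config`.
#' @export
drift_config <- function(N = 50L, generations = 100L, replicates = 100L,
                         init_females = NULL, init_males = NULL,
                         fertility_penalty = NULL,
                         viability_rule = c("nullisomy_lethal", "all_viable"),
                         seed = 1L) {
  viability_rule <- match.arg(viability_rule)
  N <- as.integer(N)
  if (N < 2L || N %% 2L != 0L)
    stop("'N' must be an even integer >= 2", call. = FALSE)
  if (!is.null(fertility_penalty) &&
      (any(fertility_penalty < 0) || any(fertility_penalty > 1)))
    stop("'fertility_penalty' values must lie in [0, 1]", call. = FALSE)
  structure(list(N = N, generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 init_females = init_females, init_males = init_males,
                 fertility_penalty = fertility_penalty,
                 viability_rule = viability_rule,
                 seed = as.integer(seed)),
            class = "drift_config")
}

# Validated initial pools as character vectors of genotype keys.
.init_pools <- function(config, hypothesis) {
  half <- config$N %/% 2L
  expand <- function(counts, want_sex, label) {
    if (sum(counts) != half)
      stop("initial ", label, " counts must sum to N/2 = ", half,
           call. = FALSE)
    keys <- character(0)
    for (gs in names(counts)) {
      g <- as_genotype(gs)
      if (sex_of(g) != want_sex)
        stop("initial ", label, " pool contains a ", sex_of(g),
             " genotype: ", gs, call. = FALSE)
      if (!is_viable(g, config$viability_rule))
        stop("initial ", label, " pool contains an inviable genotype: ",
             gs, call. = FALSE)
      keys <- c(keys, rep(genotype_key(g), counts[[gs]]))
    }
    keys
  }
  if (is.null(config$init_females) && is.null(config$init_males)) {
    founders <- make_founders(hypothesis)
    carrier <- genotype_key(founders$translocation_carrier)
    wf <- genotype_key(founders$wildtype_female)
    wm <- genotype_key(founders$wildtype_male)
    if (hypothesis == "HX") {
      fem <- c(carrier, rep(wf, half - 1L)); mal <- rep(wm, half)
    } else {
      fem <- rep(wf, half); mal <- c(carrier, rep(wm, half - 1L))
    }
    return(list(females = fem, males = mal))
  }
  if (is.null(config$init_females) || is.null(config$init_males))
    stop("provide both 'init_females' and 'init_males' or neither",
         call. = FALSE)
  fem <- expand(config$init_females, "female", "female")
  mal <- expand(config$init_males, "male", "male")
  if (length(fem) == 0L || length(mal) == 0L)
    stop("both sexes must be present in the initial population",
         call. = FALSE)
  list(females = fem, males = mal)
}

#' Wright--Fisher simulation of the translocation polymorphism
#'
#' Each generation, every offspring is produced by drawing a mother and a
#' father uniformly with replacement from the previous generation's
#' sex-classified pools and sampling its genotype from the exact cross
#' distribution; offspring of penalized karyomorphs are rejected with the
#' configured probability (parents re-drawn), and offspring fill the
#' female/male slots of the next generation until both hold `N/2`
#' individuals. The tracked quantity is the frequency of the translocated
#' (`T`) chromosome among all chromosome-1-centromere chromosomes; 0 is
#' absorbing (loss). Under `"HX"` the `T` chromosome is X-linked, so it can
#' never fix in the whole chromosome-1 pool (males retain the Y-bearing
#' `M`); trajectories still carrying `T` at the end are `"segregating"`.
#'
#' @param config A [drift_config()].
#' @param hypothesis `"HX"` or `"HY"`.
#' @return A list of class `drift_result`: `freq` (replicates x
#'   (generations + 1) matrix of `T` frequencies, column 1 = initial),
#'   `terminal` (`"lost"`/`"segregating"` per replicate), `config`,
#'   `hypothesis`.
#' @export
wright_fisher <- function(config = drift_config(),
                          hypothesis = c("HX", "HY")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(config, "drift_config"))
  set.seed(config$seed)
  pools0 <- .init_pools(config, hypothesis)
  half <- config$N %/% 2L
  G <- config$generations; R <- config$replicates
  penalty <- config$fertility_penalty

  # per-genotype lookup tables, grown lazily
  info <- new.env(parent = emptyenv())
  geno_info <- function(key) {
    v <- get0(key, envir = info)
    if (!is.null(v)) return(v)
    g <- as_genotype(key)
    v <- list(sex = sex_of(g),
              tcount = sum(vapply(g$chr1, `[[`, "", "form") == "T"),
              karyomorph = classify_karyomorph(g), genotype = g)
    assign(key, v, envir = info)
    v
  }
  cross_cache <- new.env(parent = emptyenv())
  cross_dist <- function(mk, fk) {
    ck <- paste(mk, fk, sep = " x ")
    v <- get0(ck, envir = cross_cache)
    if (!is.null(v)) return(v)
    cr <- cross(geno_info(mk)$genotype, geno_info(fk)$genotype,
                viability_rule = config$viability_rule)
    v <- list(keys = cr$offspring$genotype,
              prob = cr$offspring$probability,
              sex = cr$offspring$sex,
              karyomorph = cr$offspring$karyomorph)
    assign(ck, v, envir = cross_cache)
    v
  }
  tfreq <- function(fem, mal) {
    keys <- c(fem, mal)
    sum(vapply(keys, function(k) geno_info(k)$tcount, 0L)) /
      (2L * length(keys))
  }

  freq <- matrix(0, nrow = R, ncol = G + 1L)
  terminal <- character(R)
  for (r in seq_len(R)) {
    fem <- pools0$females; mal <- pools0$males
    freq[r, 1L] <- tfreq(fem, mal)
    lost_at <- NA_integer_
    for (g in seq_len(G)) {
      if (freq[r, g] == 0) { freq[r, g + 1L] <- 0; next }  # absorbing
      new_f <- character(0); new_m <- character(0)
      guard <- 0L
      while (length(new_f) < half || length(new_m) < half) {
        guard <- guard + 1L
        if (guard > 1000L)
          stop("offspring rejection did not terminate (check ",
               "fertility_penalty)", call. = FALSE)
        need <- 2L * (2L * half - length(new_f) - length(new_m)) + 4L
        mo <- sample(fem, need, replace = TRUE)
        fa <- sample(mal, need, replace = TRUE)
        pair <- paste(mo, fa, sep = " x ")
        off_key <- character(need); off_sex <- character(need)
        off_km <- character(need)
        for (pk in unique(pair)) {
          pos <- which(pair == pk)
          d <- get0(pk, envir = cross_cache)
          if (is.null(d)) {
            mf <- strsplit(pk, " x ", fixed = TRUE)[[1L]]
            d <- cross_dist(mf[1L], mf[2L])
          }
          idx <- sample.int(length(d$keys), length(pos), replace = TRUE,
                            prob = d$prob)
          off_key[pos] <- d$keys[idx]
          off_sex[pos] <- d$sex[idx]
          off_km[pos] <- d$karyomorph[idx]
        }
        if (!is.null(penalty)) {
          pen <- penalty[off_km]
          pen[is.na(pen)] <- 0
          keep <- stats::runif(need) >= pen
          off_key <- off_key[keep]; off_sex <- off_sex[keep]
        }
        # fill slots in draw order (independent of parental pair) so the
        # accepted offspring remain an iid sample from the cross mixture
        nf <- off_key[off_sex == "female"]
        nm <- off_key[off_sex == "male"]
        room_f <- half - length(new_f); room_m <- half - length(new_m)
        if (room_f > 0L && length(nf) > 0L)
          new_f <- c(new_f, nf[seq_len(min(room_f, length(nf)))])
        if (room_m > 0L && length(nm) > 0L)
          new_m <- c(new_m, nm[seq_len(min(room_m, length(nm)))])
      }
      fem <- new_f; mal <- new_m
      freq[r, g + 1L] <- tfreq(fem, mal)
    }
    terminal[r] <- if (freq[r, G + 1L] == 0) "lost" else "segregating"
  }
  structure(list(freq = freq, terminal = terminal, config = config,
                 hypothesis = hypothesis),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat("<drift> ", x$config$replicates, " replicates, N = ", x$config$N,
      ", ", x$config$generations, " generations (", x$hypothesis, ")\n",
      "  initial T frequency: ", signif(x$freq[1L, 1L], 4), "\n",
      "  mean terminal T frequency: ",
      signif(mean(x$freq[, ncol(x$freq)]), 4), "\n",
      "  lost: ", sum(x$terminal == "lost"), "/", length(x$terminal), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.drift_result <- function(x, ...) {
  gens <- 0:(ncol(x$freq) - 1L)
  qs <- apply(x$freq, 2L, stats::quantile, probs = c(0.1, 0.5, 0.9))
  graphics::matplot(gens, t(qs), type = "l", lty = c(2, 1, 2),
                    col = "grey30", xlab = "generation",
                    ylab = "T-chromosome frequency", ...)
  graphics::lines(gens, colMeans(x$freq), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Loss probability of the translocated chromosome
#'
#' Fraction of [wright_fisher()] trajectories absorbed at frequency 0 by
#' the final generation, with its binomial Monte-Carlo standard error.
#'
#' @param config A [drift_config()] with `replicates >= 100`.
#' @param hypothesis `"HX"` or `"HY"`.
#' @return List with `estimate`, `se`, `n_replicates` and the underlying
#'   `drift_result`.
#' @export
loss_probability <- function(config = drift_config(),
                             hypothesis = c("HX", "HY")) {
  if (config$replicates < 100L)
    stop("'replicates' must be >= 100 for a loss-probability estimate",
         call. = FALSE)
  res <- wright_fisher(config, hypothesis)
  p <- mean(res$terminal == "lost")
  list(estimate = p,
       se = sqrt(p * (1 - p) / config$replicates),
       n_replicates = config$replicates,
       result = res)
}
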