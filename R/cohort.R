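# Constructive simulator of sex-linked microsatellite haplotype cohorts.
#
# The generator builds three reference haplotypes (classes Y, Xn, Xr) of a
# ~400 bp microsatellite-containing locus with a constructively known
# multiple alignment, then samples diploid individuals whose allele classes
# follow their genotype's haplotype profile.

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Default per-population sampling quotas (normal females / normal males /
# rearranged females / rearranged males); column sums 12/12/33/17.
.POPULATIONS <- data.frame(
  population = c("DYYEC", "QLTTS", "PZLMS", "DJYHK", "PZCF", "WCYX", "WCXK",
                 "QCS", "DYHP", "DYWS", "DYGTS", "QLDZ", "EMS"),
  normal_female     = c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0),
  normal_male       = c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1),
  rearranged_female = c(7, 7, 2, 2, 2, 2, 2, 2, 2, 3, 2, 0, 0),
  rearranged_male   = c(5, 1, 0, 1, 2, 2, 1, 1, 2, 0, 2, 0, 0),
  stringsAsFactors = FALSE)

#' Locus configuration for the synthetic sex-linked marker
#'
#' Defines the constructive layout of the three reference haplotypes: a
#' dinucleotide repeat tract embedded in random flanking sequence, with
#' fixed class-diagnostic substitutions and length differences. Defaults
#' give a 400 bp normal-X (`Xn`) haplotype, an `Xr` haplotype 6 bp shorter
#' (three fewer repeat units plus 5 private flanking substitutions) and a
#' `Y` haplotype 31 bp shorter than `Xn` (a 25 bp flanking deletion plus
#' three fewer repeat units, with 37 flanking and 5 repeat-tract private
#' substitutions), for 47 variable alignment columns in total.
#'
#' @param flanking_left,flanking_right Flanking lengths in bp (default 170
#'   each, so `flanking_length` = 340).
#' @param repeat_unit Two-base repeat motif (default `"CA"`).
#' @param repeat_count Repeat units in the `Xn` haplotype (default 30).
#' @param xn_xr_length_diff Xn-Xr size difference in bp (default 6; must be
#'   an even number of repeat bases).
#' @param xy_length_diff X-Y size difference in bp, must lie in \[27, 35\]
#'   (default 31, the midpoint).
#' @param repeat_variable_sites Diagnostic substitutions inside the repeat
#'   tract (default 5; must lie in \[4, 6\]).
#' @param flanking_variable_sites Diagnostic substitutions in the flanks
#'   (default 42; must lie in \[41, 43\]).
#' @param xr_substitutions How many of the flanking substitutions separate
#'   `Xr` from `Xn` (default 5); the rest, plus all repeat-tract ones,
#'   separate `Y` from both X classes, so the Y lineage is the diverged one.
#' @param within_class_substitutions Random private substitutions added to
#'   each simulated allele copy (default 0: alleles are exact class copies).
#' @param seed Integer seed making the references deterministic.
#' @return A list of class `locus_config` (validated; derived fields
#'   `repeat_counts`, `flank_indel` and `total_variable_sites` filled in).
#' @export
locus_config <- function(flanking_left = 170L, flanking_right = 170L,
                         repeat_unit = "CA", repeat_count = 30L,
                         xn_xr_length_diff = 6L, xy_length_diff = 31L,
                         repeat_variable_sites = 5L,
                         flanking_variable_sites = 42L,
                         xr_substitutions = 5L,
                         within_class_substitutions = 0L,
                         seed = 1L) {
  cfg <- list(flanking_left = as.integer(flanking_left),
              flanking_right = as.integer(flanking_right),
              repeat_unit = repeat_unit,
              repeat_count = as.integer(repeat_count),
              xn_xr_length_diff = as.integer(xn_xr_length_diff),
              xy_length_diff = as.integer(xy_length_diff),
              repeat_variable_sites = as.integer(repeat_variable_sites),
              flanking_variable_sites = as.integer(flanking_variable_sites),
              xr_substitutions = as.integer(xr_substitutions),
              within_class_substitutions = as.integer(within_class_substitutions),
              seed = as.integer(seed))
  if (nchar(cfg$repeat_unit) != 2L ||
      !all(strsplit(cfg$repeat_unit, "")[[1L]] %in% .BASES))
    stop("'repeat_unit' must be a 2 bp nucleotide motif", call. = FALSE)
  if (cfg$xy_length_diff < 27L || cfg$xy_length_diff > 35L)
    stop("'xy_length_diff' must lie in [27, 35] bp", call. = FALSE)
  if (cfg$xn_xr_length_diff < 0L || cfg$xn_xr_length_diff %% 2L != 0L)
    stop("'xn_xr_length_diff' must be a non-negative even number of bases",
         call. = FALSE)
  cfg$flank_indel <- cfg$xy_length_diff - cfg$xn_xr_length_diff
  if (cfg$flank_indel < 1L)
    stop("'xy_length_diff' must exceed 'xn_xr_length_diff' (the Y carries ",
         "a flanking deletion on top of the repeat difference)", call. = FALSE)
  cfg$total_variable_sites <-
    cfg$repeat_variable_sites + cfg$flanking_variable_sites
  units_xr <- cfg$repeat_count - cfg$xn_xr_length_diff %/% 2L
  cfg$repeat_counts <- c(Xn = cfg$repeat_count, Xr = units_xr, Y = units_xr)
  if (units_xr < 1L)
    stop("'repeat_count' too small for the requested length difference",
         call. = FALSE)
  if (cfg$repeat_variable_sites > 2L * units_xr)
    stop("more repeat-tract variable sites requested than shared repeat ",
         "columns available", call. = FALSE)
  if (cfg$xr_substitutions < 0L ||
      cfg$xr_substitutions >= cfg$flanking_variable_sites)
    stop("'xr_substitutions' must be fewer than 'flanking_variable_sites' ",
         "(the Y lineage must remain the diverged one)", call. = FALSE)
  if (cfg$flanking_left < cfg$flank_indel + 40L)
    stop("'flanking_left' too short to host the Y deletion plus variable ",
         "sites", call. = FALSE)
  class(cfg) <- "locus_config"
  cfg
}

#' Build the Y/Xn/Xr reference haplotypes and their true alignment
#'
#' Constructive generation (no rejection sampling): length differences,
#' variable-site counts and their repeat/flanking partition match the
#' configuration exactly, and the multiple alignment is known by
#' construction rather than estimated.
#'
#' @param config A [locus_config()].
#' @return A list of class `reference_haplotypes`: `alignment` (3 x L
#'   character matrix, rows `Y`, `Xn`, `Xr`, gaps as `"-"`),
#'   `sequences` (named character vector of ungapped sequences),
#'   `repeat_region` (column indices of the repeat tract) and `config`.
#' @examples
#' refs <- build_reference_haplotypes(locus_config(seed = 1))
#' nchar(refs$sequences)  # Y 369, Xn 400, Xr 394
#' @export
build_reference_haplotypes <- function(config = locus_config()) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  Lf <- config$flanking_left; Lr <- config$flanking_right
  n_rep_cols <- 2L * config$repeat_count
  total <- Lf + n_rep_cols + Lr
  repeat_cols <- (Lf + 1L):(Lf + n_rep_cols)
  unit <- strsplit(config$repeat_unit, "")[[1L]]

  xn <- c(sample(.BASES, Lf, replace = TRUE),
          rep(unit, config$repeat_count),
          sample(.BASES, Lr, replace = TRUE))

  # Y flanking deletion: one contiguous block inside the left flank.
  del_start <- sample(seq(10L, Lf - config$flank_indel - 10L), 1L)
  del_cols <- del_start:(del_start + config$flank_indel - 1L)

  flank_cols <- setdiff(c(seq_len(Lf), (Lf + n_rep_cols + 1L):total), del_cols)
  sub_cols <- sample(flank_cols, config$flanking_variable_sites)
  xr_cols <- sub_cols[seq_len(config$xr_substitutions)]
  y_flank_cols <- sub_cols[-seq_len(config$xr_substitutions)]

  shared_rep_cols <- repeat_cols[seq_len(2L * config$repeat_counts[["Y"]])]
  y_rep_cols <- sample(shared_rep_cols, config$repeat_variable_sites)
  rep_gap_cols <- setdiff(repeat_cols, shared_rep_cols)

  xr <- xn
  xr[xr_cols] <- unname(.TRANSITION[xr[xr_cols]])
  xr[rep_gap_cols] <- "-"

  y <- xn
  y[c(y_flank_cols, y_rep_cols)] <-
    unname(.TRANSITION[y[c(y_flank_cols, y_rep_cols)]])
  y[del_cols] <- "-"
  y[rep_gap_cols] <- "-"

  aln <- rbind(Y = y, Xn = xn, Xr = xr)
  colnames(aln) <- NULL
  seqs <- apply(aln, 1L, function(r) paste(r[r != "-"], collapse = ""))
  structure(list(alignment = aln, sequences = seqs,
                 repeat_region = repeat_cols, config = config,
                 diagnostic_columns = list(xr = sort(xr_cols),
                                           y_flanking = sort(y_flank_cols),
                                           y_repeat = sort(y_rep_cols),
                                           y_deletion = del_cols)),
            class = "reference_haplotypes")
}

#' @export
print.reference_haplotypes <- function(x, ...) {
  vs <- count_variable_sites(x$alignment, x$repeat_region)
  cat("<reference haplotypes> Y/Xn/Xr, alignment ", ncol(x$alignment),
      " columns\n  lengths: ",
      paste(names(x$sequences), nchar(x$sequences), collapse = ", "),
      "\n  variable sites: ", vs[["total"]], " (",
      vs[["repeat_region"]], " repeat, ", vs[["flanking"]], " flanking)\n",
      sep = "")
  invisible(x)
}

#' Count variable columns of an alignment
#'
#' A column is variable iff at least two distinct non-gap nucleotides occur
#' in it; columns with gaps are judged on their non-gap residues only.
#'
#' @param alignment Character matrix (rows = sequences, `"-"` = gap) or list
#'   of equal-length character strings.
#' @param repeat_region Optional integer vector of repeat-tract columns for
#'   the repeat/flanking partition.
#' @return Named integer vector `total`, `repeat_region`, `flanking`.
#' @export
count_variable_sites <- function(alignment, repeat_region = integer(0)) {
  if (!is.matrix(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences have unequal padded lengths",
           call. = FALSE)
    alignment <- do.call(rbind, strsplit(unlist(alignment), ""))
  }
  variable <- apply(alignment, 2L, function(col) {
    res <- col[col != "-"]
    length(unique(res)) >= 2L
  })
  total <- sum(variable)
  in_rep <- sum(variable[intersect(seq_along(variable), repeat_region)])
  c(total = total, repeat_region = in_rep, flanking = total - in_rep)
}

#' Cohort configuration
#'
#' Sampling design of the simulated cohort. Defaults mirror the study
#' design: 74 frogs = 12 normal-karyotype females + 12 normal males + 33
#' rearranged females + 17 rearranged males, spread over 13 populations
#' (metadata only; populations do not affect generation). Default
#' karyomorph weights put all rearranged individuals on the T-carrying
#' types III/IV/V (uniform); type II is available via the weights.
#'
#' @param normal_females,normal_males,rearranged_females,rearranged_males
#'   Per-category counts (defaults 12, 12, 33, 17).
#' @param rearranged_karyomorph_weights Named non-negative weights over
#'   `c("II","III","IV","V")`, normalized internally.
#' @param hypothesis `"HX"` or `"HY"` — which translocation origin the
#'   cohort is generated under.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(normal_females = 12L, normal_males = 12L,
                          rearranged_females = 33L, rearranged_males = 17L,
                          rearranged_karyomorph_weights =
                            c(II = 0, III = 1, IV = 1, V = 1),
                          hypothesis = c("HX", "HY"),
                          seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  counts <- c(normal_females, normal_males, rearranged_females,
              rearranged_males)
  if (any(counts < 0L)) stop("category counts must be >= 0", call. = FALSE)
  w <- rearranged_karyomorph_weights
  if (is.null(names(w)) || !all(names(w) %in% c("II", "III", "IV", "V")) ||
      any(w < 0) || sum(w) <= 0)
    stop("'rearranged_karyomorph_weights' must be non-negative weights ",
         "named over II, III, IV, V", call. = FALSE)
  structure(list(normal_females = as.integer(normal_females),
                 normal_males = as.integer(normal_males),
                 rearranged_females = as.integer(rearranged_females),
                 rearranged_males = as.integer(rearranged_males),
                 rearranged_karyomorph_weights = w / sum(w),
                 hypothesis = hypothesis,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Assign population labels to a category, following the default quotas in
# order and recycling the last population if user counts exceed them.
.assign_populations <- function(category_col, n) {
  quota <- .POPULATIONS[[category_col]]
  labs <- rep(.POPULATIONS$population, quota)
  if (n <= length(labs)) labs[seq_len(n)]
  else c(labs, rep(utils::tail(.POPULATIONS$population, 1L),
                   n - length(labs)))
}

# Reference row used for a haplotype class. The rearranged lineage reference
# serves whichever chromosome is translocated (Xr under HX, Yr under HY);
# Yn maps to the Y reference.
.class_reference <- function(class) {
  switch(class, Xn = "Xn", Xr = "Xr", Y = "Y", Yn = "Y", Yr = "Xr",
         stop("no reference sequence for haplotype class '", class, "'",
              call. = FALSE))
}

#' Simulate a diploid cohort of sex-linked haplotypes
#'
#' Each individual receives a genotype consistent with its category (normal
#' karyotype = type I; rearranged = karyomorph drawn from the configured
#' weights, genotype uniform among reachable genotypes of that sex and
#' karyomorph), then two allele sequences copied from the class reference
#' haplotypes (plus optional within-class substitutions). Requesting a
#' category that is unrealizable under the hypothesis (e.g. rearranged
#' females carrying T under `"HY"`) is an error naming the category.
#'
#' @param locus A [locus_config()].
#' @param cohort A [cohort_config()].
#' @return A list of class `qb_cohort`: `individuals` (data frame: `id`,
#'   `sex`, `karyomorph`, `category`, `population`, `genotype`), `records`
#'   (per-allele data frame: `header`, `id`, `allele_index`, `sex`,
#'   `karyomorph`, `class`, `sequence`), `alignment` (character matrix of
#'   all allele rows in true alignment coordinates), `references`, and the
#'   two configs. Sequence headers follow `{specimen}_{allele}_{sex}_{karyomorph}`.
#' @examples
#' co <- simulate_cohort(locus_config(seed = 1), cohort_config(seed = 1))
#' nrow(co$individuals)  # 74
#' @export
simulate_cohort <- function(locus = locus_config(),
                            cohort = cohort_config()) {
  stopifnot(inherits(locus, "locus_config"),
            inherits(cohort, "cohort_config"))
  refs <- build_reference_haplotypes(locus)
  set.seed(cohort$seed)
  hyp <- cohort$hypothesis
  closure <- reachable_karyomorphs(hyp)

  w <- cohort$rearranged_karyomorph_weights
  w <- w[w > 0]
  sample_rearranged <- function(sex, category) {
    ok <- vapply(names(w), function(km) {
      any(vapply(closure$genotypes, function(g)
        sex_of(g) == sex && classify_karyomorph(g) == km, NA))
    }, NA)
    if (!all(ok))
      stop("cannot generate category '", category, "' under ", hyp,
           ": karyomorph(s) ", paste(names(w)[!ok], collapse = ", "),
           " unrealizable for ", sex, " individuals", call. = FALSE)
    km <- sample(names(w), 1L, prob = as.numeric(w))
    cand <- reachable_genotypes(sex, km, hyp, report = closure)
    cand[[sample.int(length(cand), 1L)]]
  }

  cats <- c(rep("normal_female", cohort$normal_females),
            rep("normal_male", cohort$normal_males),
            rep("rearranged_female", cohort$rearranged_females),
            rep("rearranged_male", cohort$rearranged_males))
  pops <- c(.assign_populations("normal_female", cohort$normal_females),
            .assign_populations("normal_male", cohort$normal_males),
            .assign_populations("rearranged_female", cohort$rearranged_females),
            .assign_populations("rearranged_male", cohort$rearranged_males))
  n <- length(cats)
  ids <- sprintf("QB%03d", seq_len(n))

  wt_female <- genotype(c("M", "M"), c("X", "X"), c("m", "m"))
  wt_male   <- genotype(c("M", "M"), c("X", "Y"), c("m", "m"))

  genos <- vector("list", n)
  for (i in seq_len(n)) {
    genos[[i]] <- switch(cats[i],
      normal_female = wt_female,
      normal_male = wt_male,
      rearranged_female = sample_rearranged("female", "rearranged_female"),
      rearranged_male = sample_rearranged("male", "rearranged_male"))
  }

  sexes <- vapply(genos, sex_of, "")
  kms <- vapply(genos, classify_karyomorph, "")
  L <- ncol(refs$alignment)
  aln <- matrix("-", nrow = 2L * n, ncol = L)
  rec <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    prof <- haplotype_profile(genos[[i]], hyp)
    for (a in 1:2) {
      row <- refs$alignment[.class_reference(prof$classes[a]), ]
      if (locus$within_class_substitutions > 0L) {
        pos <- sample(which(row != "-"), locus$within_class_substitutions)
        row[pos] <- unname(.TRANSITION[row[pos]])
      }
      r <- 2L * (i - 1L) + a
      aln[r, ] <- row
      rec[[r]] <- data.frame(
        header = paste(ids[i], a, if (sexes[i] == "male") "M" else "F",
                       kms[i], sep = "_"),
        id = ids[i], allele_index = a, sex = sexes[i], karyomorph = kms[i],
        class = prof$classes[a],
        sequence = paste(row[row != "-"], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  rownames(aln) <- records$header

  individuals <- data.frame(
    id = ids, sex = sexes, karyomorph = kms, category = cats,
    population = pops,
    genotype = vapply(genos, genotype_key, ""),
    stringsAsFactors = FALSE)

  structure(list(individuals = individuals, records = records,
                 alignment = aln, references = refs,
                 locus_config = locus, cohort_config = cohort),
            class = "qb_cohort")
}

#' @export
print.qb_cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$individuals), " individuals, ",
      nrow(x$records), " haplotype sequences (hypothesis ",
      x$cohort_config$hypothesis, ")\n", sep = "")
  print(table(sex = x$individuals$sex, karyomorph = x$individuals$karyomorph))
  invisible(x)
}

#' Write and read cohort FASTA files
#'
#' Headers follow the schema `{specimen}_{allele}_{sex}_{karyomorph}`
#' (e.g. `QB012_1_M_IV`); the round-trip is lossless for sequence and
#' metadata.
#'
#' @param records Data frame with columns `header` and `sequence` (as in a
#'   `qb_cohort$records`), or a `qb_cohort`.
#' @param path File path.
#' @return `read_fasta()` returns a records data frame with the metadata
#'   fields re-parsed from the headers.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "qb_cohort")) records <- records$records
  stopifnot(is.data.frame(records),
            all(c("header", "sequence") %in% names(records)))
  writeLines(as.vector(rbind(paste0(">", records$header),
                             records$sequence)), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  headers <- names(dna)
  seqs <- vapply(as.character(dna), function(s)
    toupper(paste(s, collapse = "")), "")
  meta <- lapply(seq_along(headers), function(i)
    parse_fasta_header(headers[i], line = 2L * i - 1L))
  out <- do.call(rbind, meta)
  out$header <- headers
  out$sequence <- unname(seqs)
  out[, c("header", "id", "allele_index", "sex", "karyomorph", "sequence")]
}

#' Parse a cohort FASTA header
#'
#' @param header Header string `{specimen}_{allele}_{sex}_{karyomorph}`.
#' @param line Optional line number for error messages.
#' @return One-row data frame with `id`, `allele_index`, `sex`, `karyomorph`.
#' @export
parse_fasta_header <- function(header, line = NA_integer_) {
  where <- if (is.na(line)) "" else paste0(" (line ", line, ")")
  parts <- strsplit(header, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 4L)
    stop("malformed FASTA header '", header, "'", where,
         ": expected specimen_allele_sex_karyomorph", call. = FALSE)
  if (!parts[2L] %in% c("1", "2"))
    stop("malformed FASTA header '", header, "'", where,
         ": allele index must be 1 or 2", call. = FALSE)
  if (!parts[3L] %in% c("M", "F"))
    stop("malformed FASTA header '", header, "'", where,
         ": sex must be M or F", call. = FALSE)
  if (!parts[4L] %in% c(.KARYOMORPHS, "OTHER"))
    stop("malformed FASTA header '", header, "'", where,
         ": unknown karyomorph '", parts[4L], "'", call. = FALSE)
  data.frame(id = parts[1L], allele_index = as.integer(parts[2L]),
             sex = if (parts[3L] == "M") "male" else "female",
             karyomorph = parts[4L], stringsAsFactors = FALSE)
}

#' Write and read cohort metadata tables (TSV)
#'
#' @param individuals Data frame as in `qb_cohort$individuals`, or a
#'   `qb_cohort`.
#' @param path File path.
#' @export
write_metadata <- function(individuals, path) {
  if (inherits(individuals, "qb_cohort")) individuals <- individuals$individuals
  utils::write.table(individuals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
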