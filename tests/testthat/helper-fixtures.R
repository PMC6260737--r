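# Shared fixtures: representative genotypes for each karyomorph and a
# brute-force global-alignment oracle for small strings.

geno_I_f   <- "M/M;m/m|X,X"
geno_I_m   <- "M/M;m/m|X,Y"
geno_II_f  <- "M/M;m/St|X,X"
geno_II_m  <- "M/M;m/St|X,Y"
geno_III_f <- "M/T;m/m|X,X"
geno_III_m <- "M/T;m/m|Y,X"   # M carries Y, T carries X (HX male)
geno_IV_f  <- "M/T;m/St|X,X"
geno_IV_m  <- "M/T;m/St|Y,X"
geno_V_f   <- "M/T;St/St|X,X"
geno_V_m   <- "M/T;St/St|Y,X"

karyomorph_reps_female <- c(I = geno_I_f, II = geno_II_f, III = geno_III_f,
                            IV = geno_IV_f, V = geno_V_f)

# Exhaustive-search optimal global alignment score (linear gap cost), used
# as an independent oracle for global_align() on short strings.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Segment multiset summed over a list of gametes.
gamete_segment_counts <- function(gams) {
  segs <- unlist(lapply(gams, function(g)
    c(segments_of(g$chr1$form), segments_of(g$chr6$form))))
  vapply(c("S1q", "S1p", "S6"), function(s) sum(segs == s), 0L)
}
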