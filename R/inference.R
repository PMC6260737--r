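# Distance-based haplogroup inference: pairwise alignment, p-distances,
# neighbour-joining, bootstrap, clade extraction and composition labelling.

#' Global pairwise alignment (Needleman--Wunsch, linear gap cost)
#'
#' Optimal global alignment under a simple scoring scheme. Ties in the
#' dynamic programme are broken deterministically: diagonal (match/mismatch)
#' is preferred, then a gap in `b`, then a gap in `a`, so the result is
#' reproducible.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch,gap Scores (defaults +1, -1, -2).
#' @return A list of class `pairwise_alignment`: `a`, `b` (padded with
#'   `"-"`), `score`, `params`.
#' @examples
#' global_align("ACGT", "AGT")$score  # 1
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  S[, 1L] <- gap * (0:n); S[1L, ] <- gap * (0:m)
  P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    si <- S[i, ]          # previous row
    sc <- S[i + 1L, ]     # current row being filled
    for (j in seq_len(m)) {
      d <- si[j] + if (av[i] == bv[j]) match else mismatch
      u <- si[j + 1L] + gap
      l <- sc[j] + gap
      best <- max(d, u, l)
      sc[j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
    S[i + 1L, ] <- sc
  }
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) {
      ai <- c(av[i - 1L], ai); bi <- c(bv[j - 1L], bi)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ai <- c(av[i - 1L], ai); bi <- c("-", bi)
      i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1L], bi)
      j <- j - 1L
    }
  }
  structure(list(a = paste(ai, collapse = ""), b = paste(bi, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 params = c(match = match, mismatch = mismatch, gap = gap)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$a, "\n", x$b, "\n  score: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Proportion of differing sites of a pairwise alignment
#'
#' Columns containing a pad symbol in either sequence are excluded
#' (pairwise gap deletion); the distance is mismatches over comparable
#' columns.
#'
#' @param alignment A `pairwise_alignment`, or a list/vector of two padded
#'   equal-length strings.
#' @return Numeric p-distance in \[0, 1\]. Errors when no comparable
#'   columns remain.
#' @export
p_distance <- function(alignment) {
  if (inherits(alignment, "pairwise_alignment"))
    alignment <- c(alignment$a, alignment$b)
  alignment <- unlist(alignment)
  if (length(alignment) != 2L || nchar(alignment[1L]) != nchar(alignment[2L]))
    stop("expected two aligned sequences of equal padded length",
         call. = FALSE)
  a <- strsplit(alignment[1L], "")[[1L]]
  b <- strsplit(alignment[2L], "")[[1L]]
  ok <- a != "-" & b != "-"
  if (!any(ok))
    stop("undefined distance: no comparable (gap-free) columns",
         call. = FALSE)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' p-distances (or Jukes--Cantor corrected distances) with pairwise gap
#' deletion, computed with `ape::dist.dna`.
#'
#' @param alignment Character matrix (rows = sequences, `"-"` gaps) with
#'   row names, e.g. a `qb_cohort$alignment`.
#' @param model `"p"` (default) or `"JC69"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("p", "JC69")) {
  model <- match.arg(model)
  stopifnot(is.matrix(alignment), !is.null(rownames(alignment)))
  dna <- ape::as.DNAbin(tolower(alignment))
  D <- ape::dist.dna(dna, model = if (model == "p") "raw" else "JC69",
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  if (any(!is.finite(D)))
    stop("undefined distance: some sequence pair shares no comparable ",
         "columns", call. = FALSE)
  D
}

#' Neighbour-joining tree
#'
#' Saitou--Nei agglomeration with the standard Q-criterion. Negative branch
#' lengths are clamped to zero and ties in the Q-minimization are broken
#' deterministically by label order (an internal node sorts by the smallest
#' tip label below it), so the tree is reproducible. Sets of
#' indistinguishable sequences (pairwise distance zero and identical
#' distances to everything else) are collapsed before agglomeration and
#' re-attached afterwards as zero-length fans on their representative's
#' branch: plain NJ does not keep such sets together (once clusters start
#' collapsing, the Q-criterion can interleave cross-cluster joins among the
#' remaining zero-distance leaves), whereas their within-set arrangement
#' carries no information and the fan keeps each set monophyletic.
#'
#' @param D Symmetric distance matrix with >= 3 labelled rows (a `dist`
#'   object is accepted).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (is.data.frame(D)) D <- as.matrix(D)
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) < 3L)
    stop("neighbour joining needs at least 3 labelled sequences",
         call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- paste0("t", seq_len(nrow(D)))
  labels <- rownames(D)
  if (anyDuplicated(labels))
    stop("sequence labels must be unique", call. = FALSE)

  # collapse indistinguishable leaves (d = 0 and identical rows)
  nfull <- nrow(D)
  group <- integer(nfull)
  for (i in seq_len(nfull)) {
    if (group[i] > 0L) next
    group[i] <- max(group) + 1L
    for (j in seq_len(nfull)) {
      if (j == i || group[j] > 0L || D[i, j] != 0) next
      if (all(D[i, -c(i, j)] == D[j, -c(i, j)])) group[j] <- group[i]
    }
  }
  members <- split(labels, group)
  members <- lapply(members, sort)
  # if fewer than 3 distinguishable groups remain (e.g. a bootstrap
  # replicate that erases all differences between two classes), split
  # singletons off the largest group so agglomeration still has 3 lineages
  while (length(members) < 3L) {
    sizes <- vapply(members, length, 0L)
    big <- which(sizes == max(sizes))
    if (max(sizes) < 2L)
      stop("neighbour joining needs at least 3 sequences", call. = FALSE)
    big <- big[order(vapply(members[big], `[[`, "", 1L))][1L]
    members <- c(members, list(members[[big]][1L]))
    members[[big]] <- members[[big]][-1L]
  }
  # representative = smallest label; fans substituted into the newick later
  reps <- vapply(members, `[[`, "", 1L)
  fan_of <- vapply(members, function(g) {
    if (length(g) == 1L) g
    else paste0("(", paste0(g, ":0", collapse = ","), ")")
  }, "")
  rep_idx <- match(reps, labels)
  D <- D[rep_idx, rep_idx, drop = FALSE]
  m <- nrow(D)
  # subtree newick fragments and sort keys (smallest tip label below)
  sub <- unname(fan_of)
  key <- unname(reps)
  brlen <- function(x) sprintf("%.12g", max(x, 0))
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ck1 <- pmin(key[cand[, 1L]], key[cand[, 2L]])
    ck2 <- pmax(key[cand[, 1L]], key[cand[, 2L]])
    pick <- order(ck1, ck2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", sub[i], ":", brlen(li), ",",
                     sub[j], ":", brlen(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], merged)
    key <- c(key[keep], min(key[i], key[j]))
    m <- m - 1L
  }
  # final three lineages: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", brlen(la), ",", sub[2], ":", brlen(lb),
                ",", sub[3], ":", brlen(lc), ");")
  ape::read.tree(text = nwk)
}

# Tips below each node of a phylo tree (indices), via one postorder pass.
.tips_below <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(below, sort)
}

# Canonical key of the bipartition separating tip set `tips` (indices into
# `labels`): the side not containing the first label, as a sorted string.
.bipart_key <- function(tips, n) {
  side <- if (1L %in% tips) setdiff(seq_len(n), tips) else tips
  paste(side, collapse = ",")
}

# All non-trivial bipartition keys of a tree, using tip *labels* mapped to
# the reference ordering `ref_labels` so keys are comparable across trees.
.tree_bipartitions <- function(tree, ref_labels) {
  n <- length(ref_labels)
  idx <- match(tree$tip.label, ref_labels)
  below <- .tips_below(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= length(tree$tip.label)) next
    tips <- sort(idx[below[[ch]]])
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    keys <- c(keys, .bipart_key(tips, n))
  }
  unique(keys)
}

#' Bootstrap support for the internal edges of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of `tree` the
#' fraction of replicate trees containing the same bipartition.
#'
#' @param alignment Character matrix with row names (all sequences).
#' @param tree The reference tree (default: NJ tree of `alignment`).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed.
#' @param model Distance model, as in [distance_matrix()].
#' @return Data frame with one row per non-trivial internal edge of the
#'   reference tree: `node` (child node id), `n_tips`, `support` in
#'   \[0, 1\]. The bipartition key is kept in attribute `"keys"`.
#' @export
bootstrap_support <- function(alignment, tree = NULL, n_replicates = 100L,
                              seed = NULL, model = "p") {
  stopifnot(is.matrix(alignment), n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- nj_tree(distance_matrix(alignment, model))
  ref_labels <- sort(rownames(alignment))
  n <- length(ref_labels)
  idx <- match(tree$tip.label, ref_labels)
  below <- .tips_below(tree)
  ntip <- length(tree$tip.label)
  edge_nodes <- integer(0); edge_keys <- character(0); edge_ntips <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) next
    tips <- sort(idx[below[[ch]]])
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    edge_nodes <- c(edge_nodes, ch)
    edge_keys <- c(edge_keys, .bipart_key(tips, n))
    edge_ntips <- c(edge_ntips, length(tips))
  }
  counts <- integer(length(edge_keys))
  replicate_keys <- vector("list", n_replicates)
  L <- ncol(alignment)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    Dr <- distance_matrix(alignment[, cols, drop = FALSE], model)
    tr <- nj_tree(Dr)
    keys_r <- .tree_bipartitions(tr, ref_labels)
    replicate_keys[[r]] <- keys_r
    counts <- counts + (edge_keys %in% keys_r)
  }
  out <- data.frame(node = edge_nodes, n_tips = edge_ntips,
                    support = counts / n_replicates)
  attr(out, "keys") <- edge_keys
  attr(out, "replicate_keys") <- replicate_keys
  attr(out, "ref_labels") <- ref_labels
  out
}

#' Extract k clades from a tree by removing long internal edges
#'
#' Removes the `k - 1` internal edges that maximize edge length (ties
#' broken by bootstrap support when given, then by tip-label order) among
#' edge sets whose removal yields `k` groups that each contain at least one
#' leaf and are each separable by a single tree edge (bipartition groups).
#'
#' @param tree A `phylo` tree with >= k leaves.
#' @param k Number of groups (default 3).
#' @param support Optional data frame from [bootstrap_support()] used for
#'   tie-breaking and to report per-group support.
#' @return A list of class `clade_partition`: `groups` (list of `k`
#'   character vectors of tip labels), `edges` (child node ids of the
#'   removed edges), `support` (named numeric, `NA` where unknown).
#' @export
extract_k_clades <- function(tree, k = 3L, support = NULL) {
  ntip <- length(tree$tip.label)
  if (ntip < k) stop("tree has fewer than k leaves", call. = FALSE)
  below <- .tips_below(tree)
  cand <- integer(0); len <- numeric(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) next
    nb <- length(below[[ch]])
    if (nb < 1L || nb >= ntip) next
    cand <- c(cand, ch); len <- c(len, tree$edge.length[e])
  }
  if (length(cand) < k - 1L)
    stop("partition failure: not enough internal edges for k = ", k,
         call. = FALSE)
  sup <- rep(NA_real_, length(cand))
  if (!is.null(support)) sup <- support$support[match(cand, support$node)]
  first_tip <- vapply(cand, function(nd)
    min(tree$tip.label[below[[nd]]]), "")
  ord <- order(-len, -ifelse(is.na(sup), -1, sup), first_tip)
  cand <- cand[ord]; len <- len[ord]; sup <- sup[ord]

  all_tips <- seq_len(ntip)
  # single-edge-separable tip sets (either side of any edge, plus leaves)
  sep_keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    tips <- below[[ch]]
    sep_keys <- c(sep_keys, paste(tips, collapse = ","),
                  paste(setdiff(all_tips, tips), collapse = ","))
  }
  groups_from <- function(sel) {
    sets <- lapply(sel, function(nd) below[[nd]])
    sizes <- vapply(sets, length, 0L)
    sets <- sets[order(-sizes)]
    groups <- list()
    remaining_parent <- all_tips
    # laminar family: subtract each set from its smallest strict superset
    assigned <- rep(0L, ntip)  # group id owning each tip so far
    for (s in seq_along(sets)) {
      g <- sets[[s]]
      owner <- assigned[g[1L]]
      if (owner > 0L) groups[[owner]] <- setdiff(groups[[owner]], g)
      groups[[length(groups) + 1L]] <- g
      assigned[g] <- length(groups)
    }
    root_group <- all_tips[assigned == 0L]
    groups <- c(groups, list(root_group))
    groups
  }
  sel_idx <- utils::combn(seq_along(cand), k - 1L, simplify = FALSE)
  for (sel in sel_idx) {
    sel_nodes <- cand[sel]
    if (anyDuplicated(vapply(sel_nodes, function(nd)
      paste(below[[nd]], collapse = ","), ""))) next
    groups <- groups_from(sel_nodes)
    if (length(groups) != k) next
    if (any(vapply(groups, length, 0L) < 1L)) next
    keys <- vapply(groups, function(g) paste(sort(g), collapse = ","), "")
    if (!all(keys %in% sep_keys)) next
    out_groups <- lapply(groups, function(g) sort(tree$tip.label[g]))
    out_sup <- sup[sel]
    return(structure(list(groups = out_groups, edges = sel_nodes,
                          edge_support = out_sup, tree = tree),
                     class = "clade_partition"))
  }
  stop("partition failure: no set of ", k - 1L, " internal edges yields ",
       k, " bipartition-separable non-empty groups", call. = FALSE)
}

#' @export
print.clade_partition <- function(x, ...) {
  labs <- names(x$groups)
  if (is.null(labs)) labs <- paste0("group", seq_along(x$groups))
  for (i in seq_along(x$groups))
    cat(labs[i], ": ", length(x$groups[[i]]), " leaves\n", sep = "")
  invisible(x)
}

#' Label extracted clades by their composition
#'
#' Applies the composition rules used to interpret the three clades of the
#' sex-linked haplotype tree: the group whose sequences all come from males
#' is labelled `Y`; among the rest, the group containing only individuals
#' with rearranged karyotypes is `Xr`; the remainder is `Xn`. If a rule
#' matches zero or several groups, labelling fails with a message listing
#' the group compositions.
#'
#' @param partition A `clade_partition` with 3 groups.
#' @param meta Data frame with columns `leaf` (tip label), `sex`
#'   (`"female"`/`"male"`) and `category` (`"normal"`/`"rearranged"`),
#'   covering all leaves.
#' @return The partition with `groups` named `Y`, `Xr`, `Xn` and a
#'   `composition` summary attached.
#' @export
label_clades <- function(partition, meta) {
  stopifnot(inherits(partition, "clade_partition"))
  if (length(partition$groups) != 3L)
    stop("composition labelling expects exactly 3 groups", call. = FALSE)
  leaves <- unlist(partition$groups)
  if (!all(leaves %in% meta$leaf))
    stop("metadata does not cover all leaves", call. = FALSE)
  sx <- meta$sex[match(leaves, meta$leaf)]
  comp <- lapply(partition$groups, function(g) {
    i <- match(g, meta$leaf)
    list(n = length(g),
         all_male = all(meta$sex[i] == "male"),
         all_rearranged = all(meta$category[i] == "rearranged"))
  })
  describe <- function() paste(vapply(seq_along(comp), function(i)
    sprintf("group %d: n=%d, all_male=%s, all_rearranged=%s", i,
            comp[[i]]$n, comp[[i]]$all_male, comp[[i]]$all_rearranged), ""),
    collapse = "; ")
  y_idx <- which(vapply(comp, `[[`, NA, "all_male"))
  if (length(y_idx) != 1L)
    stop("labelling failure: ", length(y_idx), " all-male group(s) [",
         describe(), "]", call. = FALSE)
  rest <- setdiff(seq_along(comp), y_idx)
  xr_idx <- rest[vapply(comp[rest], `[[`, NA, "all_rearranged")]
  if (length(xr_idx) != 1L)
    stop("labelling failure: ", length(xr_idx),
         " rearranged-only group(s) among the non-Y groups [", describe(),
         "]", call. = FALSE)
  xn_idx <- setdiff(rest, xr_idx)
  ord <- c(y_idx, xr_idx, xn_idx)
  partition$groups <- partition$groups[ord]
  names(partition$groups) <- c("Y", "Xr", "Xn")
  partition$edge_support <- partition$edge_support  # order refers to edges
  partition$composition <- comp[ord]
  partition
}

#' Infer and label haplogroups from an alignment
#'
#' End-to-end inference: distance matrix, NJ tree, optional bootstrap,
#' extraction of `k` clades and composition-based labelling.
#'
#' @param alignment Character matrix of aligned sequences with header row
#'   names, e.g. `qb_cohort$alignment`.
#' @param meta Leaf metadata as in [label_clades()]; for a `qb_cohort` use
#'   [cohort_leaf_meta()].
#' @param k Number of clades (default 3).
#' @param n_replicates Bootstrap replicates (0 = no bootstrap).
#' @param seed Optional integer seed for the bootstrap.
#' @param model Distance model (`"p"` or `"JC69"`).
#' @return A list of class `haplogroup_fit`: `tree`, `partition` (labelled),
#'   `assignments` (data frame leaf/clade), `support` (bootstrap table or
#'   `NULL`), `clade_support` (named supports of the removed edges).
#' @export
infer_haplogroups <- function(alignment, meta, k = 3L, n_replicates = 0L,
                              seed = NULL, model = "p") {
  D <- distance_matrix(alignment, model)
  tree <- nj_tree(D)
  sup <- NULL
  if (n_replicates > 0L)
    sup <- bootstrap_support(alignment, tree, n_replicates, seed, model)
  part <- extract_k_clades(tree, k, sup)
  part <- label_clades(part, meta)
  assignments <- data.frame(
    leaf = unlist(part$groups),
    clade = rep(names(part$groups),
                vapply(part$groups, length, 0L)),
    stringsAsFactors = FALSE)
  clade_support <- .group_supports(part, tree, sup)
  structure(list(tree = tree, partition = part, assignments = assignments,
                 support = sup, clade_support = clade_support),
            class = "haplogroup_fit")
}

# Bootstrap support of each labelled group's bipartition, counted directly
# across the stored replicate bipartition sets.
.group_supports <- function(partition, tree, sup) {
  if (is.null(sup)) return(NULL)
  ref_labels <- attr(sup, "ref_labels")
  n <- length(ref_labels)
  reps <- attr(sup, "replicate_keys")
  out <- vapply(partition$groups, function(g) {
    tips <- sort(match(g, ref_labels))
    key <- .bipart_key(tips, n)
    mean(vapply(reps, function(ks) key %in% ks, NA))
  }, 0)
  names(out) <- names(partition$groups)
  out
}

#' @export
print.haplogroup_fit <- function(x, ...) {
  cat("<haplogroup fit> ", length(x$tree$tip.label), " leaves, ",
      length(x$partition$groups), " clades\n", sep = "")
  for (nm in names(x$partition$groups)) {
    s <- if (!is.null(x$clade_support)) x$clade_support[[nm]] else NA
    cat("  ", nm, ": ", length(x$partition$groups[[nm]]), " leaves",
        if (!is.na(s)) sprintf(" (bootstrap %.2f)", s) else "", "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
plot.haplogroup_fit <- function(x, ...) {
  cols <- c(Y = "firebrick", Xr = "dodgerblue3", Xn = "darkgreen")
  tipcol <- cols[x$assignments$clade[match(x$tree$tip.label,
                                           x$assignments$leaf)]]
  ape::plot.phylo(x$tree, tip.color = tipcol, cex = 0.4,
                  type = "unrooted", ...)
  invisible(x)
}

#' Leaf metadata for labelling a simulated cohort's clades
#'
#' @param cohort A `qb_cohort`.
#' @return Data frame with `leaf`, `sex`, `category` (normal/rearranged)
#'   and the generator-truth `class` per sequence.
#' @export
cohort_leaf_meta <- function(cohort) {
  stopifnot(inherits(cohort, "qb_cohort"))
  cat_of <- ifelse(cohort$individuals$karyomorph == "I", "normal",
                   "rearranged")
  data.frame(
    leaf = cohort$records$header,
    sex = cohort$records$sex,
    category = cat_of[match(cohort$records$id, cohort$individuals$id)],
    class = cohort$records$class,
    stringsAsFactors = FALSE)
}
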