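#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of mismatching positions per pair, with pairwise deletion of
#' positions where either sequence carries a gap (`-` or `.`).
#'
#' @param msa named character vector of equal-length gapped sequences.
#' @return object of class `dist_matrix`: symmetric matrix with taxa
#'   dimnames.
#' @export
p_distance <- function(msa) {
  stopifnot(length(msa) >= 2)
  if (length(unique(nchar(msa))) != 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  d <- pdist_from_matrix(m)
  class(d) <- c("dist_matrix", class(d))
  d
}

pdist_from_matrix <- function(m) {
  n <- nrow(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("no comparable positions between ", rownames(m)[i], " and ",
             rownames(m)[j])
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree construction
#'
#' Classic agglomerative neighbor joining: at each step the pair minimizing
#' the Q-criterion is joined, with ties broken by the smallest (i, j) index
#' pair, and branch lengths come from the standard formulas. Negative
#' branch-length estimates are clamped to zero and flagged
#' (`attr(tree, "clamped")`). Exact on additive distance matrices.
#'
#' @param dm symmetric distance matrix with taxa dimnames (n >= 3).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  d <- as.matrix(unclass(dm))
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("non-symmetric matrix")
  n <- nrow(d)
  stopifnot(n >= 3)
  labs <- rownames(d)
  reps <- labs
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (nrow(d) > 3) {
    k <- nrow(d)
    r <- rowSums(d)
    Q <- (k - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- d[i, j] - bi
    newrep <- sprintf("(%s:%s,%s:%s)", reps[i], fmt(bi), reps[j], fmt(bj))
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    reps <- c(reps[keep], newrep)
    d <- d2
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", reps[1], fmt(b1),
                 reps[2], fmt(b2), reps[3], fmt(b3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the taxa; the stored side is the one NOT
# containing the overall lexicographically smallest taxon.
tree_splits <- function(tree) {
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  sides <- list()
  for (p in parts) {
    tips <- labs[p]
    if (length(tips) <= 1 || length(tips) >= length(labs) - 1) next
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    key <- paste(sort(tips), collapse = "\r")
    if (!key %in% keys) {
      keys <- c(keys, key)
      sides[[key]] <- sort(tips)
    }
  }
  sides
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing its bipartition. Seeded and
#' deterministic for a given seed.
#'
#' @param msa named character vector of equal-length gapped sequences.
#' @param n_reps bootstrap replicates (the classic choice is 1000).
#' @param seed RNG seed.
#' @return the original NJ tree with `node.label` supports (percent) and a
#'   `supports` attribute: named vector, bipartition key -> percent.
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  tree <- neighbor_joining(pdist_from_matrix(m))
  orig <- tree_splits(tree)
  counts <- setNames(numeric(length(orig)), names(orig))
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_tree <- neighbor_joining(pdist_from_matrix(m[, cols, drop = FALSE]))
    rep_keys <- names(tree_splits(rep_tree))
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  # node labels: support of the edge above each internal node
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  node_lab <- vapply(seq_along(parts), function(k) {
    tips <- labs[parts[[k]]]
    if (length(tips) <= 1 || length(tips) >= length(labs) - 1) return("")
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    key <- paste(sort(tips), collapse = "\r")
    if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }, character(1))
  tree$node.label <- node_lab
  attr(tree, "supports") <- supports
  attr(tree, "sides") <- orig
  tree
}

#' Assign family members to groups from a supported tree
#'
#' A member is assigned to group G iff the smallest bipartition side with
#' bootstrap support strictly greater than `support_min` that contains the
#' member and at least one labeled reference contains references of group G
#' only; otherwise the member is `"unplaced"`.
#'
#' @param tree a tree from [bootstrap_support()] (carries split supports).
#' @param reference_labels named character vector: reference leaf -> group.
#' @param support_min support threshold in percent (strictly greater-than).
#' @return named character vector: member leaf -> group or `"unplaced"`.
#' @export
assign_groups <- function(tree, reference_labels, support_min = 46) {
  supports <- attr(tree, "supports")
  sides <- attr(tree, "sides")
  if (is.null(supports) || is.null(sides))
    stop("tree carries no supports; run bootstrap_support() first")
  labs <- tree$tip.label
  refs <- names(reference_labels)
  if (anyDuplicated(refs)) {
    dup <- refs[duplicated(refs)]
    conf <- vapply(dup, function(r)
      length(unique(reference_labels[refs == r])) > 1, logical(1))
    if (any(conf)) stop("reference with conflicting labels: ",
                        paste(dup[conf], collapse = ", "))
  }
  missing <- setdiff(refs, labs)
  if (length(missing))
    stop("references absent from tree: ", paste(missing, collapse = ", "))
  members <- setdiff(labs, refs)
  ok_keys <- names(supports)[supports > support_min]
  out <- setNames(rep("unplaced", length(members)), members)
  for (mem in members) {
    cands <- lapply(ok_keys, function(k) {
      side <- sides[[k]]
      if (mem %in% side) side else setdiff(labs, side)
    })
    cands <- cands[order(lengths(cands))]
    for (side in cands) {
      hit_refs <- intersect(side, refs)
      if (length(hit_refs) == 0) next
      grp <- unique(reference_labels[hit_refs])
      if (length(grp) == 1) out[mem] <- grp
      break
    }
  }
  out
}

#' Write a tree to Newick
#'
#' @param tree an `ape::phylo` (supports, if present, are written as
#'   internal node labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Simple progressive multiple aligner (convenience)
#'
#' A deliberately simple progressive aligner -- average-linkage guide tree
#' on 3-mer composition distances, then profile-profile Needleman-Wunsch
#' merges under BLOSUM62 with a linear gap penalty. Provided so that
#' unaligned input can reach [p_distance()]; it is NOT a reimplementation
#' of any production aligner, and serious use should supply an external
#' alignment.
#'
#' @param seqs named character vector of protein sequences.
#' @param gap linear gap penalty.
#' @return named character vector of equal-length gapped sequences.
#' @export
align_progressive <- function(seqs, gap = 8) {
  n <- length(seqs)
  stopifnot(n >= 2)
  if (n == 2) return(merge_profiles(seqs[1], seqs[2], gap))
  kmer <- function(s) {
    k <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    tabulate(match(k, unique_kmers), length(unique_kmers)) / length(k)
  }
  unique_kmers <- unique(unlist(lapply(seqs, function(s)
    substring(s, 1:(nchar(s) - 2), 3:nchar(s)))))
  comp <- t(vapply(seqs, kmer, numeric(length(unique_kmers))))
  hc <- hclust(dist(comp), method = "average")
  clusters <- lapply(seq_len(n), function(i) seqs[i])
  merged <- vector("list", n - 1)
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(idx) if (idx < 0) clusters[[-idx]] else merged[[idx]]
    merged[[s]] <- merge_profiles_multi(pick(hc$merge[s, 1]),
                                        pick(hc$merge[s, 2]), gap)
  }
  out <- merged[[n - 1]]
  out[names(seqs)]
}

profile_freqs <- function(aligned) {
  m <- do.call(rbind, strsplit(aligned, ""))
  L <- ncol(m)
  f <- matrix(0, 20, L)
  for (j in seq_len(L)) {
    cnt <- table(factor(m[, j], levels = AA_ALPHABET))
    f[, j] <- as.numeric(cnt) / nrow(m)
  }
  f
}

merge_profiles_multi <- function(a, b, gap) {
  fa <- profile_freqs(a); fb <- profile_freqs(b)
  cell <- t(fa) %*% blosum62() %*% fb
  steps <- .nw_steps(cell, gap)
  ia <- 0L; ib <- 0L
  La <- nchar(a[1]); Lb <- nchar(b[1])
  outa <- character(length(steps)); outb <- character(length(steps))
  cols_a <- integer(0); cols_b <- integer(0)
  for (s in seq_along(steps)) {
    if (steps[s] == 1) { ia <- ia + 1L; ib <- ib + 1L
      cols_a <- c(cols_a, ia); cols_b <- c(cols_b, ib)
    } else if (steps[s] == 2) { ia <- ia + 1L
      cols_a <- c(cols_a, ia); cols_b <- c(cols_b, NA)
    } else { ib <- ib + 1L
      cols_a <- c(cols_a, NA); cols_b <- c(cols_b, ib)
    }
  }
  expand <- function(seqv, cols) {
    vapply(seqv, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ifelse(is.na(cols), "-", ch[cols]), collapse = "")
    }, character(1))
  }
  c(expand(a, cols_a), expand(b, cols_b))
}

merge_profiles <- function(a, b, gap) merge_profiles_multi(a, b, gap)
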