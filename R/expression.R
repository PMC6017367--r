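#' FPKM normalization
#'
#' `FPKM = counts * 1e9 / (gene_length_bp * library_size)`. When `counts`
#' is a matrix, `library_size` defaults to the column sums (note: the
#' original scale uses mapped-read totals; column sums are the in-matrix
#' proxy).
#'
#' @param counts non-negative count vector or genes x samples matrix.
#' @param gene_length_bp per-gene transcript lengths (bp, > 0).
#' @param library_size per-sample library sizes (> 0).
#' @return object of class `expr_matrix` (matrix with a `transform`
#'   attribute `"fpkm"`), or a numeric vector for vector input.
#' @export
fpkm <- function(counts, gene_length_bp, library_size = NULL) {
  if (any(counts < 0)) stop("negative counts")
  stopifnot(all(gene_length_bp > 0))
  if (is.matrix(counts)) {
    if (is.null(library_size)) library_size <- colSums(counts)
    stopifnot(all(library_size > 0))
    f <- sweep(counts * 1e9 / gene_length_bp, 2, library_size, "/")
    structure(f, transform = "fpkm", class = c("expr_matrix", "matrix"))
  } else {
    stopifnot(!is.null(library_size), all(library_size > 0))
    counts * 1e9 / (gene_length_bp * library_size)
  }
}

#' Log-transform an FPKM matrix
#'
#' Elementwise `log10(FPKM + 0.01)`, so 0 maps to -2. Refuses to transform
#' twice (state flag).
#'
#' @param m an `expr_matrix` in raw FPKM state.
#' @return the transformed `expr_matrix` (state `"log10"`).
#' @export
log_transform <- function(m) {
  state <- attr(m, "transform")
  if (identical(state, "log10"))
    stop("matrix is already log-transformed")
  out <- log10(unclass(m) + 0.01)
  structure(out, transform = "log10", class = c("expr_matrix", "matrix"))
}

#' Hierarchical clustering for heat-map ordering
#'
#' Agglomerative clustering (default: average linkage on Euclidean
#' distances) of rows, via [stats::hclust()]; returns the merge tree and
#' the dendrogram leaf order.
#'
#' @param m numeric matrix (>= 2 rows, no missing values).
#' @param linkage linkage method.
#' @param metric distance metric.
#' @return list(order (row indices), labels (ordered rownames),
#'   merge, height, hclust).
#' @export
hierarchical_cluster <- function(m, linkage = "average",
                                 metric = "euclidean") {
  m <- unclass(m)
  stopifnot(nrow(m) >= 2)
  if (any(!is.finite(m))) stop("matrix contains missing values")
  hc <- hclust(dist(m, method = metric), method = linkage)
  list(order = hc$order,
       labels = if (!is.null(rownames(m))) rownames(m)[hc$order],
       merge = hc$merge, height = hc$height, hclust = hc)
}

#' Differential-expression calls between two conditions
#'
#' Per gene, the fold change of mean library-size-normalized expression
#' (counts per million; a 0.5 pseudo-count stabilizes zeros), a two-sided
#' permutation p-value on replicate labels (exhaustive when the number of
#' label splits is at most `max_exhaustive`, otherwise `n_perm` sampled
#' permutations, seeded), and Benjamini-Hochberg adjustment. A gene is
#' called up or down only when both gates hold: fold change at least
#' `fc_min` AND adjusted p below `alpha` (a raw-p mode is available via
#' `adjust = FALSE`).
#'
#' @param counts_a,counts_b genes x replicates count matrices (>= 2
#'   replicates each, same genes).
#' @param gene_lengths optional transcript lengths; fold changes are
#'   length-invariant, lengths only affect the reported means.
#' @param fc_min fold-change gate (linear scale).
#' @param alpha significance gate.
#' @param library_size per-sample library sizes for normalization
#'   (columns of A then B). Defaults to column sums; pass equal values
#'   (e.g. all 1) for counts already on a common scale.
#' @param adjust use BH-adjusted p-values (the default criterion).
#' @param seed RNG seed for sampled permutations.
#' @param max_exhaustive exhaustive-enumeration cap on label splits.
#' @param n_perm sampled permutations when not exhaustive.
#' @return data.frame (gene, mean_a, mean_b, lfc, p, padj, call) with
#'   `call` in {up, down, ns}.
#' @export
call_de <- function(counts_a, counts_b, gene_lengths = NULL, fc_min = 2,
                    alpha = 0.05, library_size = NULL, adjust = TRUE,
                    seed = 1, max_exhaustive = 1000, n_perm = 10000) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2)
    stop("each condition needs at least 2 replicates")
  stopifnot(nrow(counts_a) == nrow(counts_b))
  na <- ncol(counts_a); nb <- ncol(counts_b)
  x <- cbind(counts_a, counts_b)
  # library-size normalization (counts per million)
  libs <- if (is.null(library_size)) colSums(x)
          else rep_len(library_size, na + nb)
  libs[libs == 0] <- 1
  xn <- sweep(x, 2, libs / 1e6, "/")
  stat <- function(idx_a) {
    ma <- rowMeans(xn[, idx_a, drop = FALSE])
    mb <- rowMeans(xn[, -idx_a, drop = FALSE])
    abs(log2((mb + 0.5) / (ma + 0.5)))
  }
  obs_ma <- rowMeans(xn[, seq_len(na), drop = FALSE])
  obs_mb <- rowMeans(xn[, na + seq_len(nb), drop = FALSE])
  lfc <- log2((obs_mb + 0.5) / (obs_ma + 0.5))
  obs <- abs(lfc)

  # mid-p convention: ties between permuted and observed statistics get
  # half weight, keeping the null distribution near-uniform on discrete
  # count data (plain >= counting is markedly conservative there)
  n_splits <- choose(na + nb, na)
  if (n_splits <= max_exhaustive) {
    splits <- combn(na + nb, na)
    gt <- eq <- rep(0, nrow(x))
    for (k in seq_len(ncol(splits))) {
      s <- stat(splits[, k])
      gt <- gt + (s > obs + 1e-12)
      eq <- eq + (abs(s - obs) <= 1e-12)
    }
    p <- (gt + 0.5 * eq) / ncol(splits)
  } else {
    set.seed(as.integer(seed))
    gt <- rep(0, nrow(x)); eq <- rep(1, nrow(x)) # identity is a tie
    for (k in seq_len(n_perm)) {
      s <- stat(sample.int(na + nb, na))
      gt <- gt + (s > obs + 1e-12)
      eq <- eq + (abs(s - obs) <= 1e-12)
    }
    p <- (gt + 0.5 * eq) / (n_perm + 1)
  }
  padj <- p.adjust(p, method = "BH")
  crit <- if (adjust) padj else p
  call <- rep("ns", nrow(x))
  call[crit < alpha & lfc >= log2(fc_min)] <- "up"
  call[crit < alpha & lfc <= -log2(fc_min)] <- "down"
  data.frame(gene = rownames(x) %||% seq_len(nrow(x)),
             mean_a = obs_ma, mean_b = obs_mb, lfc = lfc,
             p = p, padj = padj, call = call, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative qPCR expression by the delta-Ct method
#'
#' `2^-(Ct_target - Ct_reference)`, the reference being the internal
#' control gene.
#'
#' @param ct_target,ct_reference finite Ct values (vectorized).
#' @return relative expression (> 0).
#' @export
qpcr_relative <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' Two-fold qPCR regulation call
#'
#' Ratio r = treated / control: `"up"` when r >= fold_min, `"down"` when
#' r <= 1/fold_min (boundaries inclusive), else `"ns"`.
#'
#' @param rel_treated,rel_control relative expression values (> 0).
#' @param fold_min fold threshold.
#' @return character vector of calls.
#' @export
qpcr_classify <- function(rel_treated, rel_control, fold_min = 2) {
  if (any(rel_treated <= 0) || any(rel_control <= 0))
    stop("relative expression must be positive")
  r <- rel_treated / rel_control
  ifelse(r >= fold_min, "up", ifelse(r <= 1 / fold_min, "down", "ns"))
}

#' Expression presence per gene and tissue
#'
#' A gene counts as expressed in a sample iff its FPKM reaches `fpkm_min`
#' (with threshold 0, any nonzero value counts). Reports the per-tissue
#' percentage of expressed genes and the all-tissue percentage (genes
#' expressed in every tested tissue).
#'
#' @param m an `expr_matrix` in raw FPKM state (samples = tissues).
#' @param fpkm_min presence threshold.
#' @return list(presence matrix, per_tissue_pct, all_tissue_pct).
#' @export
expression_presence <- function(m, fpkm_min = 1) {
  if (identical(attr(m, "transform"), "log10"))
    stop("expression_presence expects raw FPKM values")
  pres <- if (fpkm_min > 0) unclass(m) >= fpkm_min else unclass(m) > 0
  list(presence = pres,
       per_tissue_pct = 100 * colMeans(pres),
       all_tissue_pct = 100 * mean(apply(pres, 1, all)))
}
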