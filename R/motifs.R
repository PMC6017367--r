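#' Exon/intron structure of a gene model
#'
#' @param gm a [gene_model].
#' @return object of class `gene_structure`: exon spans, intron spans
#'   (inter-exon gaps in genome order) and the intron count.
#' @export
gene_structure <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
    stop("overlapping exons in gene ", gm$gene_id)
  introns <- if (nrow(ex) > 1)
    cbind(start = ex[-nrow(ex), 2] + 1L, end = ex[-1, 1] - 1L)
  else matrix(integer(), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  structure(list(gene_id = gm$gene_id, exons = ex, introns = introns,
                 intron_count = nrow(ex) - 1L, strand = gm$strand),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure> %s: %d exon(s), %d intron(s)\n",
              x$gene_id, nrow(x$exons), x$intron_count))
  invisible(x)
}

# --- EM motif elicitation -------------------------------------------------
#
# Simplified MEME-style machinery: per motif, widths from a geometric grid
# inside [w_min, w_max] are tried; for each width EM (ZOOPS or ANR site
# model) runs from sampled n-mer seeds to convergence; the winning width is
# picked after trimming uninformative flanking columns, by the
# finite-sample-adjusted relative-entropy score. Reported sites are then
# probabilistically erased before the next motif is sought.

window_index <- function(lens, w) {
  # all windows of width w across sequences: (seq, offset) pairs
  out <- lapply(seq_along(lens), function(i) {
    if (lens[i] < w) return(NULL)
    cbind(seq = i, off = seq_len(lens[i] - w + 1))
  })
  do.call(rbind, out)
}

# erasure prior per window: product of positional erasure weights,
# computed through cumulative log sums on the concatenated weights
window_erasure <- function(erase, cum, wins, w) {
  lg <- cumsum(c(0, log(pmax(unlist(erase), 1e-300))))
  gs <- cum[wins[, 1]] + wins[, 2] - 1L  # 0-based global window starts
  exp(lg[gs + w + 1L] - lg[gs + 1L])
}

# log-probability of every window under a positions-x-aa log matrix
window_scores <- function(g, gs, logmat, w) {
  sc <- numeric(length(gs))
  for (j in seq_len(w)) sc <- sc + logmat[j, g[gs + j] + 1L]
  sc
}

em_motif <- function(enc, lens, w, bg, seed_window, mode, erase,
                     max_iter = 100, tol = 1e-4) {
  wins <- window_index(lens, w)
  if (is.null(wins)) return(NULL)
  nw <- nrow(wins)
  g <- unlist(enc, use.names = FALSE)
  cum <- cumsum(c(0L, lens))
  gs <- cum[wins[, 1]] + wins[, 2] - 1L
  uw <- window_erasure(erase, cum, wins, w)
  bg_mat <- matrix(rep(log(bg), each = w), nrow = w)
  sc_b <- window_scores(g, gs, bg_mat, w)
  # init PWM from the seed window, residues mixed with background
  pwm <- matrix(rep(bg, each = w), nrow = w)
  sw <- seed_window
  for (j in seq_len(w)) {
    a <- enc[[sw[1]]][sw[2] + j - 1] + 1L
    pwm[j, ] <- 0.3 * bg
    pwm[j, a] <- pwm[j, a] + 0.7
  }
  lambda <- min(0.3, length(enc) / nw)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sc_m <- window_scores(g, gs, log(pwm), w)
    a <- log(lambda * uw + 1e-300) + sc_m
    b <- log(1 - lambda + 1e-300) + sc_b
    mx <- pmax(a, b)
    z <- exp(a - mx) / (exp(a - mx) + exp(b - mx))
    ll <- sum(mx + log(exp(a - mx) + exp(b - mx)))
    if (mode == "zoops") {
      # at most one site per sequence: cap the per-sequence posterior mass
      tot <- rowsum(z, wins[, 1])
      fac <- pmin(1, 1 / pmax(tot[wins[, 1], 1], 1e-300))
      z <- z * ifelse(tot[wins[, 1], 1] > 1, fac, 1)
    }
    # M-step
    cnt <- matrix(0, w, 20)
    for (j in seq_len(w)) {
      rs <- rowsum(z, g[gs + j] + 1L)
      cnt[j, as.integer(rownames(rs))] <- rs[, 1]
    }
    nsites <- sum(z)
    pwm <- (cnt + 0.25 * matrix(rep(bg, each = w), nrow = w)) /
      (nsites + 0.25)
    lambda <- max(1e-6, min(0.5, nsites / nw))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pwm = pwm, z = z, wins = wins, nsites = sum(z), w = w,
       loglik = ll, trace = trace)
}

# relative entropy per column (bits), adjusted for finite-sample bias
adj_re <- function(pwm, bg, nsites) {
  re <- apply(pwm, 1, function(p) sum(p * log2(pmax(p, 1e-12) / bg)))
  bias <- 19 / (2 * max(nsites, 1) * log(2))
  re - bias
}

#' Discover conserved motifs by expectation maximization
#'
#' Greedy sequential elicitation of up to `k_max` motifs of widths in
#' `[w_min, w_max]` (the classic search settings are 15 motifs, widths
#' 6..50). Per motif, a geometric width grid is scanned; per width, EM runs
#' from seeded n-mer starts until the log likelihood changes by less than
#' `tol` (or `max_iter` iterations). Flanking columns whose
#' finite-sample-adjusted relative entropy falls below a quarter of the
#' strongest column's (floor 0.3 bits) are trimmed, the best motif is
#' selected by the adjusted relative entropy summed over columns times the
#' expected site count, its sites are probabilistically erased, and the
#' search repeats.
#'
#' @param proteins named character vector (>= 2 sequences).
#' @param k_max maximum number of motifs.
#' @param w_min,w_max motif width bounds.
#' @param mode `"anr"` (any number of repetitions) or `"zoops"`
#'   (zero-or-one occurrence per sequence).
#' @param seed RNG seed (identical seeds give identical motif sets).
#' @param n_starts EM starts per width.
#' @param max_iter,tol EM convergence controls.
#' @return list of motifs; each has `id`, `width`, `pwm` (width x 20 rows
#'   summing to 1), `consensus`, `sites` (data.frame seq_id, offset, site,
#'   z), `nsites`, `escore`, and the EM log-likelihood `trace`.
#' @export
discover_motifs <- function(proteins, k_max = 15, w_min = 6, w_max = 50,
                            mode = c("anr", "zoops"), seed = 7,
                            n_starts = 3, max_iter = 100, tol = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(length(proteins) >= 2, w_min <= w_max)
  if (k_max == 0) return(list())
  lens <- nchar(proteins)
  if (all(lens < w_min)) stop("all sequences shorter than w_min")
  set.seed(as.integer(seed))
  enc <- lapply(proteins, function(p) {
    v <- aa_encode(p); v[v < 0] <- 0L; v
  })
  cnt <- tabulate(unlist(enc) + 1L, 20)
  bg <- (cnt + 1) / (sum(cnt) + 20)

  widths <- unique(round(w_min * 1.3^(0:50)))
  widths <- c(widths[widths < w_max & widths >= w_min], w_max)
  widths <- widths[widths <= max(lens)]

  erase <- lapply(lens, function(L) rep(1, L))
  motifs <- list()
  for (m in seq_len(k_max)) {
    best <- NULL
    for (w in widths) {
      wins <- window_index(lens, w)
      if (is.null(wins)) next
      uw <- window_erasure(erase, cumsum(c(0L, lens)), wins, w)
      if (all(uw < 0.5)) next
      # two-stage start selection: screen many seeds with a few EM
      # iterations, then run the most promising ones to convergence
      avail <- which(uw >= 0.5)
      cand <- sample(avail, min(8 * n_starts, length(avail)))
      screen <- vapply(cand, function(s)
        em_motif(enc, lens, w, bg, wins[s, ], mode, erase,
                 max_iter = 4, tol = tol)$loglik, numeric(1))
      pick <- cand[order(screen, decreasing = TRUE)][
        seq_len(min(n_starts, length(cand)))]
      for (s in pick) {
        fit <- em_motif(enc, lens, w, bg, wins[s, ], mode, erase,
                        max_iter, tol)
        if (is.null(fit) || fit$nsites < 2) next
        re <- adj_re(fit$pwm, bg, fit$nsites)
        # trim flanks below a threshold relative to the strongest column
        keep <- which(re >= max(0.3, 0.25 * max(re)))
        if (length(keep) == 0) next
        from <- min(keep); to <- max(keep)
        if (to - from + 1 < w_min) {
          # keep the best contiguous w_min window instead
          sums <- vapply(seq_len(fit$w - w_min + 1), function(o)
            sum(re[o:(o + w_min - 1)]), numeric(1))
          from <- which.max(sums); to <- from + w_min - 1
        }
        score <- fit$nsites * sum(pmax(re[from:to], 0))
        if (is.null(best) || score > best$score)
          best <- list(fit = fit, from = from, to = to, score = score)
      }
    }
    if (is.null(best)) break
    fit <- best$fit
    from <- best$from; to <- best$to
    wtrim <- to - from + 1
    pwm <- fit$pwm[from:to, , drop = FALSE]
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- AA_ALPHABET
    site_rows <- which(fit$z > 0.5)
    sites <- data.frame(
      seq_id = names(proteins)[fit$wins[site_rows, 1]],
      offset = fit$wins[site_rows, 2] + from - 1L,
      z = fit$z[site_rows])
    sites$site <- substr(proteins[sites$seq_id], sites$offset,
                         sites$offset + wtrim - 1L)
    consensus <- paste(AA_ALPHABET[apply(pwm, 1, which.max)],
                       collapse = "")
    motifs[[m]] <- list(id = m, width = wtrim, pwm = pwm,
                        consensus = consensus, sites = sites,
                        nsites = fit$nsites,
                        escore = fit$nsites *
                          sum(adj_re(pwm, bg, fit$nsites)),
                        trace = fit$trace)
    class(motifs[[m]]) <- "motif"
    # probabilistic erasure of the reported sites
    for (k in seq_len(nrow(fit$wins))) {
      if (fit$z[k] < 1e-3) next
      i <- fit$wins[k, 1]
      span <- (fit$wins[k, 2] + from - 1L):(fit$wins[k, 2] + to - 1L)
      span <- span[span <= lens[i]]
      erase[[i]][span] <- erase[[i]][span] * (1 - fit$z[k])
    }
  }
  motifs
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif %d> width %d, %.1f sites, consensus %s\n",
              x$id, x$width, x$nsites, x$consensus))
  invisible(x)
}

#' Motif presence matrix
#'
#' A motif is present in a sequence iff its best PWM log-odds window score
#' (bits, against the motif's own background) reaches `score_min`.
#'
#' @param motifs list of motifs from [discover_motifs()].
#' @param proteins named character vector.
#' @param score_min minimum log-odds score (bits).
#' @return logical matrix, genes x motifs.
#' @export
motif_presence <- function(motifs, proteins, score_min = 10) {
  stopifnot(length(motifs) > 0)
  out <- matrix(FALSE, length(proteins), length(motifs),
                dimnames = list(names(proteins),
                                paste0("motif", vapply(motifs, `[[`,
                                                       numeric(1), "id"))))
  cnt <- tabulate(unlist(lapply(proteins, aa_encode)) + 1L, 20)
  bg <- (cnt + 1) / (sum(cnt) + 20)
  for (mi in seq_along(motifs)) {
    mt <- motifs[[mi]]
    lodds <- log2(pmax(mt$pwm, 1e-12)) -
      matrix(rep(log2(bg), each = mt$width), nrow = mt$width)
    for (pi in seq_along(proteins)) {
      enc <- aa_encode(proteins[[pi]]); enc[enc < 0] <- 0L
      L <- length(enc)
      if (L < mt$width) next
      nwin <- L - mt$width + 1
      sc <- numeric(nwin)
      for (j in seq_len(mt$width))
        sc <- sc + lodds[j, enc[j:(j + nwin - 1)] + 1L]
      out[pi, mi] <- max(sc) >= score_min
    }
  }
  out
}
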