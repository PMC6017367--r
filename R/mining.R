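#' Build a log-odds domain profile from a seed alignment
#'
#' The profile is a position-specific scoring matrix over the 20 amino
#' acids, built from the match columns of the seed alignment (columns with
#' gap fraction < 50 percent). Per-column scores are
#' `log2(((count + pseudocount * bg) / (N + pseudocount)) / bg)` where `N`
#' is the number of residues observed in the column and `bg` the background
#' frequency of the residue. Rows whose id starts with `#` are annotation
#' rows; the row named `#active_site` marks the catalytic-Cys column
#' with `*`.
#'
#' @param seed_alignment named character vector of equal-length gapped
#'   sequences (see [ubc_seed_alignment()]); may include annotation rows.
#' @param pseudocount total background pseudocount per column.
#' @return object of class `domain_profile` with fields `scores`
#'   (20 x W matrix, bits), `consensus_length`, `active_site_col`,
#'   `background`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1) {
  ann <- seed_alignment[startsWith(names(seed_alignment), "#")]
  seqs <- seed_alignment[!startsWith(names(seed_alignment), "#")]
  if (length(seqs) < 1) stop("seed alignment has no sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged seed alignment: sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  W0 <- ncol(m)
  is_gap <- m == "-" | m == "."
  gap_frac <- colMeans(is_gap)
  if (any(gap_frac == 1))
    warning("dropping ", sum(gap_frac == 1), " all-gap column(s)")
  match_cols <- which(gap_frac < 0.5)
  if (length(match_cols) == 0) stop("no match columns in seed alignment")

  counts_all <- table(factor(m[!is_gap], levels = AA_ALPHABET))
  bad <- setdiff(unique(as.vector(m[!is_gap])), AA_ALPHABET)
  if (length(bad)) stop("non-amino-acid symbol(s) in seed alignment: ",
                        paste(bad, collapse = ""))
  bg <- (as.numeric(counts_all) + 1) / (sum(counts_all) + 20)
  names(bg) <- AA_ALPHABET

  scores <- matrix(0, nrow = 20, ncol = length(match_cols),
                   dimnames = list(AA_ALPHABET, NULL))
  for (k in seq_along(match_cols)) {
    col <- m[, match_cols[k]]
    col <- col[!(col %in% c("-", "."))]
    cnt <- as.numeric(table(factor(col, levels = AA_ALPHABET)))
    p <- (cnt + pseudocount * bg) / (length(col) + pseudocount)
    scores[, k] <- log2(p / bg)
  }

  active <- NA_integer_
  if ("#active_site" %in% names(ann)) {
    star <- as.integer(regexpr("\\*", ann[["#active_site"]]))
    if (star < 1) stop("annotation row #active_site has no '*' marker")
    active <- match(star, match_cols)
    if (is.na(active))
      stop("active-site column is not a match column")
  }
  structure(list(scores = scores,
                 consensus_length = length(match_cols),
                 active_site_col = active,
                 background = bg),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %d columns, active-site column %s\n",
              x$consensus_length,
              ifelse(is.na(x$active_site_col), "unset",
                     x$active_site_col)))
  invisible(x)
}

#' Consensus sequence of a profile (argmax residue per column)
#' @param profile a `domain_profile`.
#' @return amino-acid string.
#' @export
profile_consensus <- function(profile) {
  paste(AA_ALPHABET[apply(profile$scores, 2, which.max)], collapse = "")
}

# local alignment of one protein against the profile (bit scores)
align_to_profile <- function(profile, protein, gap_open = 10,
                             gap_extend = 0.5, traceback = TRUE) {
  .profile_sw(aa_encode(protein), profile$scores, gap_open, gap_extend,
              traceback)
}

# Gumbel (EVD) calibration of profile scores on shuffled sequences drawn
# from the pooled residues of the input proteome.
calibrate_evd <- function(profile, proteins, n_shuffles = 1000,
                          gap_open = 10, gap_extend = 0.5, seed = 101) {
  pool <- aa_encode(paste(proteins, collapse = ""))
  pool <- pool[pool >= 0]
  len <- max(30L, as.integer(stats::median(nchar(proteins))))
  set.seed(as.integer(seed))
  shuffles <- lapply(seq_len(n_shuffles), function(i)
    pool[sample.int(length(pool), len, replace = TRUE)])
  sc <- .profile_sw_scores(shuffles, profile$scores, gap_open, gap_extend)
  beta <- sd(sc) * sqrt(6) / pi
  mu <- mean(sc) - 0.57721566 * beta
  list(mu = mu, beta = beta, scores = sc)
}

#' Scan a proteome with a domain profile
#'
#' Best affine-gap local alignment of each protein against the profile;
#' statistical significance is calibrated by fitting a Gumbel distribution
#' to the scores of seeded shuffles of the pooled input residues, and the
#' E-value of a hit is `n_proteins * P(score >= s)` under that fit. Only
#' hits with E-value at or below the cutoff are returned. Sequences with
#' non-amino-acid symbols are skipped with a warning.
#'
#' @param profile a [build_profile()] result.
#' @param proteins named character vector of protein sequences.
#' @param e_cutoff E-value cutoff (default 0.01).
#' @param gap_open,gap_extend affine gap penalties in bits.
#' @param n_shuffles shuffled sequences used for calibration.
#' @param seed seed for the calibration shuffles.
#' @return data.frame of hits (gene_id, score, evalue, t_start, t_end,
#'   p_start, p_end, coverage) with the per-hit alignment column/position
#'   pairs in `attr(, "alignments")`.
#' @export
scan_proteome <- function(profile, proteins, e_cutoff = 0.01,
                          gap_open = 10, gap_extend = 0.5,
                          n_shuffles = 1000, seed = 101) {
  stopifnot(length(proteins) > 0, e_cutoff > 0)
  ok <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               toupper(proteins))
  if (any(!ok)) {
    for (id in names(proteins)[!ok])
      warning("skipping ", id, ": non-amino-acid symbols", call. = FALSE)
    proteins <- proteins[ok]
  }
  if (length(proteins) == 0)
    return(empty_hits())
  evd <- calibrate_evd(profile, proteins, n_shuffles, gap_open, gap_extend,
                       seed)
  n <- length(proteins)
  rows <- vector("list", n)
  alns <- list()
  for (i in seq_len(n)) {
    a <- align_to_profile(profile, proteins[[i]], gap_open, gap_extend)
    z <- (a$score - evd$mu) / evd$beta
    pval <- -expm1(-exp(-z))       # 1 - exp(-exp(-z)), stable
    ev <- n * pval
    if (ev <= e_cutoff && a$score > 0) {
      rows[[i]] <- data.frame(
        gene_id = names(proteins)[i], score = a$score, evalue = ev,
        t_start = a$t_start, t_end = a$t_end,
        p_start = a$p_start, p_end = a$p_end,
        coverage = (a$p_end - a$p_start + 1) / profile$consensus_length)
      alns[[names(proteins)[i]]] <- a$pairs
    }
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  attr(hits, "alignments") <- alns
  attr(hits, "evd") <- evd[c("mu", "beta")]
  hits
}

empty_hits <- function() {
  structure(data.frame(gene_id = character(), score = numeric(),
                       evalue = numeric(), t_start = integer(),
                       t_end = integer(), p_start = integer(),
                       p_end = integer(), coverage = numeric()),
            alignments = list())
}

# pairwise local alignment under BLOSUM62; bit score = half the raw score
pairwise_local <- function(a, b, gap_open = 11, gap_extend = 1) {
  .pair_sw(aa_encode(a), aa_encode(b), blosum62(), gap_open, gap_extend)
}

#' Confirm candidate hits by similarity to reference proteins
#'
#' A candidate is retained iff its best local-alignment bit score
#' (BLOSUM62; bits = raw score / 2) against any reference reaches
#' `bit_threshold`.
#'
#' @param hits hit table from [scan_proteome()].
#' @param proteins the scanned proteome (named character).
#' @param references named character vector of reference proteins.
#' @param bit_threshold minimum bit score.
#' @return the retained subset of `hits` (attributes preserved).
#' @export
confirm_by_similarity <- function(hits, proteins, references,
                                  bit_threshold = 50) {
  stopifnot(length(references) > 0)
  if (nrow(hits) == 0) return(hits)
  keep <- vapply(hits$gene_id, function(g) {
    best <- max(vapply(references, function(r)
      pairwise_local(proteins[[g]], r)$score, numeric(1)))
    best / 2 >= bit_threshold
  }, logical(1))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignments") <- attr(hits, "alignments")[out$gene_id]
  out
}

#' Filter candidates for domain completeness and redundancy
#'
#' Candidates whose profile coverage is below `min_coverage` are removed as
#' incomplete. Among the remainder, pairs with identity at or above
#' `redundancy_identity` over at least 95 percent mutual coverage are
#' collapsed, keeping the longer protein (ties: lexicographically smaller
#' id).
#'
#' @param hits hit table from [scan_proteome()].
#' @param proteins the scanned proteome.
#' @param min_coverage minimum profile coverage in (0, 1].
#' @param redundancy_identity identity threshold in (0, 1].
#' @return object of class `candidate_set` with fields `hits`,
#'   `removed_incomplete`, `removed_redundant`, `accepted`.
#' @export
filter_candidates <- function(hits, proteins, min_coverage = 0.6,
                              redundancy_identity = 0.98) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            redundancy_identity > 0, redundancy_identity <= 1)
  if (nrow(hits) == 0)
    return(structure(list(hits = hits, removed_incomplete = character(),
                          removed_redundant = character(),
                          accepted = character()),
                     class = "candidate_set"))
  incomplete <- hits$gene_id[hits$coverage < min_coverage]
  left <- setdiff(hits$gene_id, incomplete)

  # redundancy graph among complete candidates
  redundant <- character()
  if (length(left) > 1) {
    parent <- seq_along(left)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(left)[-length(left)]) {
      for (j in (i + 1):length(left)) {
        pa <- proteins[[left[i]]]; pb <- proteins[[left[j]]]
        al <- pairwise_local(pa, pb)
        if (al$aln_len == 0) next
        ident <- al$identical / al$aln_len
        cov_a <- (al$a_end - al$a_start + 1) / nchar(pa)
        cov_b <- (al$b_end - al$b_start + 1) / nchar(pb)
        if (ident >= redundancy_identity && cov_a >= 0.95 && cov_b >= 0.95) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    comp <- vapply(seq_along(left), find, integer(1))
    for (grp in split(seq_along(left), comp)) {
      if (length(grp) < 2) next
      ids <- left[grp]
      lens <- nchar(proteins[ids])
      keep <- ids[order(-lens, ids)][1]
      redundant <- c(redundant, setdiff(ids, keep))
    }
  }
  accepted <- setdiff(left, redundant)
  structure(list(hits = hits,
                 removed_incomplete = incomplete,
                 removed_redundant = redundant,
                 accepted = accepted),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0("<candidate_set> %d hit(s): %d accepted, ",
                     "%d incomplete, %d redundant removed\n"),
              nrow(x$hits), length(x$accepted),
              length(x$removed_incomplete), length(x$removed_redundant)))
  invisible(x)
}

#' Name accepted family members by chromosomal location
#'
#' Members are sorted by scaffold (natural numeric ordering, so scaffold2
#' precedes scaffold10) and start coordinate, then named `prefix1..prefixN`.
#'
#' @param accepted character vector of accepted gene ids.
#' @param gene_models named list of [gene_model] objects covering them.
#' @param prefix name prefix (e.g. `"DlUBC"`).
#' @return data.frame (name, gene_id, scaffold, start) in naming order.
#' @export
assign_names <- function(accepted, gene_models, prefix = "DlUBC") {
  missing <- setdiff(accepted, names(gene_models))
  if (length(missing))
    stop("no gene model for: ", paste(missing, collapse = ", "))
  gm <- gene_models[accepted]
  sc <- vapply(gm, function(g) g$scaffold, character(1))
  st <- vapply(gm, function(g) g$start, integer(1))
  key <- natural_order(sc)
  # natural_order gives scaffold ordering; refine by start within scaffold
  o <- order(match(sc, unique(sc[key])), st)
  data.frame(name = paste0(prefix, seq_along(accepted)),
             gene_id = accepted[o], scaffold = sc[o], start = st[o],
             row.names = NULL)
}

#' Mine a family from a proteome end to end
#'
#' Convenience pipeline: profile scan, reference confirmation, coverage and
#' redundancy filtering, location-ordered naming.
#'
#' @inheritParams scan_proteome
#' @inheritParams confirm_by_similarity
#' @inheritParams filter_candidates
#' @param gene_models named list of [gene_model]s for naming.
#' @param prefix member name prefix.
#' @return list(candidates = `candidate_set`, members = naming table).
#' @export
mine_family <- function(profile, proteins, gene_models,
                        references = NULL, e_cutoff = 0.01,
                        min_coverage = 0.6, redundancy_identity = 0.98,
                        bit_threshold = 50, prefix = "DlUBC",
                        n_shuffles = 1000, seed = 101) {
  hits <- scan_proteome(profile, proteins, e_cutoff,
                        n_shuffles = n_shuffles, seed = seed)
  if (!is.null(references))
    hits <- confirm_by_similarity(hits, proteins, references, bit_threshold)
  cs <- filter_candidates(hits, proteins, min_coverage, redundancy_identity)
  members <- assign_names(cs$accepted, gene_models, prefix)
  list(candidates = cs, members = members)
}
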