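# ExPASy-style average residue masses (Da); protein mass adds one water.
AA_MASS <- c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155,
             F = 147.1766, G = 57.0519, H = 137.1411, I = 113.1594,
             K = 128.1741, L = 113.1594, M = 131.1926, N = 114.1038,
             P = 97.1167, Q = 128.1307, R = 156.1875, S = 87.0782,
             T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.01524

#' Protein molecular weight
#'
#' Sum of average (not monoisotopic) residue masses plus one water,
#' matching the convention of the usual proteomics web tools.
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @return molecular weight in kDa.
#' @export
molecular_weight <- function(protein) {
  ch <- strsplit(toupper(protein), "")[[1]]
  m <- AA_MASS[ch]
  if (anyNA(m))
    stop("unknown residue '", ch[which(is.na(m))[1]], "' at position ",
         which(is.na(m))[1])
  (sum(m) + WATER_MASS) / 1000
}

# pKa sets for pI computation; Bjellqvist matches the common web tool,
# EMBOSS provided as an alternative (pI is pKa-set dependent).
PKA_SETS <- list(
  bjellqvist = c(nterm = 7.50, cterm = 3.55, C = 9.00, D = 4.05, E = 4.45,
                 H = 5.98, K = 10.00, R = 12.00, Y = 10.00),
  emboss = c(nterm = 8.6, cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1))

protein_charge <- function(counts, pka, pH) {
  pos <- c(nterm = 1, counts[c("H", "K", "R")])
  neg <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
  q_pos <- sum(pos / (1 + 10^(pH - pka[c("nterm", "H", "K", "R")])))
  q_neg <- sum(neg / (1 + 10^(pka[c("cterm", "D", "E", "C", "Y")] - pH)))
  q_pos - q_neg
}

#' Protein isoelectric point
#'
#' Net charge as a function of pH is the Henderson-Hasselbalch sum over the
#' ionizable side chains (D, E, C, Y, H, K, R) and the termini; the pI is
#' found by bisection on pH in 0..14 to `|Q| < 1e-4`.
#'
#' @param protein amino-acid string.
#' @param pka_set `"bjellqvist"` (default), `"emboss"`, or a named numeric
#'   vector with entries nterm, cterm, C, D, E, H, K, R, Y.
#' @param tol convergence tolerance on the net charge.
#' @param max_iter bisection iteration cap (error on non-convergence).
#' @return the isoelectric point (pH units).
#' @export
isoelectric_point <- function(protein, pka_set = "bjellqvist",
                              tol = 1e-4, max_iter = 200) {
  pka <- if (is.character(pka_set)) PKA_SETS[[match.arg(pka_set,
                                                        names(PKA_SETS))]]
         else pka_set
  ch <- strsplit(toupper(protein), "")[[1]]
  if (!all(ch %in% AA_ALPHABET)) stop("invalid residue in protein")
  counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                   function(a) sum(ch == a), numeric(1))
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- protein_charge(counts, pka, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge in ", max_iter, " iterations")
}

#' E2 architecture class from terminal extensions
#'
#' Class I has neither extension flanking the catalytic domain, class II an
#' N-terminal extension only, class III a C-terminal extension only, class
#' IV both. An extension counts when its length reaches `extension_min`.
#'
#' @param size_aa protein length (aa).
#' @param domain_span numeric length-2 vector, 1-based inclusive aa span of
#'   the domain.
#' @param extension_min minimum extension length (aa) to count.
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_architecture <- function(size_aa, domain_span, extension_min = 25) {
  stopifnot(extension_min >= 1, domain_span[1] >= 1,
            domain_span[2] <= size_aa)
  n_ext <- domain_span[1] - 1
  c_ext <- size_aa - domain_span[2]
  if (n_ext < extension_min && c_ext < extension_min) "I"
  else if (n_ext >= extension_min && c_ext < extension_min) "II"
  else if (n_ext < extension_min && c_ext >= extension_min) "III"
  else "IV"
}

#' Detect a ubiquitin-conjugating enzyme variant (UEV)
#'
#' A UEV is a domain-bearing protein whose residue aligned to the profile's
#' active-site (catalytic Cys) column is not cysteine. If the active-site
#' column is deleted in the alignment, the protein is flagged UEV with a
#' warning (no Cys present at the site).
#'
#' @param protein amino-acid string.
#' @param profile a [build_profile()] result with `active_site_col` set.
#' @param alignment two-column matrix of (profile column, target position)
#'   pairs, as stored in `attr(hits, "alignments")` by [scan_proteome()].
#' @return logical: `TRUE` when the active-site Cys is absent.
#' @export
detect_uev <- function(protein, profile, alignment) {
  if (is.na(profile$active_site_col))
    stop("profile has no active-site column")
  row <- which(alignment[, 1] == profile$active_site_col)
  if (length(row) == 0) {
    warning("active-site column deleted in alignment; no Cys at site")
    return(TRUE)
  }
  substr(protein, alignment[row[1], 2], alignment[row[1], 2]) != "C"
}

#' Summarize a gene family table
#'
#' Computes the family-level aggregates: mean/min/max of full length, ORF
#' length, protein size, molecular weight and pI (rounded to the customary
#' printed precision: bp and aa to integers, kDa and pI to 2 decimals), the
#' intron-count histogram, intronless gene names, and per-class counts when
#' an `e2_class` column is present.
#'
#' @param members a [load_table1()] fixture or any data.frame with columns
#'   `name`, `full_length_bp`, `orf_bp`, `size_aa`, `mw_kda`, `pi`,
#'   `introns` (optionally `e2_class`).
#' @return object of class `family_summary`.
#' @export
summarize_family <- function(members) {
  stopifnot(nrow(members) >= 1)
  num <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  stats <- rbind(full_length_bp = round(num(members$full_length_bp)),
                 orf_bp = round(num(members$orf_bp)),
                 size_aa = round(num(members$size_aa)),
                 mw_kda = round(num(members$mw_kda), 2),
                 pi = round(num(members$pi), 2))
  hist <- table(factor(members$introns, levels = 0:max(members$introns)))
  out <- list(n = nrow(members), stats = stats,
              intron_hist = hist,
              intronless = members$name[members$introns == 0],
              n_introns_3_4 = sum(members$introns %in% c(3, 4)),
              extremes = list(
                full_length = members$name[c(which.min(members$full_length_bp),
                                             which.max(members$full_length_bp))],
                orf = members$name[c(which.min(members$orf_bp),
                                     which.max(members$orf_bp))],
                pi = members$name[c(which.min(members$pi),
                                    which.max(members$pi))]))
  if (!is.null(members$e2_class))
    out$class_counts <- table(factor(members$e2_class,
                                     levels = c("I", "II", "III", "IV")))
  structure(out, class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat(sprintf("<family_summary> n = %d\n", x$n))
  print(x$stats)
  cat("introns with 3 or 4:", x$n_introns_3_4, "of", x$n, "\n")
  cat("intronless:", paste(x$intronless, collapse = ", "), "\n")
  if (!is.null(x$class_counts)) {
    cat("classes: ")
    print(x$class_counts)
  }
  invisible(x)
}

#' Characterize mined members into a family table
#'
#' Builds the per-member description table (the shape of the packaged
#' 40-row fixture) from a genome bundle and a hit table: ORF length from
#' the protein (stop codon included in the ORF), MW, pI, domain span,
#' architecture class, UEV flag, intron count and genomic full length.
#'
#' @param members naming table from [assign_names()].
#' @param bundle a [genome_bundle].
#' @param hits hit table from [scan_proteome()] (for domain spans).
#' @param profile the scanning profile (for UEV detection); optional.
#' @param extension_min architecture-class threshold (aa).
#' @return data.frame, one row per member.
#' @export
characterize_family <- function(members, bundle, hits, profile = NULL,
                                extension_min = 25) {
  alns <- attr(hits, "alignments")
  rows <- lapply(seq_len(nrow(members)), function(i) {
    gid <- members$gene_id[i]
    prot <- bundle$proteins[[gid]]
    gm <- bundle$genes[[gid]]
    h <- hits[hits$gene_id == gid, ][1, ]
    span <- c(h$t_start, h$t_end)
    uev <- if (!is.null(profile) && !is.na(profile$active_site_col))
      detect_uev(prot, profile, alns[[gid]]) else NA
    data.frame(name = members$name[i], locus_id = gid,
               location = sprintf("%s:%d:%d", gm$scaffold, gm$start, gm$end),
               orf_bp = 3 * (nchar(prot) + 1), size_aa = nchar(prot),
               domain_start = span[1], domain_end = span[2],
               pi = round(isoelectric_point(prot), 2),
               mw_kda = round(molecular_weight(prot), 2),
               introns = n_introns(gm),
               full_length_bp = gm$end - gm$start + 1,
               e2_class = classify_architecture(nchar(prot), span,
                                                extension_min),
               uev = uev)
  })
  do.call(rbind, rows)
}
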