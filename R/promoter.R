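#' Extract the upstream promoter of a gene
#'
#' Takes the `length` bases upstream of the annotated gene start (the
#' transcription-start proxy), strand-aware: for a plus-strand gene the
#' bases immediately 5' of the start; for a minus-strand gene the reverse
#' complement of the bases immediately 3' of the end. Clipped at scaffold
#' bounds with a truncation flag; a gene with no upstream sequence yields
#' an empty, flagged promoter (not an error).
#'
#' @param bundle a [genome_bundle] (or named scaffold vector).
#' @param gm a [gene_model].
#' @param length promoter length in bp (the study's choice is 1500).
#' @return list(seq, truncated, length, gene_id).
#' @export
extract_promoter <- function(bundle, gm, length = 1500) {
  scaffolds <- if (inherits(bundle, "genome_bundle")) bundle$scaffolds
               else bundle
  s <- scaffolds[[gm$scaffold]]
  if (is.null(s)) stop("unknown scaffold ", gm$scaffold)
  slen <- nchar(s)
  if (gm$strand == "+") {
    from <- max(1L, gm$start - length)
    to <- gm$start - 1L
    seq <- if (to >= from) substr(s, from, to) else ""
  } else {
    from <- gm$end + 1L
    to <- min(slen, gm$end + length)
    seq <- if (to >= from) revcomp(substr(s, from, to)) else ""
  }
  list(seq = seq, truncated = nchar(seq) < length,
       length = nchar(seq), gene_id = gm$gene_id)
}

#' Scan a promoter for cis-element consensus matches
#'
#' Reports every position and strand where an element's IUPAC consensus
#' matches (all overlapping matches; no greedy consumption). Minus-strand
#' matches are reported at the plus-strand offset of the site's leftmost
#' base. `N` in the promoter matches nothing.
#'
#' @param promoter result of [extract_promoter()] or a DNA string.
#' @param table a [read_element_table()] table.
#' @return data.frame (gene_id, element, category, offset (0-based),
#'   strand, match).
#' @export
scan_elements <- function(promoter, table) {
  seq <- if (is.list(promoter)) promoter$seq else promoter
  gid <- if (is.list(promoter)) promoter$gene_id else NA_character_
  empty <- data.frame(gene_id = character(), element = character(),
                      category = character(), offset = integer(),
                      strand = character(), match = character())
  if (nchar(seq) == 0) return(empty)
  if (grepl("[^ACGTN]", toupper(seq)))
    stop("promoter sequence must be over ACGTN")
  subj <- Biostrings::DNAString(toupper(seq))
  out <- list()
  for (r in seq_len(nrow(table))) {
    pat <- Biostrings::DNAString(table$consensus[r])
    for (std in c("+", "-")) {
      p <- if (std == "+") pat else Biostrings::reverseComplement(pat)
      if (length(p) > length(subj)) next
      hits <- Biostrings::matchPattern(p, subj,
                                       fixed = c(pattern = FALSE,
                                                 subject = TRUE))
      if (length(hits) == 0) next
      out[[length(out) + 1]] <- data.frame(
        gene_id = gid, element = table$element[r],
        category = table$category[r],
        offset = BiocGenerics::start(hits) - 1L, strand = std,
        match = as.character(hits))
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  # N in the promoter matches nothing: drop windows overlapping an N
  npos <- which(strsplit(toupper(seq), "")[[1]] == "N")
  if (length(npos)) {
    keep <- vapply(seq_len(nrow(res)), function(r)
      !any(npos > res$offset[r] &
             npos <= res$offset[r] + nchar(res$match[r])), logical(1))
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0) return(empty)
  }
  res[order(res$offset, res$element, res$strand), , drop = FALSE]
}

#' Promoter cis-element categories per gene and family counts
#'
#' A category is present in a gene's promoter iff at least one element of
#' that category matched.
#'
#' @param hits data.frame of hits (rbind of [scan_elements()] results,
#'   with `gene_id` filled).
#' @param table the element table (defines the category universe).
#' @param genes character vector of all gene ids (so genes without hits
#'   are counted as absent).
#' @return list(presence = genes x categories logical matrix,
#'   counts = named integer vector per category).
#' @export
categorize_promoters <- function(hits, table, genes) {
  cats <- sort(unique(table$category))
  pres <- matrix(FALSE, length(genes), length(cats),
                 dimnames = list(genes, cats))
  if (nrow(hits) > 0) {
    for (r in seq_len(nrow(hits))) {
      g <- hits$gene_id[r]
      if (g %in% genes) pres[g, hits$category[r]] <- TRUE
    }
  }
  list(presence = pres, counts = colSums(pres))
}

#' Scan all gene promoters of a genome bundle
#'
#' @param bundle a [genome_bundle].
#' @param table element table.
#' @param length promoter length (bp).
#' @return list(hits, promoters, categories) where `categories` is the
#'   [categorize_promoters()] result.
#' @export
scan_promoters <- function(bundle, table = read_element_table(),
                           length = 1500) {
  proms <- lapply(bundle$genes, function(gm)
    extract_promoter(bundle, gm, length))
  hits <- do.call(rbind, lapply(proms, scan_elements, table = table))
  if (is.null(hits))
    hits <- scan_elements(list(seq = "", gene_id = NA), table)
  rownames(hits) <- NULL
  list(hits = hits, promoters = proms,
       categories = categorize_promoters(hits, table,
                                         names(bundle$genes)))
}
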