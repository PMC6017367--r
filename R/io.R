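#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a plain named
#' character vector. Identifiers are the first whitespace-delimited token of
#' each header and must be unique; sequences are uppercased. Gap characters
#' (`-` and `.`) are stripped unless `alignment = TRUE`, so plain sequence
#' files and aligned FASTA share one reader.
#'
#' @param path path to a FASTA file.
#' @param alignment logical; keep gap columns (for aligned FASTA).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alignment = FALSE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0))
    stop("empty FASTA record: ", ids[nchar(seqs) == 0][1])
  if (!alignment) seqs <- gsub("[-.]", "", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Gene model constructor
#'
#' Coordinates are 1-based inclusive in genome orientation (GFF3 convention);
#' minus-strand exon lists are stored in genome order with the strand
#' recorded. Conversion to 0-based slicing happens only inside the sequence
#' slicing helpers.
#'
#' @param gene_id,scaffold identifiers.
#' @param start,end 1-based inclusive gene span on the scaffold.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), sorted, non-overlapping.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, start, end, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("unknown strand symbol: ", strand)
  if (nrow(exons) < 1) stop("gene ", gene_id, " has no exons")
  if (any(exons[, 2] < exons[, 1]))
    stop("exon end < start in gene ", gene_id)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  if (min(exons[, 1]) < start || max(exons[, 2]) > end)
    stop("exon outside gene span in gene ", gene_id)
  structure(list(gene_id = gene_id, scaffold = scaffold,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s), %d intron(s)\n",
              x$gene_id, x$scaffold, x$start, x$end, x$strand,
              nrow(x$exons), nrow(x$exons) - 1L))
  invisible(x)
}

#' Number of introns of a gene model
#' @param gm a `gene_model`.
#' @return integer intron count (exons - 1).
#' @export
n_introns <- function(gm) nrow(gm$exons) - 1L

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon (or CDS when no exons are present) features via
#' [rtracklayer::import()] and groups exons under their gene. Exons outside
#' the parent span and unknown strand symbols are rejected.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model] objects.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0) stop("no gene features in ", path)
  mrna <- gr[typ == "mRNA"]
  sub <- gr[typ %in% c("exon", "CDS")]
  # map every sub-feature to its gene id (directly or through an mRNA)
  m2g <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  out <- list()
  for (k in seq_along(genes)) {
    g <- genes[k]
    gid <- g$ID
    tr_ids <- names(m2g)[m2g == gid]
    par <- as.character(unlist(sub$Parent))
    take <- sub[par %in% c(gid, tr_ids)]
    st <- as.character(BiocGenerics::strand(g))
    if (!st %in% c("+", "-")) stop("unknown strand symbol for gene ", gid)
    tt <- as.character(take$type)
    use <- if (any(tt == "exon")) take[tt == "exon"] else take
    if (length(use) == 0) stop("gene ", gid, " has no exon/CDS features")
    ex <- cbind(BiocGenerics::start(use), BiocGenerics::end(use))
    out[[gid]] <- gene_model(gid, as.character(GenomeInfoDb::seqnames(g)),
                             BiocGenerics::start(g), BiocGenerics::end(g),
                             st, ex)
  }
  out
}

#' Write gene models to GFF3
#'
#' Deterministic three-level (gene/mRNA/exon) writer; byte-stable output is
#' part of the seeded-generator contract.
#'
#' @param genes list of [gene_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in genes) {
    base <- sprintf("%s\tfamchar\t%%s\t%%d\t%%d\t.\t%s\t.\t%%s",
                    gm$scaffold, gm$strand)
    writeLines(sprintf(base, "gene", gm$start, gm$end,
                       paste0("ID=", gm$gene_id)), con)
    tid <- paste0(gm$gene_id, ".t1")
    writeLines(sprintf(base, "mRNA", gm$start, gm$end,
                       paste0("ID=", tid, ";Parent=", gm$gene_id)), con)
    for (i in seq_len(nrow(gm$exons)))
      writeLines(sprintf(base, "exon", gm$exons[i, 1], gm$exons[i, 2],
                         paste0("ID=", tid, ".exon", i, ";Parent=", tid)),
                 con)
  }
  invisible(path)
}

#' Genome bundle constructor
#'
#' Container tying scaffolds, gene models and the proteome together; checks
#' that gene coordinates fit their scaffold and that every gene has exactly
#' one protein.
#'
#' @param scaffolds named character vector of DNA strings.
#' @param genes named list of [gene_model] objects.
#' @param proteins named character vector of amino-acid strings; may be
#'   empty for DNA-only bundles (e.g. promoter scanning), otherwise every
#'   gene must have exactly one protein.
#' @return an object of class `genome_bundle`.
#' @export
genome_bundle <- function(scaffolds, genes, proteins = character(0)) {
  for (gm in genes) {
    if (!gm$scaffold %in% names(scaffolds))
      stop("gene ", gm$gene_id, " on unknown scaffold ", gm$scaffold)
    if (gm$start < 1 || gm$end > nchar(scaffolds[[gm$scaffold]]))
      stop("gene ", gm$gene_id, " outside scaffold bounds")
    if (length(proteins) && !gm$gene_id %in% names(proteins))
      stop("gene ", gm$gene_id, " has no protein")
  }
  structure(list(scaffolds = scaffolds, genes = genes, proteins = proteins),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d scaffold(s) (%d bp), %d gene(s)\n",
              length(x$scaffolds), sum(nchar(x$scaffolds)),
              length(x$genes)))
  invisible(x)
}

#' Read / write a genes-by-samples count matrix (plain TSV)
#'
#' @param path TSV path; first column gene ids, header row sample ids.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts
#' @param m matrix to write.
#' @export
write_counts <- function(m, path) {
  d <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects columns `gene`, `sample`, `replicate`, `ct_target`,
#' `ct_reference` (reference = internal-control gene, Actin-style).
#'
#' @param path TSV path.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  d <- read.delim(path)
  need <- c("gene", "sample", "ct_target", "ct_reference")
  if (!all(need %in% names(d)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a cis-element consensus table
#'
#' TSV with columns `element`, `consensus` (IUPAC DNA codes), `category`.
#' The table is validated at load: non-IUPAC characters or duplicate element
#' names are rejected.
#'
#' @param path TSV path; default is the bundled element table.
#' @return data.frame of class `cis_element_table`.
#' @export
read_element_table <- function(path = system.file("extdata",
                                                  "cis_elements.tsv",
                                                  package = "famchar")) {
  d <- read.delim(path)
  need <- c("element", "consensus", "category")
  if (!all(need %in% names(d)))
    stop("element table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$element))
    stop("duplicate element name in table")
  d$consensus <- toupper(d$consensus)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", d$consensus)
  if (any(bad))
    stop("invalid IUPAC code in consensus for: ",
         paste(d$element[bad], collapse = ", "))
  class(d) <- c("cis_element_table", "data.frame")
  d
}

#' Load the packaged family description table
#'
#' Returns the bundled 40-member UBC family table (name, locus, location,
#' ORF length, protein size, domain span, pI, MW, intron count, full
#' length), validated against its internal invariants: exactly 40 rows,
#' ORF bp = 3 x (protein aa + 1) (stop codon included in the ORF, excluded
#' from the protein), and domain span within the protein.
#'
#' @return data.frame of class `table1_fixture` with 40 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "dlubc_table1.tsv", package = "famchar")
  d <- read.delim(path)
  if (nrow(d) != 40) stop("family table must have exactly 40 rows")
  if (!all(d$orf_bp == 3 * (d$size_aa + 1)))
    stop("ORF/protein-length invariant violated")
  if (!all(d$domain_end <= d$size_aa))
    stop("domain span exceeds protein length")
  class(d) <- c("table1_fixture", "data.frame")
  d
}
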