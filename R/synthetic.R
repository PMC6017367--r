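#' Built-in UBC-domain consensus (synthetic)
#'
#' A 148-residue UBC-domain-like consensus used by the synthetic generators
#' and the packaged seed alignment. It is a constructed (synthetic) sequence
#' emulating the canonical E2 fold: an HPN triad region, the catalytic
#' cysteine inside the conserved `HPNIYSNGSICLDIL` block, and typical
#' flanking stretches. It is not any real protein.
#'
#' @return a single amino-acid string.
#' @export
ubc_consensus <- function() {
  paste0("MASKRILKELKDLQKDPPTSCSAGPVAEDMFHWQATIMGPPDSPYAGGVFLVSIHFPPDY",
         "PFKPPKVAFRTKVFHPNIYSNGSICLDILKEQWSPALTISKVLLSICSLLTDANPDDPLV",
         "PEIAHIYKSDRSRYETTARSWTQKYAMG")
}

#' Position of the catalytic cysteine within [ubc_consensus()]
#' @return integer position (1-based).
#' @export
ubc_active_site <- function() {
  as.integer(regexpr("HPNIYSNGSIC", ubc_consensus())) + 10L
}

random_aa <- function(n) {
  if (n == 0) return("")
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-substitute a fraction of residues, never touching `protect` positions
mutate_protein <- function(seq, rate, protect = integer()) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1)
  paste(ch, collapse = "")
}

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

reverse_translate <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Configuration for the synthetic genome / count generators
#'
#' Defaults reproduce the study conditions of the worked family: 72
#' domain-bearing candidates (40 complete, 24 with a truncated domain, 8
#' near-identical duplicates of kept genes), 3 catalytically dead (UEV)
#' members among the 40, plus domain-free decoy genes; one designated gene
#' retains only 6 bp of upstream scaffold so the truncated-promoter path is
#' always exercised.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical output.
#' @param n_scaffolds number of scaffolds.
#' @param n_true complete-domain genes implanted.
#' @param n_decoys genes with no domain implant.
#' @param n_incomplete genes carrying a 5'- or 3'-truncated domain copy
#'   (< 60 percent of the consensus length).
#' @param n_redundant near-identical duplicates (>= 98 percent identity over
#'   the full length) of true genes placed at distinct loci.
#' @param n_uev true genes whose active-site Cys is substituted.
#' @param domain_consensus amino-acid string implanted as the domain.
#' @param mutation_rate per-residue substitution rate applied to implants.
#' @param cis_implants data.frame with columns `element`, `gene`, `offset`
#'   (0-based from the promoter 5' end), `strand`; elements are looked up
#'   in `element_table`.
#' @param element_table cis-element consensus table (see
#'   [read_element_table()]).
#' @param counts_design list(n_genes, n_reps, dispersion, lfc) forwarded to
#'   [generate_counts()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_scaffolds = 4, n_true = 40,
                             n_decoys = 20, n_incomplete = 24,
                             n_redundant = 8, n_uev = 3,
                             domain_consensus = ubc_consensus(),
                             mutation_rate = 0.08,
                             cis_implants = NULL,
                             element_table = read_element_table(),
                             counts_design = list(n_genes = 2000, n_reps = 3,
                                                  dispersion = 0.05,
                                                  lfc = NULL)) {
  stopifnot(n_scaffolds >= 1, n_true >= 1, n_decoys >= 0,
            n_incomplete >= 0, n_redundant >= 0,
            n_uev >= 0, n_uev <= n_true,
            mutation_rate >= 0, mutation_rate < 1)
  seed <- as.integer(seed)
  if (!is.null(cis_implants)) {
    stopifnot(all(c("element", "gene", "offset", "strand") %in%
                    names(cis_implants)))
    unknown <- setdiff(cis_implants$element, element_table$element)
    if (length(unknown))
      stop("cis implant uses unknown element(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(seed = seed, n_scaffolds = n_scaffolds, n_true = n_true,
                 n_decoys = n_decoys, n_incomplete = n_incomplete,
                 n_redundant = n_redundant, n_uev = n_uev,
                 domain_consensus = toupper(domain_consensus),
                 mutation_rate = mutation_rate,
                 cis_implants = cis_implants,
                 element_table = element_table,
                 counts_design = counts_design),
            class = "synthetic_config")
}

# concrete instantiation of an IUPAC consensus (one base per code)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(cc) {
    s <- IUPAC_SETS[[cc]]
    s[sample.int(length(s), 1)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Builds proteins first (implanting the domain consensus per the role of
#' each gene), reverse-translates them to a CDS, splits the CDS into exons
#' with intron counts drawn from the family's observed 0-8 histogram, and
#' assembles multi-scaffold DNA with intergenic spacers. Gene `true01` is
#' always placed with exactly 6 bp of upstream scaffold (the
#' truncated-promoter case); all other promoter windows fit inside their
#' spacers. Requested cis-elements are written into promoter windows at the
#' stated offsets and strands. A manifest records the ground truth for every
#' gene.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `bundle` ([genome_bundle]), `manifest`
#'   (data.frame), `config`; class `synthetic_genome`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cons <- config$domain_consensus
  Lc <- nchar(cons)
  asite <- ubc_active_site()
  if (substr(cons, asite, asite) != "C")
    asite <- as.integer(regexpr("C", cons)) # fallback for custom consensi

  ids <- c(sprintf("true%02d", seq_len(config$n_true)),
           if (config$n_incomplete)
             sprintf("inc%02d", seq_len(config$n_incomplete)),
           if (config$n_redundant)
             sprintf("red%02d", seq_len(config$n_redundant)),
           if (config$n_decoys)
             sprintf("dec%02d", seq_len(config$n_decoys)))
  roles <- sub("[0-9]+$", "", ids)
  roles <- c(true = "true", inc = "incomplete", red = "redundant",
             dec = "decoy")[roles]
  n <- length(ids)

  uev <- logical(n)
  if (config$n_uev > 0) uev[seq_len(config$n_uev)] <- TRUE

  proteins <- character(n)
  dom_start <- dom_end <- rep(NA_integer_, n)
  src <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    role <- roles[i]
    if (role == "true") {
      core <- mutate_protein(cons, config$mutation_rate, protect = asite)
      if (uev[i]) substr(core, asite, asite) <- "S"
      ne <- sample(0:80, 1); ce <- sample(0:80, 1)
      proteins[i] <- paste0(random_aa(ne), core, random_aa(ce))
      dom_start[i] <- ne + 1L; dom_end[i] <- ne + Lc
    } else if (role == "incomplete") {
      frac <- runif(1, 0.25, 0.55)
      keep <- max(10L, floor(frac * Lc))
      core <- if (runif(1) < 0.5) substr(cons, 1, keep)
              else substr(cons, Lc - keep + 1, Lc)
      core <- mutate_protein(core, config$mutation_rate)
      ne <- sample(0:60, 1); ce <- sample(0:60, 1)
      proteins[i] <- paste0(random_aa(ne), core, random_aa(ce))
      dom_start[i] <- ne + 1L; dom_end[i] <- ne + keep
    } else if (role == "redundant") {
      # strictly shorter near-identical copy, so "keep the longer" is
      # unambiguous (>= 98 percent identity over >= 95 percent coverage)
      j <- sample(which(roles == "true"), 1)
      drop <- sample(2:5, 1)
      p <- mutate_protein(proteins[j], 0.005)
      proteins[i] <- substr(p, 1, nchar(p) - drop)
      dom_start[i] <- dom_start[j]
      dom_end[i] <- min(dom_end[j], nchar(proteins[i]))
      src[i] <- ids[j]
    } else {
      proteins[i] <- random_aa(sample(80:400, 1))
    }
  }

  # gene structure: intron counts drawn from the family's 0-8 histogram
  intron_weights <- c(3, 1, 3, 11, 11, 3, 4, 2, 1)
  cds <- vapply(proteins, reverse_translate, character(1), USE.NAMES = FALSE)
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    L3 <- nchar(cds[i])
    k <- sample(0:8, 1, prob = intron_weights)
    k <- min(k, L3 - 1L)
    brk <- sort(sample(seq_len(L3 - 1), k))
    seg_start <- c(1L, brk + 1L)
    seg_end <- c(brk, L3)
    ilen <- if (k) sample(80:400, k, replace = TRUE) else integer()
    structures[[i]] <- list(seg_start = seg_start, seg_end = seg_end,
                            ilen = ilen)
  }

  # placement: true01 first on scaffold 1 with 6 bp upstream
  scafs <- sprintf("scaffold%d", seq_len(config$n_scaffolds))
  others <- setdiff(seq_len(n), 1L)
  assign_scaf <- c(1L, sort(sample(seq_len(config$n_scaffolds),
                                   length(others), replace = TRUE)))
  ord <- c(1L, sample(others))
  strands <- c("+", sample(c("+", "-"), n - 1, replace = TRUE))
  names(strands) <- ids[ord]

  scaff_seq <- setNames(rep("", config$n_scaffolds), scafs)
  genes <- list()
  upstream_bp <- setNames(integer(n), ids)
  pos <- setNames(rep(0L, config$n_scaffolds), scafs)
  first_on_scaf <- rep(TRUE, config$n_scaffolds)
  for (k in seq_len(n)) {
    i <- ord[k]; sc <- scafs[assign_scaf[k]]
    gid <- ids[i]
    spacer <- if (gid == "true01") 6L else sample(1600:3000, 1)
    st <- strands[[gid]]
    stru <- structures[[i]]
    # build gene body in coding orientation
    parts <- character(0)
    rel_ex <- matrix(0L, nrow = length(stru$seg_start), ncol = 2)
    at <- 0L
    for (e in seq_along(stru$seg_start)) {
      exon <- substr(cds[i], stru$seg_start[e], stru$seg_end[e])
      rel_ex[e, ] <- c(at + 1L, at + nchar(exon))
      parts <- c(parts, exon)
      at <- at + nchar(exon)
      if (e < length(stru$seg_start)) {
        intr <- paste0("GT", random_dna(stru$ilen[e] - 4L), "AG")
        parts <- c(parts, intr)
        at <- at + nchar(intr)
      }
    }
    body <- paste(parts, collapse = "")
    blen <- nchar(body)
    gstart <- pos[[sc]] + spacer + 1L
    gend <- gstart + blen - 1L
    if (st == "-") {
      body <- revcomp(body)
      ex <- cbind(gstart + blen - rel_ex[, 2], gstart + blen - rel_ex[, 1])
      ex <- ex[order(ex[, 1]), , drop = FALSE]
    } else {
      ex <- cbind(gstart + rel_ex[, 1] - 1L, gstart + rel_ex[, 2] - 1L)
    }
    scaff_seq[[sc]] <- paste0(scaff_seq[[sc]], random_dna(spacer), body)
    pos[[sc]] <- pos[[sc]] + spacer + blen
    genes[[gid]] <- gene_model(gid, sc, gstart, gend, st, ex)
    first_on_scaf[assign_scaf[k]] <- FALSE
  }
  # terminal pad so downstream promoter windows of minus-strand genes fit
  for (sc in scafs) scaff_seq[[sc]] <- paste0(scaff_seq[[sc]],
                                              random_dna(1600))
  for (gid in ids) {
    gm <- genes[[gid]]
    upstream_bp[[gid]] <- if (gm$strand == "+") gm$start - 1L
                          else nchar(scaff_seq[[gm$scaffold]]) - gm$end
  }

  # cis-element implants, written through promoter coordinates
  if (!is.null(config$cis_implants)) {
    tab <- config$element_table
    for (r in seq_len(nrow(config$cis_implants))) {
      imp <- config$cis_implants[r, ]
      gm <- genes[[imp$gene]]
      if (is.null(gm)) stop("cis implant for unknown gene ", imp$gene)
      cons_el <- tab$consensus[tab$element == imp$element]
      w <- nchar(cons_el)
      inst <- instantiate_iupac(cons_el)
      plen <- min(1500L, upstream_bp[[imp$gene]])
      if (imp$offset < 0 || imp$offset + w > plen)
        stop("cis implant outside promoter/scaffold bounds for gene ",
             imp$gene)
      s <- scaff_seq[[gm$scaffold]]
      if (gm$strand == "+") {
        p5 <- gm$start - plen            # genome pos of promoter 5' end
        g1 <- p5 + imp$offset
        frag <- if (imp$strand == "+") inst else revcomp(inst)
        substr(s, g1, g1 + w - 1L) <- frag
      } else {
        g2 <- gm$end + plen - imp$offset # genome pos of promoter base 'offset'
        g1 <- g2 - w + 1L
        frag <- if (imp$strand == "+") revcomp(inst) else inst
        substr(s, g1, g2) <- frag
      }
      scaff_seq[[gm$scaffold]] <- s
    }
  }

  names(proteins) <- ids
  bundle <- genome_bundle(scaff_seq, genes, proteins)
  manifest <- data.frame(
    gene_id = ids, role = roles, candidate = roles != "decoy",
    uev = uev, dom_start = dom_start, dom_end = dom_end,
    size_aa = nchar(proteins),
    scaffold = vapply(ids, function(g) genes[[g]]$scaffold, character(1)),
    start = vapply(ids, function(g) genes[[g]]$start, integer(1)),
    end = vapply(ids, function(g) genes[[g]]$end, integer(1)),
    strand = vapply(ids, function(g) genes[[g]]$strand, character(1)),
    introns = vapply(ids, function(g) n_introns(genes[[g]]), integer(1)),
    upstream_bp = upstream_bp[ids],
    source = src, row.names = NULL)
  structure(list(bundle = bundle, manifest = manifest, config = config),
            class = "synthetic_genome")
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.fa`, `proteins.fa`, `genes.gff3` and `manifest.tsv`.
#' Output is byte-identical for identical configs (seed contract).
#'
#' @param x a `synthetic_genome` from [generate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$bundle$scaffolds, file.path(dir, "genome.fa"))
  write_fasta(x$bundle$proteins, file.path(dir, "proteins.fa"))
  write_gff3(x$bundle$genes, file.path(dir, "genes.gff3"))
  write.table(x$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate negative-binomial count matrices for a two-condition design
#'
#' Counts are drawn NB with mean `mu * 2^(lfc * condition)` and the stated
#' dispersion (`var = mu + dispersion * mu^2`), `n_reps` replicates per
#' condition.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per condition (>= 2).
#' @param dispersion NB dispersion (> 0).
#' @param lfc per-gene log2 fold change of condition B over A; scalar,
#'   vector, or named vector over a subset (others 0).
#' @param mu baseline means; default log-uniform in 8..512.
#' @param seed RNG seed.
#' @return list(counts, condition, design); counts is genes x samples.
#' @export
generate_counts <- function(n_genes = 2000, n_reps = 3, dispersion = 0.05,
                            lfc = NULL, mu = NULL, seed = 1) {
  stopifnot(dispersion > 0, n_reps >= 2)
  set.seed(as.integer(seed))
  gids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(mu)) mu <- 2^runif(n_genes, 3, 9)
  mu <- rep_len(mu, n_genes)
  l <- rep(0, n_genes); names(l) <- gids
  if (!is.null(lfc)) {
    if (!is.null(names(lfc))) l[names(lfc)] <- lfc else l <- rep_len(lfc, n_genes)
  }
  size <- 1 / dispersion
  a <- matrix(rnbinom(n_genes * n_reps, size = size, mu = mu),
              nrow = n_genes)
  b <- matrix(rnbinom(n_genes * n_reps, size = size, mu = mu * 2^l),
              nrow = n_genes)
  counts <- cbind(a, b)
  rownames(counts) <- gids
  colnames(counts) <- c(sprintf("A_%d", seq_len(n_reps)),
                        sprintf("B_%d", seq_len(n_reps)))
  list(counts = counts,
       condition = factor(rep(c("A", "B"), each = n_reps)),
       design = data.frame(gene = gids, mu = mu, lfc = unname(l)))
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference (internal-control) Ct values are drawn around 20 cycles; the
#' target Ct offsets encode per-gene, per-treatment log2 effects so that
#' `2^-(dCt_treated - dCt_control)` recovers the implanted fold change.
#'
#' @param genes character vector of gene ids.
#' @param treatments treatment names; first is the control.
#' @param log2fc matrix genes x treatments of log2 fold changes vs control.
#' @param n_reps replicates.
#' @param noise_sd Ct technical noise (cycles).
#' @param seed RNG seed.
#' @return data.frame with columns gene, sample, replicate, ct_target,
#'   ct_reference.
#' @export
generate_qpcr <- function(genes, treatments = c("control", "treated"),
                          log2fc = NULL, n_reps = 3, noise_sd = 0.05,
                          seed = 1) {
  set.seed(as.integer(seed))
  if (is.null(log2fc))
    log2fc <- matrix(0, length(genes), length(treatments),
                     dimnames = list(genes, treatments))
  base_dct <- runif(length(genes), 2, 8)
  names(base_dct) <- genes
  rows <- expand.grid(replicate = seq_len(n_reps), sample = treatments,
                      gene = genes, stringsAsFactors = FALSE)[, 3:1]
  rows$ct_reference <- rnorm(nrow(rows), 20, 0.1)
  rows$ct_target <- rows$ct_reference + base_dct[rows$gene] -
    log2fc[cbind(rows$gene, rows$sample)] + rnorm(nrow(rows), 0, noise_sd)
  rows
}

#' Synthetic seed alignment for the UBC domain profile
#'
#' Mutated copies of [ubc_consensus()] presented as an aligned FASTA-style
#' set (equal lengths). A short insertion present in a minority of the
#' sequences creates a mostly-gap column block that exercises the
#' match-column rule, and an annotation row `#active_site` marks the
#' catalytic-Cys column with `*`.
#'
#' @param n number of sequences.
#' @param mut per-residue substitution rate.
#' @param seed RNG seed.
#' @return named character vector (aligned; includes the annotation row).
#' @export
ubc_seed_alignment <- function(n = 12, mut = 0.08, seed = 42) {
  set.seed(as.integer(seed))
  cons <- ubc_consensus()
  asite <- ubc_active_site()
  seqs <- vapply(seq_len(n),
                 function(i) mutate_protein(cons, mut, protect = asite),
                 character(1))
  # insertion block after column 40 carried by a minority of sequences
  ins_at <- 40L
  carriers <- sample(n, max(1L, floor(n / 4)))
  out <- vapply(seq_len(n), function(i) {
    ins <- if (i %in% carriers) random_aa(4) else "----"
    paste0(substr(seqs[i], 1, ins_at), ins,
           substr(seqs[i], ins_at + 1, nchar(cons)))
  }, character(1))
  names(out) <- sprintf("seed%02d", seq_len(n))
  ann <- strrep(".", nchar(out[1]))
  substr(ann, asite + 4L, asite + 4L) <- "*"  # +4: insertion block width
  c(out, "#active_site" = ann)
}

#' Synthetic reference set and family members for grouping tests
#'
#' One reference prototype per group (default: the 16 E2/UEV group labels of
#' the field), each a heavily mutated copy of the consensus so groups are
#' well separated; members are light mutations of their group prototype.
#' All sequences share the consensus length, so the set is its own
#' alignment.
#'
#' @param groups group labels.
#' @param n_members members per group.
#' @param mut_group,mut_member substitution rates for prototypes / members.
#' @param seed RNG seed.
#' @return list(msa, reference_labels, truth): `msa` named aligned
#'   sequences; `reference_labels` named vector leaf -> group for the
#'   references; `truth` the ground-truth group of each member.
#' @export
generate_reference_set <- function(groups = c("UBC1", "UBC2", "UBC3/7",
                                              "UBC4/5", "UBC6", "UBC8",
                                              "UBC9", "UBC10", "UBC11",
                                              "UBC12", "UBC13", "UBC14",
                                              "UBC15", "UEV1", "UEV2",
                                              "UEV3"),
                                   n_members = 2, mut_group = 0.3,
                                   mut_member = 0.02, seed = 1) {
  set.seed(as.integer(seed))
  cons <- ubc_consensus()
  msa <- character(0)
  labels <- character(0)
  truth <- character(0)
  for (gi in seq_along(groups)) {
    proto <- mutate_protein(cons, mut_group)
    rid <- sprintf("ref%02d", gi)
    msa[rid] <- proto
    labels[rid] <- groups[gi]
    for (m in seq_len(n_members)) {
      mid <- sprintf("mem%02d_%d", gi, m)
      msa[mid] <- mutate_protein(proto, mut_member)
      truth[mid] <- groups[gi]
    }
  }
  list(msa = msa, reference_labels = labels, truth = truth)
}
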