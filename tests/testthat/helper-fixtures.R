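# shared in-code fixtures for the test suite

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# proteins with an implanted block at a random position
implanted_proteins <- function(n, implant, len = 100, carriers = n,
                               prefix = "p") {
  w <- nchar(implant)
  out <- vapply(seq_len(n), function(i) {
    bg <- random_protein(len)
    if (i > carriers) return(bg)
    at <- sample(seq_len(len - w), 1)
    paste0(substr(bg, 1, at - 1), implant, substr(bg, at + w, len))
  }, character(1))
  setNames(out, paste0(prefix, seq_len(n)))
}

# minimal two-gene genome on one scaffold for promoter tests
tiny_bundle <- function(upstream = 2000, gene_len = 90) {
  set.seed(99)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  s <- mk(upstream + gene_len + 3000 + gene_len + 2000)
  g1s <- upstream + 1
  g1 <- gene_model("gplus", "scf1", g1s, g1s + gene_len - 1, "+",
                   cbind(g1s, g1s + gene_len - 1))
  g2s <- upstream + gene_len + 3000 + 1
  g2 <- gene_model("gminus", "scf1", g2s, g2s + gene_len - 1, "-",
                   cbind(g2s, g2s + gene_len - 1))
  genome_bundle(c(scf1 = s), list(gplus = g1, gminus = g2),
                c(gplus = random_protein(gene_len / 3 - 1),
                  gminus = random_protein(gene_len / 3 - 1)))
}

# default profile built once (used across mining/property tests)
shared_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_profile(ubc_seed_alignment())
    cache
  }
})
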