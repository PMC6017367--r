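test_that("build_profile handles degenerate and duplicated seeds", {
  s <- "ACDEFGHIKL"
  p1 <- build_profile(c(a = s), pseudocount = 1)
  expect_equal(p1$consensus_length, nchar(s))
  p2 <- build_profile(c(a = s, b = s), pseudocount = 1)
  expect_equal(profile_consensus(p2), s)
  expect_error(build_profile(c(a = "ACDE", b = "ACD")), "ragged")
  expect_warning(build_profile(c(a = "AC-E", b = "AC-E")), "all-gap")
})

test_that("profile drops mostly-gap columns and finds the active site", {
  prof <- shared_profile()
  # the seed alignment carries a 4-column minority insertion: dropped
  expect_equal(prof$consensus_length, nchar(ubc_consensus()))
  expect_equal(prof$active_site_col, ubc_active_site())
  expect_equal(substr(profile_consensus(prof), prof$active_site_col,
                      prof$active_site_col), "C")
})

test_that("seed consensus outscores 1000 shuffles of itself", {
  prof <- shared_profile()
  cons <- profile_consensus(prof)
  cons_score <- famchar:::align_to_profile(prof, cons)$score
  set.seed(1)
  ch <- strsplit(cons, "")[[1]]
  shuf <- vapply(1:1000, function(i) paste(sample(ch), collapse = ""),
                 character(1))
  scores <- vapply(shuf, function(s)
    famchar:::align_to_profile(prof, s, traceback = FALSE)$score,
    numeric(1))
  expect_gt(cons_score, max(scores))
})

test_that("gapless local alignment matches the exhaustive oracle", {
  prof <- shared_profile()
  sub <- prof
  sub$scores <- prof$scores[, 1:20]  # 20-column profile
  set.seed(7)
  for (rep in 1:10) {
    protein <- random_protein(60)
    enc <- famchar:::aa_encode(protein) + 1L
    # brute force: best sum over all diagonal (start, end) windows
    best <- 0
    for (ts in 1:60) for (ps in 1:20) {
      run <- 0
      for (k in 0:(min(60 - ts, 20 - ps))) {
        run <- run + unname(sub$scores[enc[ts + k], ps + k])
        if (run > best) best <- run
      }
    }
    got <- famchar:::align_to_profile(sub, protein, gap_open = 1e9,
                                      gap_extend = 1e9,
                                      traceback = FALSE)$score
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("scan recovers implanted domains at their true span", {
  g <- generate_genome(synthetic_config(seed = 13, n_true = 6,
                                        n_decoys = 10, n_incomplete = 2,
                                        n_redundant = 1))
  prof <- shared_profile()
  hits <- scan_proteome(prof, g$bundle$proteins, n_shuffles = 500)
  man <- g$manifest
  for (gid in man$gene_id[man$role == "true"]) {
    h <- hits[hits$gene_id == gid, ]
    expect_equal(nrow(h), 1)
    truth <- man[man$gene_id == gid, ]
    expect_lte(abs(h$t_start - truth$dom_start), 3)
    expect_lte(abs(h$t_end - truth$dom_end), 3)
  }
  expect_false(any(man$role[match(hits$gene_id, man$gene_id)] == "decoy"))
})

test_that("E-value calibration controls decoy hits", {
  prof <- shared_profile()
  set.seed(31)
  decoys <- setNames(vapply(1:200, function(i) random_protein(250), ""),
                     paste0("d", 1:200))
  hits <- scan_proteome(prof, decoys, e_cutoff = 0.01, n_shuffles = 1000,
                        seed = 31)
  expect_lte(nrow(hits), 2)
})

test_that("scan skips sequences with invalid residues, empty in empty out", {
  prof <- shared_profile()
  seqs <- c(ok = ubc_consensus(), bad = "ACDEFXB")
  expect_warning(hits <- scan_proteome(prof, seqs, n_shuffles = 200),
                 "non-amino-acid")
  expect_equal(hits$gene_id, "ok")
  expect_warning(h0 <- scan_proteome(prof, c(bad = "XXXX"),
                                     n_shuffles = 200))
  expect_equal(nrow(h0), 0)
})

test_that("lowering the E-value cutoff never adds hits", {
  g <- generate_genome(synthetic_config(seed = 17, n_true = 5,
                                        n_decoys = 10, n_incomplete = 3,
                                        n_redundant = 0))
  prof <- shared_profile()
  h1 <- scan_proteome(prof, g$bundle$proteins, e_cutoff = 0.01,
                      n_shuffles = 300, seed = 5)
  h2 <- scan_proteome(prof, g$bundle$proteins, e_cutoff = 0.001,
                      n_shuffles = 300, seed = 5)
  expect_true(all(h2$gene_id %in% h1$gene_id))
})

test_that("similarity confirmation keeps kin and drops noise", {
  prof <- shared_profile()
  cons <- ubc_consensus()
  prots <- c(kin = cons, rnd = random_protein(148))
  hits <- data.frame(gene_id = c("kin", "rnd"))
  refs <- c(ref1 = cons)
  kept <- confirm_by_similarity(hits, prots, refs, bit_threshold = 50)
  expect_equal(kept$gene_id, "kin")
  all_kept <- confirm_by_similarity(hits, prots, refs, bit_threshold = 0)
  expect_setequal(all_kept$gene_id, c("kin", "rnd"))
  # random sequence scores below the shuffle 99th percentile of the kin
  set.seed(2)
  shuffle_scores <- vapply(1:100, function(i) {
    s <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    famchar:::pairwise_local(s, cons)$score / 2
  }, numeric(1))
  rnd_score <- famchar:::pairwise_local(prots[["rnd"]], cons)$score / 2
  expect_lt(rnd_score, quantile(shuffle_scores, 0.99) + 10)
})

test_that("filtering bookkeeping conserves candidates", {
  g <- generate_genome(synthetic_config(seed = 19, n_true = 8,
                                        n_decoys = 5, n_incomplete = 4,
                                        n_redundant = 3))
  prof <- shared_profile()
  hits <- scan_proteome(prof, g$bundle$proteins, n_shuffles = 400)
  cs <- filter_candidates(hits, g$bundle$proteins)
  expect_equal(length(cs$accepted) + length(cs$removed_incomplete) +
                 length(cs$removed_redundant), nrow(cs$hits))
  expect_length(intersect(cs$accepted,
                          c(cs$removed_incomplete, cs$removed_redundant)),
                0)
  # raising min_coverage never adds accepted genes
  cs2 <- filter_candidates(hits, g$bundle$proteins, min_coverage = 0.8)
  expect_true(all(cs2$accepted %in% cs$accepted))
})

test_that("identical candidates collapse to one", {
  p <- ubc_consensus()
  prots <- c(a1 = p, a2 = p, a3 = p)
  hits <- data.frame(gene_id = names(prots), score = 100, evalue = 0,
                     t_start = 1, t_end = nchar(p), p_start = 1,
                     p_end = 148, coverage = 1)
  cs <- filter_candidates(hits, prots)
  expect_length(cs$accepted, 1)
  expect_length(cs$removed_redundant, 2)
  expect_equal(cs$accepted, "a1")  # tie broken by smaller id
  cs0 <- filter_candidates(famchar:::empty_hits(), character())
  expect_length(cs0$accepted, 0)
})

test_that("names follow natural scaffold order then position", {
  gms <- list(
    x = gene_model("x", "scaffold10", 100, 200, "+", cbind(100, 200)),
    y = gene_model("y", "scaffold2", 100, 200, "+", cbind(100, 200)),
    z = gene_model("z", "scaffold2", 500, 600, "+", cbind(500, 600)))
  nm <- assign_names(c("x", "y", "z"), gms, prefix = "FAM")
  expect_equal(nm$gene_id, c("y", "z", "x"))  # scaffold2 before scaffold10
  expect_equal(nm$name, c("FAM1", "FAM2", "FAM3"))
  expect_error(assign_names(c("x", "missing"), gms), "missing")
  one <- assign_names("x", gms)
  expect_equal(one$name, "DlUBC1")
})

test_that("complete-domain implants are accepted and decoys rejected", {
  prof <- shared_profile()
  for (seed in c(23, 29, 37)) {
    g <- generate_genome(synthetic_config(seed = seed, n_true = 10,
                                          n_decoys = 10, n_incomplete = 5,
                                          n_redundant = 2))
    hits <- scan_proteome(prof, g$bundle$proteins, e_cutoff = 0.01,
                          n_shuffles = 400)
    cs <- filter_candidates(hits, g$bundle$proteins, min_coverage = 0.6)
    man <- g$manifest
    expect_setequal(cs$accepted, man$gene_id[man$role == "true"])
  }
})
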