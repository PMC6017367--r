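test_that("molecular weight matches residue-mass arithmetic", {
  expect_equal(molecular_weight("G"), 0.07507, tolerance = 1e-4)
  # additivity: one glycine residue mass apart
  expect_equal(molecular_weight("GG") - molecular_weight("G"),
               57.0519 / 1000, tolerance = 1e-9)
  expect_error(molecular_weight("ACB"), "position 3")
  # independent oracle: residue-count times mass-table dot product
  masses <- c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155,
              F = 147.1766, G = 57.0519, H = 137.1411, I = 113.1594,
              K = 128.1741, L = 113.1594, M = 131.1926, N = 114.1038,
              P = 97.1167, Q = 128.1307, R = 156.1875, S = 87.0782,
              T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
  set.seed(10)
  for (i in 1:20) {
    p <- random_protein(200)
    cnt <- table(factor(strsplit(p, "")[[1]], levels = names(masses)))
    oracle <- (sum(as.numeric(cnt) * masses) + 18.01524) / 1000
    expect_equal(molecular_weight(p), oracle, tolerance = 1e-9)
  }
})

test_that("pI of a chargeless chain is the terminal pKa midpoint", {
  pka <- famchar:::PKA_SETS$bjellqvist
  expect_equal(isoelectric_point("GGGGGG"),
               (pka[["nterm"]] + pka[["cterm"]]) / 2, tolerance = 0.01)
})

test_that("net charge brackets the pI", {
  set.seed(11)
  pka <- famchar:::PKA_SETS$bjellqvist
  for (i in 1:20) {
    p <- random_protein(80)
    pi <- isoelectric_point(p)
    ch <- strsplit(p, "")[[1]]
    counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                     function(a) sum(ch == a), numeric(1))
    expect_gt(famchar:::protein_charge(counts, pka, pi - 1), 0)
    expect_lt(famchar:::protein_charge(counts, pka, pi + 1), 0)
  }
})

test_that("bisection pI agrees with a fine grid scan", {
  set.seed(12)
  pka <- famchar:::PKA_SETS$bjellqvist
  grid <- seq(0, 14, by = 0.001)
  # independent vectorized Henderson-Hasselbalch oracle over the grid
  grid_pi <- function(p) {
    ch <- strsplit(p, "")[[1]]
    q <- 1 / (1 + 10^(grid - pka[["nterm"]])) -
      1 / (1 + 10^(pka[["cterm"]] - grid))
    for (a in c("H", "K", "R"))
      q <- q + sum(ch == a) / (1 + 10^(grid - pka[[a]]))
    for (a in c("D", "E", "C", "Y"))
      q <- q - sum(ch == a) / (1 + 10^(pka[[a]] - grid))
    grid[which.min(abs(q))]
  }
  for (i in 1:100) {
    p <- random_protein(60)
    expect_equal(isoelectric_point(p), grid_pi(p), tolerance = 0.01)
  }
})

test_that("architecture classes follow the extension rule", {
  # rule applied to two fixture rows with known spans
  expect_equal(classify_architecture(148, c(4, 147), 25), "I")
  expect_equal(classify_architecture(380, c(79, 236), 25), "IV")
  expect_equal(classify_architecture(200, c(1, 200), 25), "I")
  expect_equal(classify_architecture(200, c(1, 200), 1), "I")
  expect_equal(classify_architecture(200, c(60, 200), 25), "II")
  expect_equal(classify_architecture(200, c(1, 140), 25), "III")
})

test_that("every member gets exactly one class; counts sum to n", {
  t1 <- load_table1()
  cls <- vapply(seq_len(nrow(t1)), function(i)
    classify_architecture(t1$size_aa[i],
                          c(t1$domain_start[i], t1$domain_end[i])),
    character(1))
  expect_true(all(cls %in% c("I", "II", "III", "IV")))
  expect_equal(sum(table(cls)), 40)
  # raising the threshold never moves a member out of class I
  for (i in which(cls == "I"))
    expect_equal(classify_architecture(t1$size_aa[i],
                                       c(t1$domain_start[i],
                                         t1$domain_end[i]),
                                       extension_min = 40), "I")
})

test_that("UEV detection keys on the aligned active-site residue", {
  prof <- shared_profile()
  cons <- ubc_consensus()
  a <- famchar:::align_to_profile(prof, cons)
  expect_false(detect_uev(cons, prof, a$pairs))
  asite <- ubc_active_site()
  dead <- cons
  substr(dead, asite, asite) <- "S"
  ad <- famchar:::align_to_profile(prof, dead)
  expect_true(detect_uev(dead, prof, ad$pairs))
  # deleted site -> flagged with a warning
  no_site <- a$pairs[a$pairs[, 1] != prof$active_site_col, ]
  expect_warning(flag <- detect_uev(cons, prof, no_site), "deleted")
  expect_true(flag)
})

test_that("UEV flags agree with generator ground truth", {
  prof <- shared_profile()
  for (seed in c(41, 43)) {
    g <- generate_genome(synthetic_config(seed = seed, n_true = 8,
                                          n_decoys = 3, n_incomplete = 2,
                                          n_redundant = 1, n_uev = 3))
    hits <- scan_proteome(prof, g$bundle$proteins, n_shuffles = 300)
    alns <- attr(hits, "alignments")
    man <- g$manifest
    true_ids <- man$gene_id[man$role == "true"]
    got <- vapply(true_ids, function(gid)
      detect_uev(g$bundle$proteins[[gid]], prof, alns[[gid]]), logical(1))
    expect_equal(unname(got), man$uev[match(true_ids, man$gene_id)])
  }
})

test_that("family summary of a single member collapses to that member", {
  one <- data.frame(name = "m1", full_length_bp = 1000, orf_bp = 300,
                    size_aa = 99, mw_kda = 11, pi = 7, introns = 2)
  s <- summarize_family(one)
  expect_equal(unname(s$stats["full_length_bp", ]), c(1000, 1000, 1000))
  expect_equal(s$n, 1)
})

test_that("characterized synthetic members obey the ORF invariant", {
  prof <- shared_profile()
  g <- generate_genome(synthetic_config(seed = 47, n_true = 6,
                                        n_decoys = 3, n_incomplete = 2,
                                        n_redundant = 1))
  hits <- scan_proteome(prof, g$bundle$proteins, n_shuffles = 300)
  cs <- filter_candidates(hits, g$bundle$proteins)
  nm <- assign_names(cs$accepted, g$bundle$genes)
  fam <- characterize_family(nm, g$bundle, hits, prof)
  expect_equal(fam$orf_bp, 3 * (fam$size_aa + 1))
  expect_true(all(fam$pi > 0 & fam$pi < 14))
  expect_true(all(fam$mw_kda > 0))
  expect_true(all(fam$domain_end <= fam$size_aa))
})
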