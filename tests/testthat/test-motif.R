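test_that("consensus scanning finds all (i, i+4) S/T pairs including overlaps", {
  m <- scan_consensus(c(A = "SAAAS"))
  expect_equal(nrow(m), 1)
  expect_equal(m$first_pos, 1L)
  expect_equal(m$plus4_pos, 5L)
  expect_equal(m$window, "SAAAS")

  # position 5 is the +4 site of one match and the first site of the next
  m2 <- scan_consensus(c(A = "SAAASAAAS"))
  expect_equal(m2$first_pos, c(1L, 5L))
  expect_equal(m2$plus4_pos, c(5L, 9L))

  expect_equal(nrow(scan_consensus(c(A = "AAAA"))), 0)
  # tyrosine never matches
  expect_equal(nrow(scan_consensus(c(A = "YAAAY"))), 0)
})

test_that("scanner equals the brute-force double-loop oracle", {
  set.seed(21)
  for (L in c(5, 6, 30, 300)) {
    for (rep in 1:5) {
      s <- random_protein(L)
      got <- scan_consensus(c(X = s))
      want <- brute_force_scan(s)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(cbind(got$first_pos, got$plus4_pos), unname(want))
      }
    }
  }
  # one long sequence
  s <- random_protein(10000, seed = 22)
  got <- scan_consensus(c(X = s))
  want <- brute_force_scan(s)
  expect_equal(cbind(got$first_pos, got$plus4_pos), unname(want))
})

test_that("reversing a sequence maps matches by the coordinate transform", {
  s <- random_protein(500, seed = 23)
  L <- nchar(s)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  fwd <- scan_consensus(c(X = s))
  bwd <- scan_consensus(c(X = rev_s))
  # pair (i, i+4) in the original appears as (L+1-(i+4), L+1-i) reversed
  expect_setequal(bwd$first_pos, L + 1L - fwd$plus4_pos)
})

test_that("site evidence maps onto matches with the published worked examples", {
  # RCN1-like: reduced sites S113 (mult 2) and S117 (mult 2 and 1)
  rcn1 <- paste0(strrep("A", 112), "S", "AAA", "S", strrep("A", 30))
  seqs <- c(RCN1 = rcn1)
  matches <- scan_consensus(seqs)
  expect_true(any(matches$first_pos == 113 & matches$plus4_pos == 117))
  site_results <- data.frame(
    protein_id = "RCN1", position = c(113, 117, 117),
    multiplicity = c(2L, 2L, 1L), log2FC = c(-2, -1.8, -1.5),
    p_value = c(1e-4, 1e-4, 1e-3), stringsAsFactors = FALSE)
  pc <- map_sites_to_matches(matches, site_results, sequences = seqs)
  hit <- pc[pc$first_pos == 113, ]
  expect_equal(hit$n_first_reduced, 1)
  expect_equal(hit$classification, "first_reduced_only")
  expect_true(hit$first_only_in_multi)

  # HSL1-like: reduced S1325, S1328, S1329 (all mult 2); match (1325, 1329)
  hsl1 <- paste0(strrep("A", 1324), "S", "AA", "SS", strrep("A", 20))
  seqs2 <- c(HSL1 = hsl1)
  m2 <- scan_consensus(seqs2)
  expect_true(any(m2$first_pos == 1325 & m2$plus4_pos == 1329))
  sr2 <- data.frame(protein_id = "HSL1", position = c(1325, 1328, 1329),
                    multiplicity = 2L, log2FC = -2, p_value = 1e-5,
                    stringsAsFactors = FALSE)
  pc2 <- map_sites_to_matches(m2, sr2, sequences = seqs2)
  expect_equal(pc2$n_first_reduced[pc2$first_pos == 1325], 1)
  expect_true(pc2$first_only_in_multi[pc2$first_pos == 1325])
})

test_that("primed pairs require evidence at both positions; no sites means none", {
  seqs <- c(P = "AAASAAATAAA")  # match (4, 8)
  matches <- scan_consensus(seqs)
  expect_equal(nrow(matches), 1)
  no_sites <- data.frame(protein_id = character(0), position = numeric(0),
                         multiplicity = integer(0), log2FC = numeric(0),
                         p_value = numeric(0))
  pc0 <- map_sites_to_matches(matches, no_sites)
  expect_equal(pc0$classification, "none")

  both <- data.frame(protein_id = "P", position = c(4, 8),
                     multiplicity = c(2L, 1L), log2FC = c(-2, 1.2),
                     p_value = c(1e-4, 1e-3), stringsAsFactors = FALSE)
  pc1 <- map_sites_to_matches(matches, both, sequences = seqs)
  expect_equal(pc1$classification, "primed_pair")
  expect_equal(pc1$plus4_multiplicities, "1")

  plus4_only <- both[2, ]
  pc2 <- map_sites_to_matches(matches, plus4_only)
  expect_equal(pc2$classification, "plus4_only")

  # evidence = "call" mode reuses precomputed flags
  both$call <- c("reduced", "enhanced")
  pc3 <- map_sites_to_matches(matches, both, evidence = "call")
  expect_equal(pc3$classification, "primed_pair")

  # out-of-bounds site positions are rejected when sequences are given
  oob <- data.frame(protein_id = "P", position = 99, multiplicity = 1L,
                    log2FC = -2, p_value = 1e-4)
  expect_error(map_sites_to_matches(matches, oob, sequences = seqs),
               "exceeds sequence length")
})

test_that("multiplicity statistics report fractions with explicit denominators", {
  seqs <- c(P = paste(rep("SAAA", 6), collapse = ""))  # many matches
  matches <- scan_consensus(seqs)
  mk_sites <- function(mults) {
    firsts <- matches$first_pos[seq_along(mults)]
    data.frame(protein_id = rep("P", length(mults)), position = firsts,
               multiplicity = mults, log2FC = rep(-2, length(mults)),
               p_value = rep(1e-4, length(mults)), stringsAsFactors = FALSE)
  }
  all2 <- multiplicity_statistics(map_sites_to_matches(matches, mk_sites(c(2L, 2L, 3L))))
  expect_equal(all2$fraction_first_only_multi, 1.0)
  half <- multiplicity_statistics(map_sites_to_matches(matches, mk_sites(c(1L, 2L, 1L, 2L))))
  expect_equal(half$fraction_first_only_multi, 0.5)
  expect_equal(half$n_first_sites, 4)

  empty <- multiplicity_statistics(map_sites_to_matches(matches, mk_sites(integer(0))))
  expect_false(empty$defined)
  expect_true(is.na(empty$fraction_first_only_multi))
  expect_false(is.nan(empty$fraction_first_only_multi))
})

test_that("the planted multiplicity fraction is recovered through the full pipeline", {
  cfg <- simulation_config(n_substrates = 200, seed = 1)
  sim <- simulate_study(cfg)
  res <- run_study_analysis(sim, seed = 1)
  expect_gte(res$multiplicity$n_first_sites, 150)
  expect_lt(abs(res$multiplicity$fraction_first_only_multi - 0.75), 0.08)
  # +4 evidence is dominated by monophosphorylation
  expect_gt(res$multiplicity$fraction_plus4_mono, 0.7)
})

test_that("consensus enrichment separates planted substrates from clean background", {
  # identical composition in both sets: statistic must be zero
  seqs_same <- c(A1 = "SAAASAA", A2 = "SAAASAA", B1 = "SAAASAA", B2 = "SAAASAA")
  sites_same <- data.frame(protein_id = names(seqs_same), position = 1)
  e0 <- consensus_enrichment(c("A1", "A2"), c("B1", "B2"), seqs_same,
                             sites_same, n_shuffles = 10, seed = 1)
  expect_equal(e0$statistic, 0)

  # substrates all carry a phospho-supported match, background has no S/T
  sub_seqs <- stats::setNames(rep(sprintf("SAAAT%s", strrep("A", 40)), 5),
                              sprintf("SUB%d", 1:5))
  bg_seqs <- stats::setNames(rep(strrep("ALKV", 12), 5), sprintf("BG%d", 1:5))
  sites <- data.frame(protein_id = sprintf("SUB%d", 1:5), position = 1)
  e1 <- consensus_enrichment(names(sub_seqs), names(bg_seqs),
                             c(sub_seqs, bg_seqs), sites,
                             n_shuffles = 99, seed = 1)
  expect_equal(e1$statistic, 1.0)
  expect_lte(e1$p_value, 1 / (99 + 1) + 1e-12)

  expect_error(consensus_enrichment(c("A", "B"), c("B", "C"), seqs_same,
                                    sites_same), "disjoint")
  expect_error(consensus_enrichment("A1", "B1", seqs_same, sites_same,
                                    n_shuffles = 0), "n_shuffles")
})

test_that("planted enrichment is detected across seeds at reduced scale", {
  # power check: simulated substrates vs background, within-protein shuffles
  detected <- logical(8)
  for (s in seq_along(detected)) {
    cfg <- simulation_config(n_proteins = 60, n_substrates = 15,
                             mean_protein_length = 200, seed = s)
    sq <- generate_sequences(cfg)
    tr <- sq$truth$substrate_sites
    subs <- unique(tr$protein_id)
    bg <- setdiff(names(sq$sequences), subs)
    sites <- data.frame(protein_id = tr$protein_id, position = tr$first_pos)
    e <- consensus_enrichment(subs, bg, sq$sequences, sites,
                              n_shuffles = 199, seed = s)
    detected[s] <- e$p_value < 0.01
  }
  expect_gte(mean(detected), 0.95)
})
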