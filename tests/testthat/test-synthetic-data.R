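test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_substrates = 50, n_proteins = 20),
               "n_substrates")
  expect_error(simulation_config(replicates_per_group = 1),
               "replicates_per_group")
  expect_error(simulation_config(missingness_rate = 1.5),
               "missingness_rate")
  expect_error(simulation_config(fraction_primed_multiplicity_ge2 = -0.1),
               "fraction_primed_multiplicity_ge2")
  expect_error(simulation_config(rna_protein_correlation = 2),
               "rna_protein_correlation")
})

test_that("every planted consensus pair is spaced 4 apart on S/T and is rediscoverable", {
  cfg <- simulation_config(n_proteins = 50, n_substrates = 15, seed = 7)
  sq <- generate_sequences(cfg)
  tr <- sq$truth$substrate_sites
  expect_equal(nrow(tr), 15)
  expect_true(all(tr$plus4_pos - tr$first_pos == 4))
  expect_true(all(tr$first_residue %in% c("S", "T")))
  expect_true(all(tr$plus4_residue %in% c("S", "T")))
  # residues actually present in the sequences
  for (k in seq_len(nrow(tr))) {
    s <- sq$sequences[[tr$protein_id[k]]]
    expect_true(substr(s, tr$first_pos[k], tr$first_pos[k]) %in% c("S", "T"))
    expect_true(substr(s, tr$plus4_pos[k], tr$plus4_pos[k]) %in% c("S", "T"))
  }
  # cross-module property: the scanner re-discovers every planted pair
  matches <- scan_consensus(sq$sequences)
  planted_key <- paste(tr$protein_id, tr$first_pos)
  found_key <- paste(matches$protein_id, matches$first_pos)
  expect_true(all(planted_key %in% found_key))
})

test_that("a single substrate among one protein carries a planted pair; zero substrates plant nothing", {
  one <- generate_sequences(simulation_config(n_proteins = 1, n_substrates = 1,
                                              seed = 7))
  expect_gte(nrow(one$truth$substrate_sites), 1)
  m <- scan_consensus(one$sequences)
  expect_gte(nrow(m), 1)

  none <- generate_sequences(simulation_config(n_proteins = 10,
                                               n_substrates = 0, seed = 3))
  expect_equal(nrow(none$truth$substrate_sites), 0)
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulation_config(n_proteins = 50, n_substrates = 10, seed = 1)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(a$sequences, f1)
  write_fasta(b$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("noise-free limit: empirical fold changes equal planted effect sizes", {
  cfg <- simulation_config(n_proteins = 60, n_substrates = 20,
                           cv_intensity = 0, missingness_rate = 0, seed = 2)
  sq <- generate_sequences(cfg)
  sites <- generate_phospho_table(cfg, sq$sequences, sq$truth)
  expect_false(anyNA(sites))
  tr <- sq$truth$substrate_sites
  wt_cols <- grep("^WT_PDS_", names(sites), value = TRUE)
  mut_cols <- grep("^mck1del_PDS_", names(sites), value = TRUE)
  first <- merge(sites, tr[, c("protein_id", "first_pos")],
                 by.x = c("protein_id", "position"),
                 by.y = c("protein_id", "first_pos"))
  l2fc_first <- rowMeans(first[, wt_cols]) - rowMeans(first[, mut_cols])
  expect_equal(mean(l2fc_first), 2.0, tolerance = 0.05)
  plus4 <- merge(sites, tr[, c("protein_id", "plus4_pos")],
                 by.x = c("protein_id", "position"),
                 by.y = c("protein_id", "plus4_pos"))
  plus4 <- plus4[plus4$multiplicity == 1, ]
  l2fc_plus4 <- rowMeans(plus4[, mut_cols]) - rowMeans(plus4[, wt_cols])
  expect_equal(mean(l2fc_plus4), 1.0, tolerance = 0.05)
})

test_that("missingness control: zero rate leaves no absences, positive rate censors low intensities", {
  cfg0 <- simulation_config(n_proteins = 40, missingness_rate = 0, seed = 4)
  sim0 <- simulate_study(cfg0)
  expect_false(anyNA(sim0$sites))
  expect_false(anyNA(sim0$protein$values))

  cfg1 <- simulation_config(n_proteins = 200, missingness_rate = 0.1, seed = 4)
  sim1 <- simulate_study(cfg1)
  meta <- c("record_id", "protein_id", "position", "residue",
            "multiplicity", "localization_prob")
  vals <- as.matrix(sim1$sites[, setdiff(names(sim1$sites), meta)])
  rate <- mean(is.na(vals))
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
  # censoring is at low intensity: judge against the same records without
  # missingness (intensities are drawn before censoring in the stream)
  cfg0 <- simulation_config(n_proteins = 200, missingness_rate = 0, seed = 4)
  sim0 <- simulate_study(cfg0)
  full <- as.matrix(sim0$sites[, setdiff(names(sim0$sites), meta)])
  row_base <- rowMeans(full)
  hit <- rowSums(is.na(vals)) > 0
  expect_lt(mean(row_base[hit]), mean(row_base) - 1)
})

test_that("primed-only multiplicity fraction is recovered at the truth level", {
  cfg <- simulation_config(n_proteins = 400, n_substrates = 200, seed = 1)
  sq <- generate_sequences(cfg)
  frac <- mean(sq$truth$substrate_sites$primed_only_multi)
  expect_gte(frac, 0.67)  # binomial 95% band at n = 200, p = 0.75
  expect_lte(frac, 0.83)
  # and the site table honors it: planted first sites with primed_only flag
  # appear only at multiplicity 2
  sites <- generate_phospho_table(cfg, sq$sequences, sq$truth)
  tr <- sq$truth$substrate_sites
  first_recs <- merge(sites, tr, by.x = c("protein_id", "position"),
                      by.y = c("protein_id", "first_pos"))
  expect_true(all(first_recs$multiplicity[first_recs$primed_only_multi] >= 2))
  expect_true(all(first_recs$multiplicity[!first_recs$primed_only_multi] == 1))
})

test_that("planted transcript-protein effect correlation is honored", {
  # perfect correlation plants identical-ranked effects
  cfg1 <- simulation_config(n_proteins = 100, n_down_genes = 60,
                            n_up_genes = 0, n_gcn5_regulon = 0,
                            n_regulon_overlap = 0,
                            rna_protein_correlation = 1, seed = 5)
  expr1 <- generate_expression_tables(cfg1, generate_sequences(cfg1)$truth)
  eff <- expr1$truth$expression_effects
  de <- eff[eff$class == "down", ]
  expect_equal(cor(de$log2fc_rna, de$log2fc_protein), 1.0, tolerance = 0.01)

  # moderate correlation at n = 500 planted genes
  cfg2 <- simulation_config(n_proteins = 500, n_substrates = 0,
                            n_down_genes = 500, n_up_genes = 0,
                            n_gcn5_regulon = 0, n_regulon_overlap = 0,
                            rna_protein_correlation = 0.4, seed = 5)
  expr2 <- generate_expression_tables(cfg2, generate_sequences(cfg2)$truth)
  de2 <- expr2$truth$expression_effects
  expect_equal(cor(de2$log2fc_rna, de2$log2fc_protein), 0.4, tolerance = 0.1)

  # empty regulon plants nothing
  cfg0 <- simulation_config(n_proteins = 50, n_down_genes = 0, n_up_genes = 0,
                            n_gcn5_regulon = 0, n_regulon_overlap = 0, seed = 5)
  expr0 <- generate_expression_tables(cfg0, generate_sequences(cfg0)$truth)
  expect_true(all(expr0$truth$expression_effects$log2fc_rna == 0))
})

test_that("generators reject a truth from a different configuration", {
  cfg_a <- simulation_config(n_proteins = 20, seed = 1)
  cfg_b <- simulation_config(n_proteins = 20, seed = 2)
  sq <- generate_sequences(cfg_a)
  expect_error(generate_phospho_table(cfg_b, sq$sequences, sq$truth),
               "mismatch")
  expect_error(generate_expression_tables(cfg_b, sq$truth), "mismatch")
})

test_that("regulon membership sizes and overlap follow the configuration", {
  cfg <- simulation_config(n_proteins = 200, n_down_genes = 50,
                           n_up_genes = 20, n_gcn5_regulon = 40,
                           n_regulon_overlap = 25, seed = 9)
  tr <- generate_sequences(cfg)$truth
  memb <- tr$regulon$membership
  expect_equal(sum(memb %in% c("mck1_activated", "both")), 50)
  expect_equal(sum(memb %in% c("gcn5_activated", "both")), 40)
  expect_equal(sum(memb == "both"), 25)
})
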