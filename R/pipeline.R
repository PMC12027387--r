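# End-to-end convenience wrapper tying the modules together, used by the
# worked examples and the acceptance script.

#' Filter a site table on localization probability
#'
#' In-memory counterpart of the filter applied by [read_site_table()]:
#' removes records whose phosphogroup localization probability is below
#' the threshold.
#'
#' @param sites a site table data.frame.
#' @param min_localization threshold (default 0.75).
#' @return the filtered table with attribute `n_excluded`.
#' @export
filter_sites <- function(sites, min_localization = 0.75) {
  keep <- sites$localization_prob >= min_localization
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Run the full differential / occupancy / priming / integration analysis
#'
#' Runs the complete inference chain on a simulated (or assembled) study:
#' localization filtering, median normalization, left-censored imputation,
#' moderated differential testing with permutation FDR on all three
#' layers, occupancy normalization to the proteome, consensus scanning
#' with priming classification and multiplicity statistics, and
#' transcript-protein integration. When the study carries ground truth,
#' recovery metrics (primed-pair sensitivity and false-positive rate) are
#' computed as well.
#'
#' @param study a `pp_study` from [simulate_study()], or a list with the
#'   same elements (`sequences`, `sites`, `transcript`, `protein`, and
#'   optionally `truth`, `config`).
#' @param fold_phospho fold threshold for the phosphopeptide sets
#'   (default 2).
#' @param fold_expression fold threshold for transcript/protein layers
#'   (default 1.5).
#' @param fdr_threshold q-value threshold (default 0.05).
#' @param min_localization localization filter (default 0.75).
#' @param seed seed for imputation and permutation sampling.
#' @return a list with components `phospho`, `protein`, `transcript`
#'   (each: `fit`, `calls`), `occupancy`, `occupancy_overlap`, `matches`,
#'   `priming`, `protein_summary`, `multiplicity`, `integration`
#'   (`correlation`, `quadrants`, `regulon_overlap`), and `recovery`
#'   (when truth is available).
#' @export
run_study_analysis <- function(study, fold_phospho = 2, fold_expression = 1.5,
                               fdr_threshold = 0.05, min_localization = 0.75,
                               seed = 1) {
  genotypes <- unique(study$protein$samples$genotype)
  contrast <- rev(genotypes)  # mutant vs reference
  phase <- utils::tail(unique(study$protein$samples$phase), 1)

  analyze_layer <- function(fm, fold) {
    fm <- median_normalize(fm)
    fm <- impute_missing(fm, seed = seed)
    fit <- diff_test(fm, contrast = contrast, phase = phase)
    fit <- permutation_fdr(fit, seed = seed)
    list(fit = fit, calls = call_features(fit, fold_threshold = fold,
                                          fdr_threshold = fdr_threshold))
  }

  sites <- filter_sites(study$sites, min_localization)
  phospho <- analyze_layer(site_matrix(sites), fold_phospho)
  protein <- analyze_layer(study$protein, fold_expression)
  transcript <- analyze_layer(study$transcript, fold_expression)

  occ <- compute_occupancy(phospho$fit, protein$fit,
                           fold_threshold = fold_phospho,
                           fdr_threshold = fdr_threshold, seed = seed)
  occ_overlap <- level_overlap(
    occ$feature_id[occ$call_phospho == "reduced"],
    occ$feature_id[!is.na(occ$call_occupancy) & occ$call_occupancy == "reduced"],
    direction = "reduced")

  matches <- scan_consensus(study$sequences)
  site_info <- phospho$fit$feature_data
  site_results <- merge(site_info, phospho$calls, by = "feature_id")
  priming <- map_sites_to_matches(matches, site_results,
                                  sequences = study$sequences)
  prot_summary <- priming_protein_summary(priming)
  mult <- multiplicity_statistics(priming)

  correlation <- tryCatch(
    correlate_layers(transcript$calls, protein$calls),
    error = function(e) list(r = NA_real_, n = 0, genes = character(0)))
  quadrants <- classify_quadrants(transcript$calls, protein$calls)

  regulon_overlap <- NULL
  if (!is.null(study$truth)) {
    gcn5 <- study$truth$regulon$gene_id[
      study$truth$regulon$membership %in% c("gcn5_activated", "both")]
    de_down <- transcript$calls$feature_id[transcript$calls$call == "reduced"]
    if (length(gcn5) > 0 && length(de_down) > 0) {
      regulon_overlap <- gene_set_overlap(de_down, gcn5,
                                          universe = study$truth$protein_ids)
    }
  }

  recovery <- NULL
  if (!is.null(study$truth) && nrow(study$truth$substrate_sites) > 0) {
    substrates <- unique(study$truth$substrate_sites$protein_id)
    all_ids <- names(study$sequences)
    primed <- prot_summary$protein_id[prot_summary$has_primed_pair]
    recovery <- list(
      primed_sensitivity = mean(substrates %in% primed),
      primed_false_rate = mean(setdiff(all_ids, substrates) %in% primed),
      n_substrates = length(substrates))
  }

  list(contrast = contrast, phase = phase,
       phospho = phospho, protein = protein, transcript = transcript,
       occupancy = occ, occupancy_overlap = occ_overlap,
       matches = matches, priming = priming,
       protein_summary = prot_summary, multiplicity = mult,
       integration = list(correlation = correlation, quadrants = quadrants,
                          regulon_overlap = regulon_overlap),
       recovery = recovery)
}
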