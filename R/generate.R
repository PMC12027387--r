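# Synthetic-data generators. Three independent RNG streams are derived from
# the master seed (sequences / phospho table / expression tables) so that,
# e.g., changing the number of phosphosites never perturbs the sequences.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background residue frequencies: S and T upweighted to 8% each so that
# background (non-planted) consensus pairs occur and specificity is testable;
# remaining 18 residues share the rest uniformly.
residue_frequencies <- function() {
  p <- rep(0.84 / 18, 20)
  names(p) <- AA20
  p[c("S", "T")] <- 0.08
  p
}

#' Generate protein sequences with planted kinase consensus sites
#'
#' Draws `n_proteins` random amino-acid sequences from a fixed background
#' frequency table (serine and threonine at 8% each) and plants, in each of
#' `n_substrates` proteins, one (S/T)XXX(S/T) consensus pair: an S/T at a
#' random interior position and a second S/T exactly four residues
#' downstream. Regulon membership (planted Mck1-activated = the
#' down-regulated expression set, plus a Gcn5-activated set with a fixed
#' overlap) is assigned here so that all downstream generators share it.
#'
#' @param config a [simulation_config()] object.
#' @return a list with `sequences` (named character vector of amino-acid
#'   strings) and `truth` (class `pp_truth`): `substrate_sites` (one row per
#'   planted pair: positions, residues, planted log2 effects, and the
#'   `primed_only_multi` flag), `regulon` (per-gene membership in
#'   `mck1_activated` / `gcn5_activated` / `both` / `neither`), and the
#'   generating config.
#' @examples
#' sim <- generate_sequences(simulation_config(n_proteins = 5, n_substrates = 2))
#' sim$truth$substrate_sites
#' @export
generate_sequences <- function(config) {
  validate_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  freqs <- residue_frequencies()

  lens <- pmax(60L, as.integer(round(stats::rnorm(
    n, config$mean_protein_length, 0.15 * config$mean_protein_length))))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE, prob = freqs), collapse = "")
  }, character(1))
  names(seqs) <- ids

  substrates <- if (config$n_substrates > 0) {
    sort(sample(ids, config$n_substrates))
  } else character(0)

  if (length(substrates) > 0) {
    first_pos <- integer(length(substrates))
    first_res <- plus4_res <- character(length(substrates))
    for (k in seq_along(substrates)) {
      L <- nchar(seqs[[substrates[k]]])
      p <- sample(6:(L - 10), 1)
      r1 <- sample(c("S", "T"), 1)
      r2 <- sample(c("S", "T"), 1)
      s <- seqs[[substrates[k]]]
      substr(s, p, p) <- r1
      substr(s, p + 4, p + 4) <- r2
      seqs[[substrates[k]]] <- s
      first_pos[k] <- p
      first_res[k] <- r1
      plus4_res[k] <- r2
    }
    primed_only <- stats::runif(length(substrates)) <
      config$fraction_primed_multiplicity_ge2
    substrate_sites <- data.frame(
      protein_id = substrates,
      first_pos = first_pos,
      plus4_pos = first_pos + 4L,
      first_residue = first_res,
      plus4_residue = plus4_res,
      effect_first = -config$effect_size_first_site,
      effect_plus4 = config$effect_size_plus4_site,
      primed_only_multi = primed_only,
      stringsAsFactors = FALSE
    )
  } else {
    substrate_sites <- data.frame(
      protein_id = character(0), first_pos = integer(0),
      plus4_pos = integer(0), first_residue = character(0),
      plus4_residue = character(0), effect_first = numeric(0),
      effect_plus4 = numeric(0), primed_only_multi = logical(0),
      stringsAsFactors = FALSE
    )
  }

  down_genes <- if (config$n_down_genes > 0) sort(sample(ids, config$n_down_genes)) else character(0)
  up_genes <- if (config$n_up_genes > 0) {
    sort(sample(setdiff(ids, down_genes), config$n_up_genes))
  } else character(0)
  gcn5 <- character(0)
  if (config$n_gcn5_regulon > 0) {
    in_mck1 <- if (config$n_regulon_overlap > 0) {
      sample(down_genes, config$n_regulon_overlap)
    } else character(0)
    outside <- sample(setdiff(ids, down_genes),
                      config$n_gcn5_regulon - config$n_regulon_overlap)
    gcn5 <- sort(c(in_mck1, outside))
  }
  membership <- rep("neither", n)
  membership[ids %in% down_genes] <- "mck1_activated"
  membership[ids %in% gcn5] <- "gcn5_activated"
  membership[ids %in% down_genes & ids %in% gcn5] <- "both"
  regulon <- data.frame(gene_id = ids, membership = membership,
                        stringsAsFactors = FALSE)

  truth <- structure(list(
    config = config,
    protein_ids = ids,
    substrate_sites = substrate_sites,
    regulon = regulon,
    down_genes = down_genes,
    up_genes = up_genes
  ), class = "pp_truth")
  list(sequences = seqs, truth = truth)
}

# sample column ids in fixed design order
design_sample_ids <- function(config) {
  g <- expand.grid(replicate = seq_len(config$replicates_per_group),
                   phase = config$phases, genotype = config$genotypes,
                   stringsAsFactors = FALSE)
  make_sample_ids(g$genotype, g$phase, g$replicate)
}

# phase in which planted genotype effects act (the post-shift phase)
effect_phase <- function(config) config$phases[length(config$phases)]

check_truth <- function(config, truth) {
  if (!inherits(truth, "pp_truth"))
    stop("'truth' must come from generate_sequences()")
  if (!identical(truth$config, config))
    stop("truth/config mismatch: 'truth' was generated under a different configuration")
}

# left-censoring missingness: a soft detection limit. P(absent | x) is a
# sharp logistic in intensity (width 0.25 sd), with the limit placed so the
# overall expected missingness equals the configured rate - missing values
# are genuinely low, matching the assumption of downshifted-normal
# imputation.
inject_missing <- function(x, rate) {
  if (rate <= 0) return(x)
  if (rate >= 1) { x[] <- NA_real_; return(x) }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  tau <- 0.25 * s
  expected <- function(c) mean(stats::plogis(-(x - c) / tau)) - rate
  limit <- stats::uniroot(expected, range(x) + c(-6 * s, 6 * s))$root
  p <- stats::plogis(-(x - limit) / tau)
  x[stats::runif(length(x)) < p] <- NA_real_
  x
}

#' Generate a site-level phosphopeptide quantification table
#'
#' Produces one row per (protein, position, multiplicity) record with
#' per-sample log2-normal intensities under the study design. Planted first
#' sites are reduced by `effect_size_first_site` log2 units in the mutant
#' samples of the shifted phase and appear, with probability
#' `fraction_primed_multiplicity_ge2`, only as multiplicity-2 records;
#' planted +4 sites gain a monophosphorylated (multiplicity 1) record
#' increased by `effect_size_plus4_site`. Background sites are drawn on
#' observed S/T (and a small fraction of Y) residues. Missing values are
#' injected preferentially at low intensity.
#'
#' @param config a [simulation_config()]; must be the one used to generate
#'   `truth`.
#' @param sequences named character vector from [generate_sequences()].
#' @param truth the matching `pp_truth` object.
#' @return a data.frame with columns `record_id`, `protein_id`, `position`,
#'   `residue`, `multiplicity`, `localization_prob`, then one intensity
#'   column per sample (log2 scale; `NA` = absent).
#' @export
generate_phospho_table <- function(config, sequences, truth) {
  validate_config(config)
  check_truth(config, truth)
  if (!identical(sort(names(sequences)), sort(truth$protein_ids)))
    stop("truth/config mismatch: sequences do not match truth protein ids")
  set.seed(derive_seed(config$seed, 2L))

  planted <- truth$substrate_sites
  rec <- list()
  for (pid in names(sequences)) {
    chars <- strsplit(sequences[[pid]], "", fixed = TRUE)[[1]]
    planted_here <- planted[planted$protein_id == pid, , drop = FALSE]
    excl <- c(planted_here$first_pos, planted_here$plus4_pos)
    st_pos <- setdiff(which(chars %in% c("S", "T")), excl)
    y_pos <- setdiff(which(chars == "Y"), excl)
    n_bg <- stats::rpois(1, config$sites_per_protein)
    n_y <- stats::rbinom(1, n_bg, config$fraction_tyrosine_sites)
    n_st <- min(n_bg - n_y, length(st_pos))
    n_y <- min(n_y, length(y_pos))
    bg <- c(if (n_st > 0) sample(st_pos, n_st),
            if (n_y > 0) sample(y_pos, n_y))
    if (length(bg) > 0) {
      rec[[length(rec) + 1L]] <- data.frame(
        protein_id = pid, position = as.integer(bg), residue = chars[bg],
        multiplicity = sample(1:3, length(bg), replace = TRUE,
                              prob = c(0.6, 0.3, 0.1)),
        effect = 0, planted = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (nrow(planted) > 0) {
    rec[[length(rec) + 1L]] <- data.frame(
      protein_id = planted$protein_id, position = planted$first_pos,
      residue = planted$first_residue,
      multiplicity = ifelse(planted$primed_only_multi, 2L, 1L),
      effect = planted$effect_first, planted = TRUE, stringsAsFactors = FALSE)
    rec[[length(rec) + 1L]] <- data.frame(
      protein_id = planted$protein_id, position = planted$plus4_pos,
      residue = planted$plus4_residue, multiplicity = 1L,
      effect = planted$effect_plus4, planted = TRUE, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rec)
  recs <- recs[order(recs$protein_id, recs$position, recs$multiplicity), ,
               drop = FALSE]
  rownames(recs) <- NULL

  sample_ids <- design_sample_ids(config)
  meta <- parse_sample_ids(sample_ids)
  n_rec <- nrow(recs)
  base <- stats::rnorm(n_rec, 20, 2)
  sd_noise <- cv_to_sd_log2(config$cv_intensity)
  is_affected <- meta$genotype == config$genotypes[2] &
    meta$phase == effect_phase(config)
  vals <- matrix(0, n_rec, length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- base + if (is_affected[j]) recs$effect else 0
    noise <- if (sd_noise > 0) stats::rnorm(n_rec, 0, sd_noise) else 0
    vals[, j] <- mu + noise
  }
  vals <- inject_missing(vals, config$missingness_rate)

  # planted records represent the confidently localized class; background
  # records exercise the localization filter (~10% fall below 0.75)
  loc <- ifelse(recs$planted,
                stats::runif(n_rec, 0.75, 1),
                stats::rbeta(n_rec, 8, 1))

  out <- data.frame(
    record_id = sprintf("%s_%s%d_%d", recs$protein_id, recs$residue,
                        recs$position, recs$multiplicity),
    protein_id = recs$protein_id,
    position = recs$position,
    residue = recs$residue,
    multiplicity = recs$multiplicity,
    localization_prob = round(loc, 4),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(vals))
}

#' Generate transcript and protein abundance matrices
#'
#' Plants correlated transcript/protein log2 effects (bivariate normal with
#' correlation `rna_protein_correlation`) for the down- and up-regulated
#' gene sets in the mutant samples of the shifted phase, adds a
#' gene-specific phase response shared by both genotypes, and applies
#' log-normal noise. A fraction `protein_effect_overlap` of substrate
#' proteins additionally changes at the protein level, so that occupancy
#' and phosphorylation-level calls can disagree. The protein layer includes
#' every protein, so parent proteins of all phosphosites are quantified
#' (up to injected missingness).
#'
#' @inheritParams generate_phospho_table
#' @return a list with `transcript` and `protein` ([feature_matrix()]s,
#'   log2 scale) and `truth` augmented with `expression_effects` (planted
#'   per-gene log2FCs) and `protein_overlap` (substrate parents with a
#'   planted protein-level change).
#' @export
generate_expression_tables <- function(config, truth) {
  validate_config(config)
  check_truth(config, truth)
  set.seed(derive_seed(config$seed, 3L))

  ids <- truth$protein_ids
  n <- length(ids)
  e_rna <- e_prot <- stats::setNames(numeric(n), ids)
  cls <- stats::setNames(rep("none", n), ids)
  if (length(truth$down_genes) > 0) {
    eff <- rbinorm(length(truth$down_genes),
                   -config$effect_size_expression, -config$effect_size_expression,
                   config$sd_expression, config$sd_expression,
                   config$rna_protein_correlation)
    e_rna[truth$down_genes] <- eff[, 1]
    e_prot[truth$down_genes] <- eff[, 2]
    cls[truth$down_genes] <- "down"
  }
  if (length(truth$up_genes) > 0) {
    eff <- rbinorm(length(truth$up_genes),
                   config$effect_size_expression, config$effect_size_expression,
                   config$sd_expression, config$sd_expression,
                   config$rna_protein_correlation)
    e_rna[truth$up_genes] <- eff[, 1]
    e_prot[truth$up_genes] <- eff[, 2]
    cls[truth$up_genes] <- "up"
  }

  substrates <- unique(truth$substrate_sites$protein_id)
  n_overlap <- round(config$protein_effect_overlap * length(substrates))
  overlap_ids <- if (n_overlap > 0) sample(substrates, n_overlap) else character(0)
  overlap_eff <- stats::setNames(stats::rnorm(length(overlap_ids), -1, 0.3),
                                 overlap_ids)
  e_prot[overlap_ids] <- e_prot[overlap_ids] + overlap_eff

  sample_ids <- design_sample_ids(config)
  meta <- parse_sample_ids(sample_ids)
  is_shift <- meta$phase == effect_phase(config)
  is_affected <- meta$genotype == config$genotypes[2] & is_shift
  sd_noise <- cv_to_sd_log2(config$cv_intensity)

  build_layer <- function(effects) {
    base <- stats::rnorm(n, 10, 2)
    phase_resp <- stats::rnorm(n, 0, 1)
    vals <- matrix(0, n, length(sample_ids), dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      mu <- base + if (is_shift[j]) phase_resp else 0
      if (is_affected[j]) mu <- mu + effects
      noise <- if (sd_noise > 0) stats::rnorm(n, 0, sd_noise) else 0
      vals[, j] <- mu + noise
    }
    vals
  }
  rna_vals <- build_layer(e_rna)
  prot_vals <- inject_missing(build_layer(e_prot), config$missingness_rate)

  truth$expression_effects <- data.frame(
    gene_id = ids, log2fc_rna = unname(e_rna), log2fc_protein = unname(e_prot),
    class = unname(cls), stringsAsFactors = FALSE)
  truth$protein_overlap <- data.frame(
    protein_id = overlap_ids, log2fc = unname(overlap_eff),
    stringsAsFactors = FALSE)

  list(transcript = feature_matrix(rna_vals, layer = "transcript"),
       protein = feature_matrix(prot_vals, layer = "protein"),
       truth = truth)
}

#' Run all three generators under one configuration
#'
#' @param config a [simulation_config()].
#' @return a list of class `pp_study` with elements `config`, `sequences`,
#'   `truth` (fully augmented), `sites` (phospho table), `transcript` and
#'   `protein` (feature matrices).
#' @examples
#' sim <- simulate_study(simulation_config(n_proteins = 30, n_substrates = 5,
#'                                         n_down_genes = 10, n_up_genes = 5,
#'                                         n_gcn5_regulon = 8,
#'                                         n_regulon_overlap = 5, seed = 1))
#' names(sim)
#' @export
simulate_study <- function(config = simulation_config()) {
  sq <- generate_sequences(config)
  sites <- generate_phospho_table(config, sq$sequences, sq$truth)
  expr <- generate_expression_tables(config, sq$truth)
  structure(list(config = config, sequences = sq$sequences,
                 truth = expr$truth, sites = sites,
                 transcript = expr$transcript, protein = expr$protein),
            class = "pp_study")
}

#' Simulate four well-separated expression profiles for cluster recovery
#'
#' Builds a feature matrix whose rows follow one of four group-mean
#' profiles across the WT/mutant x EXP/PDS design: up in the shifted phase
#' in both genotypes, down in the shifted phase, up in the shifted phase in
#' WT only (regulator-dependent activation), and up in the mutant only
#' (regulator-dependent repression).
#'
#' @param n_per_cluster features per planted cluster.
#' @param magnitude profile amplitude in log2 units.
#' @param noise_sd residual log2 noise.
#' @param replicates replicates per group.
#' @param seed RNG seed.
#' @return list with `matrix` (a transcript [feature_matrix()]) and
#'   `clusters` (integer truth labels named by feature).
#' @export
simulate_cluster_profiles <- function(n_per_cluster = 50, magnitude = 2,
                                      noise_sd = 0.3, replicates = 3,
                                      seed = 1) {
  set.seed(derive_seed(seed, 4L))
  groups <- expand.grid(replicate = seq_len(replicates),
                        phase = c("EXP", "PDS"),
                        genotype = c("WT", "mck1del"),
                        stringsAsFactors = FALSE)
  sample_ids <- make_sample_ids(groups$genotype, groups$phase, groups$replicate)
  m <- magnitude
  # rows: WT_EXP, WT_PDS, mck1del_EXP, mck1del_PDS
  profiles <- rbind(
    up_in_pds = c(0, m, 0, m),
    down_in_pds = c(m, 0, m, 0),
    wt_only_up = c(0, m, 0, 0),
    mutant_only_up = c(0, 0, 0, m)
  )
  grp_key <- paste(groups$genotype, groups$phase, sep = "_")
  grp_idx <- match(grp_key, c("WT_EXP", "WT_PDS", "mck1del_EXP", "mck1del_PDS"))
  n_feat <- 4 * n_per_cluster
  labels <- rep(1:4, each = n_per_cluster)
  vals <- matrix(stats::rnorm(n_feat * length(sample_ids), 0, noise_sd),
                 n_feat, length(sample_ids))
  vals <- vals + profiles[labels, grp_idx] + stats::rnorm(n_feat, 8, 1)
  rownames(vals) <- sprintf("F%04d", seq_len(n_feat))
  colnames(vals) <- sample_ids
  names(labels) <- rownames(vals)
  list(matrix = feature_matrix(vals, layer = "transcript"),
       clusters = labels)
}
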