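#' Configuration for the synthetic multi-omics study generator
#'
#' Builds and validates the parameter set that defines a simulated
#' two-genotype (wild type vs `mck1del`), two-phase (exponential growth vs
#' post-diauxic shift) TMT-style study with planted Gsk-3 kinase-substrate
#' structure. The defaults are the package's reference study conditions and
#' are used throughout the test-suite and the acceptance script.
#'
#' Planted structure, in brief: `n_substrates` proteins carry at least one
#' (S/T)XXX(S/T) consensus pair. In `mck1del` samples of the PDS phase the
#' phosphopeptide covering the first (N-terminal) serine/threonine is reduced
#' by `effect_size_first_site` log2 units, and a monophosphorylated
#' (multiplicity 1) record at the +4 position is increased by
#' `effect_size_plus4_site` log2 units - the accumulation of the primed-only
#' species expected when the kinase that consumes it is absent. A fraction
#' `fraction_primed_multiplicity_ge2` of first sites is observed only on
#' multi-phosphopeptides (multiplicity >= 2).
#'
#' @param n_proteins number of proteins (and genes; identifiers are shared
#'   across layers).
#' @param mean_protein_length mean protein length in residues.
#' @param n_substrates number of proteins carrying a planted consensus pair
#'   (default: 10% of `n_proteins`).
#' @param sites_per_protein Poisson mean of additional (background)
#'   phosphosites per protein.
#' @param replicates_per_group replicates per genotype x phase group (>= 2).
#' @param genotypes,phases factor levels of the design; the first genotype is
#'   the reference (wild type).
#' @param effect_size_first_site log2 reduction of planted first-site
#'   phosphopeptides in the mutant (dimensionless, default 2.0).
#' @param effect_size_plus4_site log2 increase of the planted +4
#'   monophospho record in the mutant (default 1.0).
#' @param fraction_primed_multiplicity_ge2 proportion of planted first sites
#'   observed only at multiplicity >= 2.
#' @param cv_intensity coefficient of variation of the log-normal intensity
#'   noise.
#' @param missingness_rate overall proportion of intensities left missing,
#'   injected preferentially at low intensity (left censoring).
#' @param protein_effect_overlap proportion of substrate proteins whose
#'   parent-protein abundance also changes in the mutant.
#' @param n_down_genes,n_up_genes numbers of genes planted as down-/
#'   up-regulated in the mutant (PDS phase); defaults 25% and 10% of
#'   `n_proteins`. The down set is the planted Mck1-activated regulon.
#' @param effect_size_expression,sd_expression mean and sd (log2) of planted
#'   expression effects.
#' @param rna_protein_correlation correlation of planted transcript and
#'   protein log2 fold changes.
#' @param n_gcn5_regulon,n_regulon_overlap size of the planted Gcn5-activated
#'   regulon and of its overlap with the Mck1-activated (down) set
#'   (defaults 20% and 12.5% of `n_proteins`).
#' @param fraction_tyrosine_sites proportion of background phosphosites
#'   placed on tyrosine (ingested but never consensus-eligible).
#' @param seed master seed; all generators derive their own streams from it.
#'
#' @return an object of class `pp_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(n_proteins = 20, n_substrates = 5, seed = 1)
#' cfg$effect_size_first_site
#' @export
simulation_config <- function(n_proteins = 400,
                              mean_protein_length = 450,
                              n_substrates = NULL,
                              sites_per_protein = 3,
                              replicates_per_group = 3,
                              genotypes = c("WT", "mck1del"),
                              phases = c("EXP", "PDS"),
                              effect_size_first_site = 2.0,
                              effect_size_plus4_site = 1.0,
                              fraction_primed_multiplicity_ge2 = 0.75,
                              cv_intensity = 0.2,
                              missingness_rate = 0.05,
                              protein_effect_overlap = 0.25,
                              n_down_genes = NULL,
                              n_up_genes = NULL,
                              effect_size_expression = 1.5,
                              sd_expression = 0.8,
                              rna_protein_correlation = 0.4,
                              n_gcn5_regulon = NULL,
                              n_regulon_overlap = NULL,
                              fraction_tyrosine_sites = 0.05,
                              seed = 1) {
  # regulon and substrate sizes default to fixed fractions of the proteome
  # (40 substrates, 100 down / 40 up genes, 80-gene Gcn5 regulon with a
  # 50-gene overlap at the 400-protein reference scale)
  n_substrates <- n_substrates %||% round(0.10 * n_proteins)
  n_down_genes <- n_down_genes %||% round(0.25 * n_proteins)
  n_up_genes <- n_up_genes %||% round(0.10 * n_proteins)
  n_gcn5_regulon <- n_gcn5_regulon %||% round(0.20 * n_proteins)
  n_regulon_overlap <- n_regulon_overlap %||%
    min(round(0.125 * n_proteins), n_down_genes, n_gcn5_regulon)
  cfg <- list(
    n_proteins = n_proteins,
    mean_protein_length = mean_protein_length,
    n_substrates = n_substrates,
    sites_per_protein = sites_per_protein,
    replicates_per_group = replicates_per_group,
    genotypes = genotypes,
    phases = phases,
    effect_size_first_site = effect_size_first_site,
    effect_size_plus4_site = effect_size_plus4_site,
    fraction_primed_multiplicity_ge2 = fraction_primed_multiplicity_ge2,
    cv_intensity = cv_intensity,
    missingness_rate = missingness_rate,
    protein_effect_overlap = protein_effect_overlap,
    n_down_genes = n_down_genes,
    n_up_genes = n_up_genes,
    effect_size_expression = effect_size_expression,
    sd_expression = sd_expression,
    rna_protein_correlation = rna_protein_correlation,
    n_gcn5_regulon = n_gcn5_regulon,
    n_regulon_overlap = n_regulon_overlap,
    fraction_tyrosine_sites = fraction_tyrosine_sites,
    seed = seed
  )
  class(cfg) <- "pp_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  count_fields <- c("n_proteins", "n_substrates", "n_down_genes", "n_up_genes",
                    "n_gcn5_regulon", "n_regulon_overlap")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop_config(f, "must be a single non-negative integer")
  }
  prop_fields <- c("fraction_primed_multiplicity_ge2", "missingness_rate",
                   "protein_effect_overlap", "fraction_tyrosine_sites")
  for (f in prop_fields) {
    if (!is_proportion(cfg[[f]])) stop_config(f, "must be a proportion in [0, 1]")
  }
  if (!is.numeric(cfg$rna_protein_correlation) ||
      abs(cfg$rna_protein_correlation) > 1)
    stop_config("rna_protein_correlation", "must lie in [-1, 1]")
  pos_fields <- c("mean_protein_length", "sites_per_protein")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop_config(f, "must be a single positive number")
  }
  nonneg <- c("effect_size_first_site", "effect_size_plus4_site",
              "effect_size_expression", "sd_expression", "cv_intensity")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop_config(f, "must be a single non-negative number")
  }
  if (cfg$n_substrates > cfg$n_proteins)
    stop_config("n_substrates", "must not exceed n_proteins")
  if (cfg$n_down_genes + cfg$n_up_genes > cfg$n_proteins)
    stop_config("n_down_genes", "plus n_up_genes must not exceed n_proteins")
  if (cfg$n_gcn5_regulon > cfg$n_proteins)
    stop_config("n_gcn5_regulon", "must not exceed n_proteins")
  if (cfg$n_regulon_overlap > min(cfg$n_gcn5_regulon, cfg$n_down_genes))
    stop_config("n_regulon_overlap",
                "must not exceed the Gcn5 regulon or the down-regulated set")
  if (cfg$replicates_per_group < 2 ||
      cfg$replicates_per_group != round(cfg$replicates_per_group))
    stop_config("replicates_per_group", "must be an integer >= 2")
  if (length(cfg$genotypes) != 2L || anyDuplicated(cfg$genotypes))
    stop_config("genotypes", "must be two distinct labels")
  if (length(cfg$phases) < 1L || anyDuplicated(cfg$phases))
    stop_config("phases", "must be distinct labels")
  if (grepl("_", paste(c(cfg$genotypes, cfg$phases), collapse = "")))
    stop_config("genotypes", "and phases must not contain underscores")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_config("seed", "must be a single number")
  invisible(cfg)
}

#' @export
print.pp_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d proteins (%d substrates), ~%d residues\n",
              x$n_proteins, x$n_substrates, round(x$mean_protein_length)))
  cat(sprintf("  design: %s x %s, %d replicates/group\n",
              paste(x$genotypes, collapse = "/"),
              paste(x$phases, collapse = "/"), x$replicates_per_group))
  cat(sprintf("  planted effects (log2): first site -%.2f, +4 site +%.2f\n",
              x$effect_size_first_site, x$effect_size_plus4_site))
  cat(sprintf("  cv %.2f, missingness %.2f, seed %d\n",
              x$cv_intensity, x$missingness_rate, as.integer(x$seed)))
  invisible(x)
}
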