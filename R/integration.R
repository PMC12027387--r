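# Transcript-protein integration: fold-change correlation over the union
# of significant genes, quadrant classification, and gene-set overlap
# tests with exact hypergeometric p-values.

#' Correlate transcript and protein regulation
#'
#' Pearson correlation of log2 fold changes over the genes significant
#' (call other than `unchanged`) in either layer and quantified in both -
#' the construction used for published transcript/protein comparisons
#' where genes missing one layer are removed before correlating. Invariant
#' to gene ordering.
#'
#' @param rna_results,protein_results `DifferentialResult` data.frames
#'   (see [call_features()]) with `feature_id`, `log2FC` and `call`.
#' @return list with `r` (Pearson correlation), `n` (genes used) and
#'   `genes`.
#' @export
correlate_layers <- function(rna_results, protein_results) {
  for (d in list(rna_results, protein_results)) {
    if (!all(c("feature_id", "log2FC", "call") %in% names(d)))
      stop("results need feature_id, log2FC and call columns")
  }
  sig <- union(
    rna_results$feature_id[rna_results$call != "unchanged"],
    protein_results$feature_id[protein_results$call != "unchanged"])
  shared <- intersect(intersect(sig, rna_results$feature_id),
                      protein_results$feature_id)
  if (length(shared) < 3)
    stop("fewer than 3 genes significant in either layer and present in both")
  x <- rna_results$log2FC[match(shared, rna_results$feature_id)]
  y <- protein_results$log2FC[match(shared, protein_results$feature_id)]
  list(r = stats::cor(x, y), n = length(shared), genes = shared)
}

#' Classify genes into transcript/protein regulation quadrants
#'
#' Seven-way classification reusing the per-layer call flags: significant
#' in both layers and concordant (`both_up` / `both_down`), significant in
#' one layer only (`rna_only_up`, `rna_only_down`, `protein_only_up`,
#' `protein_only_down`), or `neither`. Genes significant in both layers
#' with opposite signs are rare but possible and are labelled
#' `discordant` so that class counts always sum to the analyzed universe
#' (the genes quantified in both layers).
#'
#' @inheritParams correlate_layers
#' @return data.frame `gene_id`, `log2FC_rna`, `log2FC_protein`, `class`,
#'   with a `counts` attribute (named table per class).
#' @export
classify_quadrants <- function(rna_results, protein_results) {
  if (anyDuplicated(rna_results$feature_id))
    stop("duplicate gene in the transcript layer")
  if (anyDuplicated(protein_results$feature_id))
    stop("duplicate gene in the protein layer")
  genes <- intersect(rna_results$feature_id, protein_results$feature_id)
  ri <- match(genes, rna_results$feature_id)
  pi <- match(genes, protein_results$feature_id)
  r_call <- rna_results$call[ri]
  p_call <- protein_results$call[pi]
  cls <- rep("neither", length(genes))
  cls[r_call == "enhanced" & p_call == "unchanged"] <- "rna_only_up"
  cls[r_call == "reduced" & p_call == "unchanged"] <- "rna_only_down"
  cls[r_call == "unchanged" & p_call == "enhanced"] <- "protein_only_up"
  cls[r_call == "unchanged" & p_call == "reduced"] <- "protein_only_down"
  cls[r_call == "enhanced" & p_call == "enhanced"] <- "both_up"
  cls[r_call == "reduced" & p_call == "reduced"] <- "both_down"
  cls[(r_call == "enhanced" & p_call == "reduced") |
        (r_call == "reduced" & p_call == "enhanced")] <- "discordant"
  out <- data.frame(gene_id = genes,
                    log2FC_rna = rna_results$log2FC[ri],
                    log2FC_protein = protein_results$log2FC[pi],
                    class = cls, stringsAsFactors = FALSE)
  levels_all <- c("both_up", "both_down", "rna_only_up", "rna_only_down",
                  "protein_only_up", "protein_only_down", "discordant",
                  "neither")
  attr(out, "counts") <- table(factor(cls, levels = levels_all))
  out
}

#' Gene-set overlap with exact hypergeometric significance
#'
#' Upper-tail hypergeometric p-value for observing at least the given
#' intersection when drawing `|B|` genes from a universe containing `|A|`
#' marked genes, plus the Jaccard index. Both sets must be contained in
#' the universe.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector containing both sets (e.g. all genes
#'   quantified in the relevant layer).
#' @return list of class `overlap_test`: `n_a`, `n_b`, `n_universe`,
#'   `n_intersect`, `p_value`, `jaccard`.
#' @examples
#' gene_set_overlap(letters[1:8], letters[4:9], letters)
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set_a is not contained in the universe")
  if (!all(set_b %in% universe)) stop("set_b is not contained in the universe")
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a)
  n_b <- length(set_b)
  U <- length(universe)
  p <- stats::phyper(k - 1, n_a, U - n_a, n_b, lower.tail = FALSE)
  uni <- length(union(set_a, set_b))
  structure(list(n_a = n_a, n_b = n_b, n_universe = U, n_intersect = k,
                 p_value = p,
                 jaccard = if (uni > 0) k / uni else NA_real_),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Gene-set overlap: |A| = %d, |B| = %d, universe %d, intersection %d\n",
              x$n_a, x$n_b, x$n_universe, x$n_intersect))
  cat(sprintf("  hypergeometric p = %.4g, Jaccard = %.3f\n", x$p_value, x$jaccard))
  invisible(x)
}
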