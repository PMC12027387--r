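# Occupancy-level regulation: phosphopeptide change normalized to the
# parent-protein change (ratio of ratios on the log2 scale). True
# stoichiometry estimation is out of scope; this is the standard
# "normalization to the proteome" interpretation.

#' Normalize phosphopeptide regulation to the parent proteome
#'
#' For every phosphopeptide record, subtracts the parent protein's log2
#' fold change from the phosphopeptide's (`log2FC_occupancy =
#' log2FC_phospho - log2FC_protein`). Occupancy-level significance is, by
#' default, recomputed by rerunning the moderated test and permutation FDR
#' on protein-normalized intensities (per sample, site log2 intensity
#' minus parent-protein log2 intensity); with `recompute_fdr = FALSE` the
#' phosphorylation-level q-values are reused and only the fold change is
#' normalized. Records whose parent protein is not quantified are flagged
#' and kept, with occupancy values left absent.
#'
#' @param phospho_fit a [diff_test()] fit on the phospho layer (q-values
#'   present; see [permutation_fdr()]).
#' @param protein_fit a [diff_test()] fit on the protein layer over the
#'   same samples (q-values present).
#' @param protein_of named character vector mapping phospho feature ids to
#'   parent protein ids; defaults to the `protein_id` column of the
#'   phospho fit's feature data.
#' @param fold_threshold,fdr_threshold calling thresholds applied at both
#'   levels (defaults 2-fold, q < 0.05).
#' @param n_permutations,seed passed to [permutation_fdr()] for the
#'   occupancy-level test.
#' @param recompute_fdr recompute occupancy q-values (default) or
#'   threshold the normalized fold changes with the phospho-level q.
#' @return a data.frame with one row per phospho record: `feature_id`,
#'   `protein_id`, `log2FC_phospho`, `log2FC_protein`, `log2FC_occupancy`,
#'   `q_phospho`, `q_occupancy`, `call_phospho`, `call_occupancy`,
#'   `parent_quantified`.
#' @export
compute_occupancy <- function(phospho_fit, protein_fit, protein_of = NULL,
                              fold_threshold = 2, fdr_threshold = 0.05,
                              n_permutations = NULL, seed = 1,
                              recompute_fdr = TRUE) {
  stopifnot(inherits(phospho_fit, "diff_fit"), inherits(protein_fit, "diff_fit"))
  if (is.null(phospho_fit$q_value) || is.null(protein_fit$q_value))
    stop("both fits need q-values; run permutation_fdr() first")
  if (is.null(protein_of)) {
    fd <- phospho_fit$feature_data
    if (is.null(fd) || !"protein_id" %in% names(fd))
      stop("'protein_of' not given and phospho fit carries no protein_id feature data")
    protein_of <- stats::setNames(fd$protein_id, fd$feature_id)
  }
  ids <- phospho_fit$feature_id
  if (!all(ids %in% names(protein_of)))
    stop("protein mapping missing for some phospho records")
  parent <- protein_of[ids]
  if (anyDuplicated(protein_fit$feature_id))
    stop("duplicate parent-protein entries in the protein fit")

  has_parent <- parent %in% protein_fit$feature_id
  l2_ph <- unname(phospho_fit$log2FC)
  l2_pr <- unname(protein_fit$log2FC[parent])
  l2_pr[!has_parent] <- NA_real_
  l2_occ <- l2_ph - l2_pr

  cut <- log2(fold_threshold)
  call_ph <- rep("unchanged", length(ids))
  call_ph[l2_ph <= -cut & phospho_fit$q_value < fdr_threshold] <- "reduced"
  call_ph[l2_ph >= cut & phospho_fit$q_value < fdr_threshold] <- "enhanced"

  q_occ <- rep(NA_real_, length(ids))
  if (recompute_fdr) {
    keep <- which(has_parent)
    if (length(keep) > 0) {
      prot_mat <- protein_fit$data[parent[keep], colnames(phospho_fit$data),
                                   drop = FALSE]
      occ_mat <- phospho_fit$data[keep, , drop = FALSE] - prot_mat
      rownames(occ_mat) <- ids[keep]
      occ_stats <- moderated_stats(occ_mat, phospho_fit$is_num,
                                   phospho_fit$is_den,
                                   prior_df = phospho_fit$prior_df_arg)
      occ_fit <- phospho_fit
      occ_fit$data <- occ_mat
      occ_fit$feature_id <- ids[keep]
      occ_fit$t <- stats::setNames(occ_stats$t, ids[keep])
      occ_fit$log2FC <- stats::setNames(occ_stats$log2fc, ids[keep])
      occ_fit$p_value <- stats::setNames(occ_stats$p, ids[keep])
      occ_fit$q_value <- NULL
      occ_fit <- permutation_fdr(occ_fit, n_permutations = n_permutations,
                                 seed = seed)
      q_occ[keep] <- unname(occ_fit$q_value)
    }
  } else {
    q_occ <- unname(phospho_fit$q_value)
    q_occ[!has_parent] <- NA_real_
  }
  call_occ <- rep("unchanged", length(ids))
  call_occ[!has_parent] <- NA_character_
  sig_occ <- has_parent & !is.na(q_occ) & q_occ < fdr_threshold
  call_occ[sig_occ & l2_occ <= -cut] <- "reduced"
  call_occ[sig_occ & l2_occ >= cut] <- "enhanced"

  data.frame(
    feature_id = ids,
    protein_id = unname(parent),
    log2FC_phospho = l2_ph,
    log2FC_protein = l2_pr,
    log2FC_occupancy = l2_occ,
    q_phospho = unname(phospho_fit$q_value),
    q_occupancy = q_occ,
    call_phospho = call_ph,
    call_occupancy = call_occ,
    parent_quantified = has_parent,
    stringsAsFactors = FALSE
  )
}

#' Overlap between phosphorylation-level and occupancy-level call sets
#'
#' Exact set arithmetic between the records called in a given direction at
#' the two levels: sizes, intersection, and the fraction of the first set
#' contained in the second (reported alongside its 3-decimal rounding).
#'
#' @param calls_a,calls_b either `DifferentialResult`-style data.frames
#'   with `feature_id` and a call column, or character vectors of feature
#'   ids already restricted to the direction of interest.
#' @param direction `"reduced"` or `"enhanced"` (applied when data.frames
#'   are given).
#' @return a list of class `overlap_summary`: `n_a`, `n_b`, `n_intersect`,
#'   `fraction_a_in_b`, `fraction_a_in_b_rounded`.
#' @export
level_overlap <- function(calls_a, calls_b, direction = c("reduced", "enhanced")) {
  direction <- match.arg(direction)
  pick <- function(x) {
    if (is.character(x)) return(unique(x))
    call_col <- intersect(c("call", "call_phospho", "call_occupancy"), names(x))
    if (!"feature_id" %in% names(x) || length(call_col) == 0)
      stop("expected a feature_id plus a call column, or a character vector")
    unique(x$feature_id[!is.na(x[[call_col[1]]]) & x[[call_col[1]]] == direction])
  }
  a <- pick(calls_a)
  b <- pick(calls_b)
  k <- length(intersect(a, b))
  frac <- if (length(a) == 0) NA_real_ else k / length(a)
  structure(list(n_a = length(a), n_b = length(b), n_intersect = k,
                 fraction_a_in_b = frac,
                 fraction_a_in_b_rounded = round(frac, 3),
                 direction = direction),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap (%s): |A| = %d, |B| = %d, |A n B| = %d, fraction of A in B = %s\n",
              x$direction, x$n_a, x$n_b, x$n_intersect,
              format(x$fraction_a_in_b_rounded)))
  invisible(x)
}
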