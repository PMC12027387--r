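# Gsk-3 consensus scanning and priming-site classification. The kinase
# consensus is (S/T)XXX(S/T): the kinase phosphorylates the N-terminal
# ("first") S/T after a priming kinase has phosphorylated the +4
# (C-terminal) S/T. All overlapping matches are reported: in cascades of
# 4-spaced serines a residue can be the +4 site of one match and the first
# site of the next.

# fast S/T indicator scan of a single character vector
scan_st_pairs <- function(chars) {
  L <- length(chars)
  if (L < 5) return(integer(0))
  st <- chars == "S" | chars == "T"
  first <- st & c(st[-(1:4)], rep(FALSE, 4))
  which(first)
}

#' Scan protein sequences for the (S/T)XXX(S/T) kinase consensus
#'
#' Reports every index pair `(i, i + 4)` with serine or threonine at both
#' positions, overlapping matches included, sorted by protein and first
#' position. Tyrosine never matches. Positions are 1-based; sites within
#' four residues of the C-terminus cannot open a match (no padding).
#'
#' @param sequences named character vector of amino-acid sequences (or a
#'   single unnamed sequence).
#' @return a data.frame with columns `protein_id`, `first_pos`,
#'   `plus4_pos`, `window` (the 5-residue matched substring).
#' @examples
#' scan_consensus(c(A = "SAAASAAAS"))
#' @export
scan_consensus <- function(sequences) {
  if (is.null(names(sequences))) {
    if (length(sequences) != 1L)
      stop("'sequences' must be named (or a single sequence)")
    names(sequences) <- "seq1"
  }
  out <- lapply(names(sequences), function(id) {
    chars <- strsplit(sequences[[id]], "", fixed = TRUE)[[1]]
    firsts <- scan_st_pairs(chars)
    if (length(firsts) == 0) return(NULL)
    data.frame(protein_id = id, first_pos = firsts, plus4_pos = firsts + 4L,
               window = substring(sequences[[id]], firsts, firsts + 4L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), first_pos = integer(0),
                      plus4_pos = integer(0), window = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map differential phosphosites onto consensus matches
#'
#' Annotates every consensus match with the phospho evidence observed at
#' its two positions and classifies it: `primed_pair` (reduced
#' phosphorylation at the first site and enhanced phosphorylation at the
#' +4 site), `first_reduced_only`, `plus4_only`, or `none`.
#'
#' Evidence at a position is, by default, directional significance of the
#' per-record moderated test: `p_value < alpha` with the signed `log2FC`
#' beyond `-log2(min_fold)` (reduced) or `+log2(min_fold)` (enhanced).
#' The consensus scan pre-specifies the position pair, so the operative
#' error control for a `primed_pair` call is the conjunction of the two
#' directional tests (the false pair rate is quadratic in `alpha`);
#' table-wide FDR q-values remain the right control for the headline
#' discovery sets and can be selected with `evidence = "q"`, while
#' `evidence = "call"` reuses the precomputed fold+FDR `call` flags.
#' `first_only_in_multi` records whether every reduced record at the
#' first site has multiplicity >= 2, i.e. the first-site phosphorylation
#' was observed only on dual-/multi-phosphopeptides.
#'
#' @param matches a [scan_consensus()] result.
#' @param site_results a data.frame with one row per phospho record:
#'   `protein_id`, `position`, `multiplicity`, `log2FC`, `p_value` /
#'   `q_value` (and `call` for `evidence = "call"`); e.g. a
#'   [call_features()] table merged with the site annotation.
#' @param evidence evidence rule: per-record directional `"p"` (default),
#'   FDR-adjusted `"q"`, or the precomputed `"call"` flags.
#' @param alpha significance threshold for the `"p"`/`"q"` rules
#'   (default 0.05).
#' @param min_fold minimal fold change for evidence (default 1, i.e.
#'   direction only).
#' @param sequences optional named sequences; when given, site positions
#'   exceeding the sequence length raise an error.
#' @return the `matches` data.frame with added columns
#'   `n_first_reduced`, `n_plus4_enhanced`, `first_multiplicities`,
#'   `plus4_multiplicities`, `classification`, `first_only_in_multi`.
#' @seealso [priming_protein_summary()], [multiplicity_statistics()]
#' @export
map_sites_to_matches <- function(matches, site_results,
                                 evidence = c("p", "q", "call"),
                                 alpha = 0.05, min_fold = 1,
                                 sequences = NULL) {
  evidence <- match.arg(evidence)
  req <- c("protein_id", "position", "multiplicity")
  if (!all(req %in% names(site_results)))
    stop("site_results lacks columns: ",
         paste(setdiff(req, names(site_results)), collapse = ", "))
  if (!is.null(sequences)) {
    len <- nchar(sequences)[site_results$protein_id]
    over <- !is.na(len) & site_results$position > len
    if (any(over))
      stop("site position exceeds sequence length for: ",
           paste(utils::head(unique(site_results$protein_id[over])), collapse = ", "))
  }
  if (evidence == "call") {
    if (!"call" %in% names(site_results))
      stop("'call' column required when evidence = \"call\"")
    reduced <- site_results$call == "reduced"
    enhanced <- site_results$call == "enhanced"
  } else {
    stat_col <- if (evidence == "p") "p_value" else "q_value"
    if (!all(c("log2FC", stat_col) %in% names(site_results)))
      stop("site_results needs log2FC and ", stat_col, " columns")
    cut <- log2(min_fold)
    sig <- !is.na(site_results[[stat_col]]) & site_results[[stat_col]] < alpha
    reduced <- sig & site_results$log2FC <= -cut & site_results$log2FC < 0
    enhanced <- sig & site_results$log2FC >= cut & site_results$log2FC > 0
  }
  key <- function(p, pos) paste(p, pos, sep = "@")
  red_key <- key(site_results$protein_id[reduced], site_results$position[reduced])
  enh_key <- key(site_results$protein_id[enhanced], site_results$position[enhanced])
  red_mult <- split(site_results$multiplicity[reduced], red_key)
  enh_mult <- split(site_results$multiplicity[enhanced], enh_key)

  k1 <- key(matches$protein_id, matches$first_pos)
  k4 <- key(matches$protein_id, matches$plus4_pos)
  m1 <- red_mult[k1]
  m4 <- enh_mult[k4]
  n1 <- vapply(m1, function(v) if (is.null(v)) 0L else length(v), integer(1))
  n4 <- vapply(m4, function(v) if (is.null(v)) 0L else length(v), integer(1))
  matches$n_first_reduced <- unname(n1)
  matches$n_plus4_enhanced <- unname(n4)
  matches$first_multiplicities <- vapply(m1, function(v) {
    if (is.null(v)) "" else paste(sort(v), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  matches$plus4_multiplicities <- vapply(m4, function(v) {
    if (is.null(v)) "" else paste(sort(v), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  matches$classification <- ifelse(
    n1 > 0 & n4 > 0, "primed_pair",
    ifelse(n1 > 0, "first_reduced_only",
           ifelse(n4 > 0, "plus4_only", "none")))
  matches$first_only_in_multi <- ifelse(
    n1 == 0, NA,
    vapply(m1, function(v) !is.null(v) && all(v >= 2), logical(1),
           USE.NAMES = FALSE))
  matches
}

#' Per-protein summary of priming calls
#'
#' Flags, for every protein in the match table, whether it carries at
#' least one consensus match with reduced first-site evidence, and among
#' those, whether at least one match is a full `primed_pair`.
#'
#' @param priming_calls a [map_sites_to_matches()] result.
#' @return a data.frame `protein_id`, `has_first_reduced`,
#'   `has_primed_pair`.
#' @export
priming_protein_summary <- function(priming_calls) {
  sp <- split(priming_calls, priming_calls$protein_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(protein_id = d$protein_id[1],
               has_first_reduced = any(d$n_first_reduced > 0),
               has_primed_pair = any(d$classification == "primed_pair"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Multiplicity statistics of priming calls
#'
#' Two fractions, each with numerator and denominator reported: the
#' fraction of distinct first sites with reduced phospho evidence that
#' were observed only on multi-phosphopeptides (multiplicity >= 2), and
#' the fraction of enhanced +4 evidence records that are
#' monophosphorylated (multiplicity 1). Empty call sets yield undefined
#' (`NA`) fractions with `defined = FALSE` rather than `NaN`s.
#'
#' @param priming_calls a [map_sites_to_matches()] result.
#' @return a list of class `multiplicity_summary`.
#' @export
multiplicity_statistics <- function(priming_calls) {
  first <- priming_calls[priming_calls$n_first_reduced > 0, , drop = FALSE]
  first <- first[!duplicated(paste(first$protein_id, first$first_pos)), ,
                 drop = FALSE]
  n_first <- nrow(first)
  n_first_multi <- sum(first$first_only_in_multi)

  plus4 <- priming_calls[priming_calls$n_plus4_enhanced > 0, , drop = FALSE]
  plus4 <- plus4[!duplicated(paste(plus4$protein_id, plus4$plus4_pos)), ,
                 drop = FALSE]
  mults <- unlist(strsplit(plus4$plus4_multiplicities, ";", fixed = TRUE))
  mults <- as.integer(mults[nzchar(mults)])
  n_plus4 <- length(mults)
  structure(list(
    fraction_first_only_multi = if (n_first > 0) n_first_multi / n_first else NA_real_,
    n_first_only_multi = n_first_multi,
    n_first_sites = n_first,
    fraction_plus4_mono = if (n_plus4 > 0) mean(mults == 1) else NA_real_,
    n_plus4_mono = sum(mults == 1),
    n_plus4_records = n_plus4,
    defined = n_first > 0 || n_plus4 > 0
  ), class = "multiplicity_summary")
}

#' @export
print.multiplicity_summary <- function(x, ...) {
  if (!x$defined) {
    cat("Multiplicity summary: no evidence (fractions undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("First sites observed only at multiplicity >= 2: %d/%d (%.1f%%)\n",
              x$n_first_only_multi, x$n_first_sites,
              100 * x$fraction_first_only_multi))
  cat(sprintf("+4 enhanced evidence at multiplicity 1: %d/%d (%.1f%%)\n",
              x$n_plus4_mono, x$n_plus4_records, 100 * x$fraction_plus4_mono))
  invisible(x)
}

#' Consensus-motif enrichment in substrate proteins
#'
#' Test statistic: fraction of substrate proteins with at least one
#' consensus match whose first position carries observed phospho evidence,
#' minus the same fraction among background proteins. The null
#' distribution comes from within-protein residue shuffles (composition
#' preserved, phospho positions fixed); the empirical p-value uses the
#' add-one rule `p = (1 + #(null >= observed)) / (n_shuffles + 1)`.
#'
#' @param substrate_ids,background_ids disjoint character vectors of
#'   protein ids.
#' @param sequences named character vector covering both sets.
#' @param phospho_sites data.frame `protein_id`, `position` of the phospho
#'   positions carrying evidence (e.g. reduced sites).
#' @param n_shuffles number of residue shuffles (>= 1).
#' @param seed RNG seed.
#' @return list of class `enrichment_test`: `statistic`,
#'   `fraction_substrate`, `fraction_background`, `p_value`, `n_shuffles`.
#' @export
consensus_enrichment <- function(substrate_ids, background_ids, sequences,
                                 phospho_sites, n_shuffles = 1000, seed = 1) {
  if (length(intersect(substrate_ids, background_ids)) > 0)
    stop("substrate and background sets must be disjoint")
  if (!is.numeric(n_shuffles) || n_shuffles < 1)
    stop("'n_shuffles' must be >= 1")
  all_ids <- c(substrate_ids, background_ids)
  if (!all(all_ids %in% names(sequences)))
    stop("sequences missing for some proteins")
  pos_by_prot <- split(phospho_sites$position, phospho_sites$protein_id)
  chars_by_prot <- lapply(sequences[all_ids], function(s)
    strsplit(s, "", fixed = TRUE)[[1]])

  hit_fraction <- function(char_list) {
    hits <- vapply(all_ids, function(id) {
      firsts <- scan_st_pairs(char_list[[id]])
      length(intersect(firsts, pos_by_prot[[id]])) > 0
    }, logical(1))
    c(sub = mean(hits[substrate_ids]), bg = mean(hits[background_ids]))
  }
  obs <- hit_fraction(chars_by_prot)
  stat_obs <- unname(obs["sub"] - obs["bg"])

  set.seed(derive_seed(seed, 8L))
  null_stats <- vapply(seq_len(n_shuffles), function(b) {
    shuffled <- lapply(chars_by_prot, sample)
    f <- hit_fraction(shuffled)
    unname(f["sub"] - f["bg"])
  }, numeric(1))
  p <- (1 + sum(null_stats >= stat_obs)) / (n_shuffles + 1)
  structure(list(statistic = stat_obs,
                 fraction_substrate = unname(obs["sub"]),
                 fraction_background = unname(obs["bg"]),
                 p_value = p, n_shuffles = n_shuffles,
                 null_statistics = null_stats),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("Consensus enrichment: %.3f (substrate) - %.3f (background) = %.3f\n",
              x$fraction_substrate, x$fraction_background, x$statistic))
  cat(sprintf("  empirical p = %.4g (%d shuffles)\n", x$p_value, x$n_shuffles))
  invisible(x)
}
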