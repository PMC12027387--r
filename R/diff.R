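# Moderated two-group differential testing with empirical-Bayes variance
# shrinkage and permutation-based FDR. This is the package's statistical
# core; the hyperparameter fit follows the classical method of moments on
# log variances (scaled-F model for the per-feature sample variances).

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf)).
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1L, y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Method-of-moments fit of the variance prior: per-feature sample variances
# s2 (residual df each) are modelled as scaled F draws around a prior
# (df_prior, s2_prior). Moments of log s2 identify both hyperparameters;
# e is the log-bias-corrected log variance (E[log s2] understates log
# sigma2 by digamma(d/2) - log(d/2)), so exp(mean(e)) is calibrated even
# in the infinite-prior-df limit where no excess spread remains.
fit_var_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = 0, s2_prior = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(mean(e))
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Core row-wise moderated statistics for a two-group complete matrix.
moderated_stats <- function(x, is_num, is_den, prior_df = NULL) {
  n1 <- sum(is_num)
  n2 <- sum(is_den)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  m1 <- rowMeans(x[, is_num, drop = FALSE])
  m2 <- rowMeans(x[, is_den, drop = FALSE])
  log2fc <- m1 - m2
  df_resid <- n1 + n2 - 2
  rss <- rowSums((x[, is_num, drop = FALSE] - m1)^2) +
    rowSums((x[, is_den, drop = FALSE] - m2)^2)
  s2 <- rss / df_resid

  if (is.null(prior_df)) {
    prior <- fit_var_prior(s2, df_resid)
  } else {
    stopifnot(is.numeric(prior_df), length(prior_df) == 1L, prior_df >= 0)
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0) fit_var_prior(s2, df_resid)$s2_prior else NA_real_)
  }
  d0 <- prior$df_prior
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2))
  } else {
    (d0 * prior$s2_prior + df_resid * s2) / (d0 + df_resid)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(log2fc = log2fc, t = t, p = p, s2 = s2, s2_post = s2_post,
       df_resid = df_resid, df_prior = d0, s2_prior = prior$s2_prior,
       df_total = df_total, n1 = n1, n2 = n2)
}

#' Moderated two-group differential test
#'
#' Fits, for every feature, the two-group comparison
#' `contrast[1] - contrast[2]` within one growth phase: the log2 fold
#' change is the difference of group means, the per-feature variance is
#' shrunk toward an empirical-Bayes prior whose hyperparameters
#' (`df_prior`, `s2_prior`) are estimated from the ensemble of per-feature
#' variances by the method of moments on log variances, and the moderated t
#' statistic `log2FC / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a t
#' distribution with `df_prior + df_resid` degrees of freedom. With
#' `prior_df = 0` the prior is switched off and the statistic reduces
#' exactly to the ordinary equal-variance two-sample t.
#'
#' @param fm a complete (imputed) log2 [feature_matrix()].
#' @param contrast length-2 character vector of genotype labels,
#'   numerator first (default mutant vs wild type).
#' @param phase growth phase to test within (default the last phase present).
#' @param prior_df optional fixed prior degrees of freedom; `NULL` (default)
#'   estimates it, `0` disables moderation.
#' @return an object of class `diff_fit` with components `log2FC`, `t`,
#'   `p_value` (named by feature), the hyperparameters, the data actually
#'   tested, and the design. Use [permutation_fdr()] to add q-values and
#'   [call_features()] to flag reduced/enhanced features;
#'   `as.data.frame()` extracts the per-feature result table.
#' @seealso [permutation_fdr()], [call_features()]
#' @export
diff_test <- function(fm, contrast = c("mck1del", "WT"), phase = NULL,
                      prior_df = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), length(contrast) == 2L)
  if (anyNA(fm$values))
    stop("matrix contains missing values; normalize and impute first")
  if (is.null(phase)) phase <- utils::tail(unique(fm$samples$phase), 1)
  sel <- fm$samples$genotype %in% contrast & fm$samples$phase == phase
  if (!any(sel)) stop("no samples match contrast/phase")
  sub <- subset_samples(fm, which(sel))
  is_num <- sub$samples$genotype == contrast[1]
  is_den <- sub$samples$genotype == contrast[2]
  st <- moderated_stats(sub$values, is_num, is_den, prior_df = prior_df)
  ids <- rownames(sub$values)
  structure(list(
    feature_id = ids,
    log2FC = stats::setNames(st$log2fc, ids),
    t = stats::setNames(st$t, ids),
    p_value = stats::setNames(st$p, ids),
    q_value = NULL,
    s2 = st$s2, s2_post = st$s2_post,
    df_resid = st$df_resid, df_prior = st$df_prior,
    s2_prior = st$s2_prior, df_total = st$df_total,
    contrast = contrast, phase = phase, layer = fm$layer,
    prior_df_arg = prior_df,
    data = sub$values, is_num = is_num, is_den = is_den,
    feature_data = fm$feature_data,
    call = match.call()
  ), class = "diff_fit")
}

#' @export
print.diff_fit <- function(x, ...) {
  cat(sprintf("Moderated differential test [%s]: %s vs %s, phase %s\n",
              x$layer, x$contrast[1], x$contrast[2], x$phase))
  cat(sprintf("  %d features, %d vs %d samples\n", length(x$log2FC),
              sum(x$is_num), sum(x$is_den)))
  cat(sprintf("  prior: df = %.2f, s2 = %.4g; total df = %.2f\n",
              x$df_prior, x$s2_prior, x$df_total))
  if (!is.null(x$q_value))
    cat(sprintf("  q-values from %d permutations; %d features at q < 0.05\n",
                x$n_permutations_used, sum(x$q_value < 0.05)))
  invisible(x)
}

#' @export
summary.diff_fit <- function(object, n = 10, ...) {
  df <- as.data.frame(object)
  ord <- order(df$p_value)
  cat(sprintf("Top %d of %d features (%s vs %s, %s):\n", min(n, nrow(df)),
              nrow(df), object$contrast[1], object$contrast[2], object$phase))
  print(utils::head(df[ord, ], n), row.names = FALSE)
  invisible(df[ord, ])
}

#' @export
coef.diff_fit <- function(object, ...) object$log2FC

#' @export
fitted.diff_fit <- function(object, ...) {
  m1 <- rowMeans(object$data[, object$is_num, drop = FALSE])
  m2 <- rowMeans(object$data[, object$is_den, drop = FALSE])
  fit <- object$data
  fit[, object$is_num] <- m1
  fit[, object$is_den] <- m2
  fit
}

#' @export
residuals.diff_fit <- function(object, ...) object$data - fitted(object)

#' Volcano plot of a differential fit
#' @param x a `diff_fit`.
#' @param fold_threshold,fdr_threshold guide lines for the calling
#'   thresholds.
#' @param ... passed to [plot()].
#' @export
plot.diff_fit <- function(x, fold_threshold = 2, fdr_threshold = 0.05, ...) {
  sig <- if (!is.null(x$q_value)) x$q_value < fdr_threshold else x$p_value < fdr_threshold
  cut <- log2(fold_threshold)
  col <- ifelse(sig & x$log2FC <= -cut, "blue",
                ifelse(sig & x$log2FC >= cut, "red", "grey60"))
  plot(x$log2FC, -log10(x$p_value), pch = 16, cex = 0.5, col = col,
       xlab = sprintf("log2FC (%s / %s)", x$contrast[1], x$contrast[2]),
       ylab = "-log10 p", ...)
  graphics::abline(v = c(-cut, cut), lty = 2, col = "grey40")
  invisible(x)
}

#' @export
as.data.frame.diff_fit <- function(x, ...) {
  data.frame(feature_id = x$feature_id,
             contrast = paste(x$contrast, collapse = "_vs_"),
             phase = x$phase,
             log2FC = unname(x$log2FC),
             t = unname(x$t),
             p_value = unname(x$p_value),
             q_value = if (is.null(x$q_value)) NA_real_ else unname(x$q_value),
             call = if (is.null(x$call_flag)) NA_character_ else unname(x$call_flag),
             stringsAsFactors = FALSE)
}

# enumerate or sample distinct non-identity group-label reassignments;
# returns a list of index vectors (columns taking the numerator label)
permutation_splits <- function(n, n1, balanced_dedupe, n_permutations, seed) {
  total <- choose(n, n1)
  if (total > 20000) {
    # design too large to enumerate: draw random distinct splits
    set.seed(derive_seed(seed, 6L))
    want <- n_permutations %||% 1000
    draws <- replicate(3 * want, sort(sample.int(n, n1)), simplify = FALSE)
    keys <- vapply(draws, paste, character(1), collapse = ",")
    draws <- draws[!duplicated(keys)]
    keep <- vapply(draws, function(s) {
      !identical(s, seq_len(n1)) && (!balanced_dedupe || 1L %in% s)
    }, logical(1))
    splits <- draws[keep]
    return(splits[seq_len(min(want, length(splits)))])
  }
  idx_all <- utils::combn(n, n1, simplify = FALSE)
  keep <- vapply(idx_all, function(s) {
    !identical(s, seq_len(n1)) &&
      (!balanced_dedupe || 1L %in% s)
  }, logical(1))
  splits <- idx_all[keep]
  if (length(splits) == 0)
    stop("no non-identity permutations available for this design")
  if (!is.null(n_permutations)) {
    if (n_permutations < 1) stop("'n_permutations' must be >= 1")
    if (n_permutations >= length(splits)) {
      if (n_permutations > length(splits))
        warning(sprintf("only %d distinct permutations available (requested %d); using all",
                        length(splits), n_permutations))
    } else {
      set.seed(derive_seed(seed, 6L))
      splits <- splits[sample.int(length(splits), n_permutations)]
    }
  }
  splits
}

#' Permutation-based false discovery rates for a differential fit
#'
#' Re-computes the moderated statistic under genotype-label reassignments
#' within the tested phase, pools the permuted |t| values across features,
#' and estimates, for the observed |t| of each feature,
#' `q = ((1 + V) / (B + 1)) / max(1, R)`, where `V` is the total number of
#' permuted statistics at least as extreme, `B` the number of permutations
#' and `R` the number of observed statistics at least as extreme. The
#' add-one numerator is the standard guard against zero permutation
#' counts. Estimates are monotonized to be non-increasing in |t| and
#' clipped to `[0, 1]`. For balanced designs, complementary label swaps
#' (which leave |t| unchanged) are counted once.
#'
#' @param fit a [diff_test()] result.
#' @param n_permutations number of label reassignments; `NULL` (default)
#'   uses every distinct non-identity reassignment. Requests beyond the
#'   number available fall back to all of them, with a warning.
#' @param seed seed for sampling reassignments when fewer than available
#'   are requested.
#' @return the `diff_fit` with `q_value` and `n_permutations_used` filled in.
#' @export
permutation_fdr <- function(fit, n_permutations = NULL, seed = 1) {
  stopifnot(inherits(fit, "diff_fit"))
  x <- fit$data
  n1 <- sum(fit$is_num)
  n <- ncol(x)
  # reorder so numerator columns come first; identity split = 1..n1
  ord <- order(!fit$is_num)
  x <- x[, ord, drop = FALSE]
  splits <- permutation_splits(n, n1, balanced_dedupe = n1 == n - n1,
                               n_permutations = n_permutations, seed = seed)
  B <- length(splits)
  perm_t <- vapply(splits, function(s) {
    is_num <- seq_len(n) %in% s
    abs(moderated_stats(x, is_num, !is_num,
                        prior_df = fit$prior_df_arg)$t)
  }, numeric(nrow(x)))

  t_obs <- abs(fit$t)
  o <- order(t_obs, decreasing = TRUE)
  t_sorted <- t_obs[o]
  R <- seq_along(t_sorted)
  null_sorted <- sort(as.vector(perm_t), decreasing = TRUE)
  V <- findInterval(-t_sorted, -null_sorted)
  q <- ((V + 1) / (B + 1)) / pmax(1, R)
  q <- pmin(1, q)
  q <- rev(cummin(rev(q)))  # non-increasing in |t|
  q_full <- numeric(length(t_obs))
  q_full[o] <- q
  fit$q_value <- stats::setNames(q_full, fit$feature_id)
  fit$n_permutations_used <- B
  fit
}

#' Flag reduced / enhanced features at fold and FDR thresholds
#'
#' A feature is `reduced` when `log2FC <= -log2(fold_threshold)` and
#' `q < fdr_threshold`, `enhanced` symmetrically, otherwise `unchanged`.
#'
#' @param fit a `diff_fit` with q-values (see [permutation_fdr()]).
#' @param fold_threshold fold-change threshold on the natural scale
#'   (e.g. 2 for the phosphopeptide sets, 1.5 for expression layers).
#' @param fdr_threshold q-value threshold (default 0.05).
#' @return a `DifferentialResult` data.frame: `feature_id`, `contrast`,
#'   `phase`, `log2FC`, `t`, `p_value`, `q_value`, `call`.
#' @export
call_features <- function(fit, fold_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(inherits(fit, "diff_fit"))
  if (!is.numeric(fold_threshold) || fold_threshold <= 0)
    stop("'fold_threshold' must be positive")
  if (is.null(fit$q_value))
    stop("q-values missing; run permutation_fdr() first")
  cut <- log2(fold_threshold)
  call_flag <- rep("unchanged", length(fit$log2FC))
  call_flag[fit$log2FC <= -cut & fit$q_value < fdr_threshold] <- "reduced"
  call_flag[fit$log2FC >= cut & fit$q_value < fdr_threshold] <- "enhanced"
  fit$call_flag <- stats::setNames(call_flag, fit$feature_id)
  out <- as.data.frame(fit)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' k-means clustering of differential features
#'
#' Rows are z-scored across samples, then partitioned with k-means
#' (Euclidean distance, `n_restarts` random starts, best fit by total
#' within-cluster sum of squares). Clusters are renumbered in decreasing
#' size order, so cluster 1 is always the largest; results are
#' deterministic under `seed`.
#'
#' @param x a [feature_matrix()] or a numeric matrix of (differential)
#'   features by samples.
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 50).
#' @return a data.frame `feature_id`, `cluster`, with attribute
#'   `profiles` (mean z-scored value per cluster per sample column).
#' @export
kmeans_de_clusters <- function(x, k = 4, seed = 1, n_restarts = 50) {
  if (inherits(x, "feature_matrix")) x <- x$values
  stopifnot(is.matrix(x))
  if (k > nrow(x)) stop("k exceeds the number of features")
  if (anyNA(x)) stop("matrix contains missing values")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("feature(s) with zero variance cannot be z-scored")
  z <- (x - rowMeans(x)) / sds
  set.seed(derive_seed(seed, 7L))
  km <- stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100)
  sizes <- km$size
  relabel <- order(sizes, decreasing = TRUE)
  new_id <- match(km$cluster, relabel)
  out <- data.frame(feature_id = rownames(x), cluster = new_id,
                    stringsAsFactors = FALSE)
  profiles <- km$centers[relabel, , drop = FALSE]
  rownames(profiles) <- seq_len(k)
  attr(out, "profiles") <- profiles
  out
}
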