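#' Median-normalize a log2 feature matrix
#'
#' Shifts each sample so that its median over present (non-missing) log2
#' values equals the global median, defined as the median of the per-sample
#' medians. With that definition the operation is exactly idempotent, and
#' adding a constant to one sample's log2 intensities is removed without
#' residue. Absent values remain absent.
#'
#' @param fm a [feature_matrix()] on the log2 scale.
#' @return the normalized `feature_matrix`.
#' @export
median_normalize <- function(fm) {
  x <- fm$values
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)))
    stop("sample(s) with no present values: ",
         paste(colnames(x)[!is.finite(med)], collapse = ", "))
  target <- stats::median(med)
  fm$values <- sweep(x, 2, med - target, "-")
  fm
}

#' Impute left-censored missing values from a downshifted normal
#'
#' Replaces each absent value in sample `s` by a draw from
#' `Normal(mean_s - downshift * sd_s, (width_factor * sd_s)^2)`, where
#' `mean_s` and `sd_s` are computed over the present values of that sample.
#' This is the standard left-censoring assumption for label-based
#' proteomics: values are missing mostly because they fell below the
#' detection limit, so they are imputed from the low tail of the observed
#' distribution.
#'
#' @param fm a normalized log2 [feature_matrix()].
#' @param downshift downward shift of the imputation distribution, in
#'   sample sds (default 1.8).
#' @param width_factor width of the imputation distribution, in sample sds
#'   (default 0.3).
#' @param seed optional seed making imputation deterministic.
#' @return the completed `feature_matrix` (no `NA` left).
#' @export
impute_missing <- function(fm, downshift = 1.8, width_factor = 0.3,
                           seed = NULL) {
  x <- fm$values
  if (!anyNA(x)) return(fm)
  if (!is.null(seed)) set.seed(derive_seed(seed, 5L))
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    pres <- x[!miss, j]
    if (length(pres) < 3)
      stop("sample ", colnames(x)[j],
           " has fewer than 3 present values; cannot impute")
    m <- mean(pres)
    s <- stats::sd(pres)
    x[miss, j] <- stats::rnorm(sum(miss), m - downshift * s, width_factor * s)
  }
  fm$values <- x
  fm
}
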