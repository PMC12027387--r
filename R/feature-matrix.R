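#' Features-by-samples intensity matrix with design metadata
#'
#' The shared container for the transcript, protein and phosphopeptide
#' layers: a numeric matrix (features in rows, samples in columns, log2
#' scale for intensities; `NA` = absent, distinct from a measured zero)
#' together with per-sample design metadata. Sample identifiers follow the
#' `genotype_phase_replicate` convention (e.g. `WT_PDS_2`).
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   colnames (sample ids).
#' @param samples optional data.frame with columns `sample_id`, `genotype`,
#'   `phase`, `replicate`; parsed from the column names when omitted.
#' @param layer one of `"transcript"`, `"protein"`, `"phospho"`.
#' @param feature_data optional data.frame of per-feature annotation
#'   (first column must be `feature_id` matching the rownames).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, samples = NULL,
                           layer = c("protein", "transcript", "phospho"),
                           feature_data = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids within a layer are not allowed")
  if (is.null(samples)) samples <- parse_sample_ids(colnames(values))
  req <- c("sample_id", "genotype", "phase", "replicate")
  if (!all(req %in% names(samples)))
    stop("'samples' must contain columns ", paste(req, collapse = ", "))
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("sample metadata does not match matrix columns")
  if (!is.null(feature_data)) {
    if (names(feature_data)[1] != "feature_id" ||
        !identical(as.character(feature_data$feature_id), rownames(values)))
      stop("'feature_data' must describe exactly the matrix rows")
  }
  structure(list(values = values, samples = samples, layer = layer,
                 feature_data = feature_data),
            class = "feature_matrix")
}

#' Compose / parse `genotype_phase_replicate` sample identifiers
#'
#' @param genotype,phase,replicate vectors of equal length.
#' @return `make_sample_ids`: a character vector; `parse_sample_ids`: a
#'   data.frame with columns `sample_id`, `genotype`, `phase`, `replicate`.
#' @export
make_sample_ids <- function(genotype, phase, replicate) {
  paste(genotype, phase, replicate, sep = "_")
}

#' @rdname make_sample_ids
#' @param ids character vector of sample identifiers.
#' @export
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed sample id (expected genotype_phase_replicate): ",
         paste(ids[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(sample_id = ids, genotype = m[, 1], phase = m[, 2],
             replicate = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  tab <- table(paste(x$samples$genotype, x$samples$phase, sep = "_"))
  cat("  groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing values: %d (%.1f%%)\n", n_na,
              100 * n_na / length(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

# subset a feature_matrix by sample index, keeping metadata in step
subset_samples <- function(fm, idx) {
  feature_matrix(fm$values[, idx, drop = FALSE],
                 samples = fm$samples[idx, , drop = FALSE],
                 layer = fm$layer, feature_data = fm$feature_data)
}

#' Convert a site-level quantification table to a phospho feature matrix
#'
#' One feature per (protein, position, multiplicity) record; the site
#' annotation columns are retained as `feature_data`. Intensities are
#' log2-transformed unless they already are (`log2 = FALSE` input scale).
#'
#' @param sites a site table as returned by [generate_phospho_table()] or
#'   [read_site_table()].
#' @param log2_transform set `TRUE` when intensities are on the raw scale.
#' @return a `feature_matrix` of layer `"phospho"`.
#' @export
site_matrix <- function(sites, log2_transform = FALSE) {
  meta_cols <- c("record_id", "protein_id", "position", "residue",
                 "multiplicity", "localization_prob")
  if (!all(meta_cols %in% names(sites)))
    stop("site table lacks columns: ",
         paste(setdiff(meta_cols, names(sites)), collapse = ", "))
  sample_cols <- setdiff(names(sites), meta_cols)
  vals <- as.matrix(sites[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (log2_transform) vals <- log2(vals)
  rownames(vals) <- sites$record_id
  fd <- sites[, meta_cols, drop = FALSE]
  names(fd)[1] <- "feature_id"
  rownames(fd) <- NULL
  feature_matrix(vals, layer = "phospho", feature_data = fd)
}
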