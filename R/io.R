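# Readers and writers for the package's tabular and sequence formats.
# Coordinates are 1-based residue indices throughout; absent intensities are
# written as empty fields (distinct from a measured zero).

#' Read / write protein sequences (FASTA)
#'
#' Thin wrappers over Biostrings. `read_fasta()` rejects duplicate
#' identifiers and empty files rather than silently coercing them.
#'
#' @param path file path.
#' @return `read_fasta`: a named character vector of amino-acid sequences in
#'   file order.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(aa) == 0)) stop("empty sequence in FASTA: ", path)
  stats::setNames(as.character(aa), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("'sequences' must have unique names")
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

site_meta_cols <- c("record_id", "protein_id", "position", "residue",
                    "multiplicity", "localization_prob")

#' Read a site-level phosphopeptide table, filtering on localization
#'
#' Reads the package's TSV dialect (one row per protein/position/
#' multiplicity record, per-sample intensity columns named
#' `genotype_phase_replicate`, empty field = absent) and removes records
#' whose phosphogroup localization probability falls below
#' `min_localization`. The number of excluded records is reported via a
#' message and attached as attribute `n_excluded`.
#'
#' @param path TSV file path.
#' @param min_localization minimum localization probability to retain
#'   (default 0.75).
#' @return a site table data.frame (see [generate_phospho_table()] for the
#'   schema).
#' @export
read_site_table <- function(path, min_localization = 0.75) {
  if (!is_proportion(min_localization))
    stop("'min_localization' must be in [0, 1]")
  x <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(site_meta_cols, names(x))
  if (length(missing_cols) > 0)
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(x$multiplicity %in% 1:3))
    stop("malformed multiplicity (must be 1, 2 or 3) in rows: ",
         paste(utils::head(which(!x$multiplicity %in% 1:3)), collapse = ", "))
  if (any(is.na(x$localization_prob)) ||
      any(x$localization_prob < 0 | x$localization_prob > 1))
    stop("localization_prob must lie in [0, 1]")
  sample_cols <- setdiff(names(x), site_meta_cols)
  parse_sample_ids(sample_cols)  # errors on unknown sample columns
  keep <- x$localization_prob >= min_localization
  message(sprintf("read_site_table: removed %d of %d records below localization %.2f",
                  sum(!keep), nrow(x), min_localization))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @rdname read_site_table
#' @param sites a site table data.frame.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a feature matrix as TSV
#'
#' First column `feature_id`, then one column per sample named
#' `genotype_phase_replicate`; empty field = absent value.
#'
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(feature_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param layer the layer label to attach.
#' @export
read_feature_matrix <- function(path, layer = c("protein", "transcript", "phospho")) {
  layer <- match.arg(layer)
  x <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "feature_id") stop("first column must be 'feature_id'")
  if (anyDuplicated(x$feature_id))
    stop("duplicate feature ids in ", path)
  vals <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- x$feature_id
  feature_matrix(vals, layer = layer)
}

#' Parse a printed phosphosite string
#'
#' Parses the `"S1325(2); S1328(2); S1329(2)"` notation used for published
#' phosphosite lists: semicolon-separated tokens of residue letter, 1-based
#' position, and the phosphopeptide multiplicity class in parentheses.
#' Duplicate positions with distinct multiplicities are legitimate and
#' preserved.
#'
#' @param text a single string (may be empty).
#' @return a data.frame with columns `residue`, `position`, `multiplicity`,
#'   in input order; zero rows for an empty string.
#' @examples
#' parse_site_string("S113(2); S117(2); S117(1)")
#' @export
parse_site_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(residue = character(0), position = integer(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens, regexec("^([STY])([0-9]+)\\(([0-9]+)\\)$", tokens))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed site token: ", paste(tokens[bad], collapse = ", "))
  out <- do.call(rbind, lapply(m, function(g) {
    data.frame(residue = g[2], position = as.integer(g[3]),
               multiplicity = as.integer(g[4]), stringsAsFactors = FALSE)
  }))
  if (!all(out$multiplicity %in% 1:3))
    stop("multiplicity outside 1..3 in: ", text)
  rownames(out) <- NULL
  out
}

#' Load a packaged worked-example table
#'
#' Two small tables transcribed by hand from the published study of the
#' yeast Gsk-3 kinase Mck1 ship with the package for worked examples and
#' round-trip tests (they are transcriptions, not machine-readable exports):
#' \describe{
#'   \item{`table1`}{Mck1-activated genes down-regulated in the mutant at
#'     both the transcript and protein levels, with log2 fold changes and a
#'     flag for genes bound and activated by the Cat8/Adr1 transcription
#'     factors.}
#'   \item{`table2`}{Mck1-dependent phosphoproteins bearing the
#'     (S/T)XXX(S/T) consensus, by functional category, with the
#'     reduced (`log2FC < -1`) and enhanced (`log2FC > 1`) phosphosite
#'     strings in `"S113(2); S117(2)"` notation.}
#' }
#'
#' @param table_id `"table1"` or `"table2"`.
#' @return the table as a data.frame.
#' @examples
#' t1 <- load_fixture("table1")
#' subset(t1, gene == "FBP1")
#' @export
load_fixture <- function(table_id) {
  files <- c(table1 = "mck1_activated_genes.tsv",
             table2 = "mck1_phosphoproteins.tsv")
  if (!table_id %in% names(files))
    stop("unknown fixture id '", table_id, "' (use 'table1' or 'table2')")
  path <- system.file("extdata", files[[table_id]], package = "phosphoprimer",
                      mustWork = TRUE)
  x <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                         stringsAsFactors = FALSE)
  if (table_id == "table2") {
    x$reduced_sites[is.na(x$reduced_sites)] <- ""
    x$enhanced_sites[is.na(x$enhanced_sites)] <- ""
  }
  x
}

#' Write / read planted ground truth as JSON
#'
#' @param truth a `pp_truth` object.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "pp_truth"))
  out <- truth
  out$config <- unclass(out$config)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- do.call(simulation_config, x$config)
  structure(x, class = "pp_truth")
}
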