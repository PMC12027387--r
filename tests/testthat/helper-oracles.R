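# Independent oracles and small builders shared across the suite.

# brute-force double-loop enumeration of (i, i+4) S/T pairs
brute_force_scan <- function(seq_string) {
  chars <- strsplit(seq_string, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- NULL
  for (i in seq_len(L)) {
    j <- i + 4L
    if (j > L) next
    if (chars[i] %in% c("S", "T") && chars[j] %in% c("S", "T"))
      out <- rbind(out, c(i, j))
  }
  out
}

# exhaustive hypergeometric upper tail: probability that a random |B|-subset
# of the universe intersects the fixed set A in >= k elements
enumerate_overlap_p <- function(n_universe, n_a, n_b, k) {
  subsets <- utils::combn(n_universe, n_b)
  in_a <- subsets <= n_a  # take A = first n_a universe elements
  mean(colSums(in_a) >= k)
}

# random amino-acid sequence with S/T-rich background
random_protein <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  p <- rep(0.84 / 18, 20)
  p[aa %in% c("S", "T")] <- 0.08
  paste(sample(aa, L, replace = TRUE, prob = p), collapse = "")
}

# a complete-null feature matrix under the two-genotype design
null_matrix <- function(n_features, n_per_group = 3, seed = 1) {
  set.seed(seed)
  ids <- make_sample_ids(rep(c("WT", "mck1del"), each = n_per_group), "PDS",
                         rep(seq_len(n_per_group), 2))
  vals <- matrix(stats::rnorm(n_features * 2 * n_per_group), n_features,
                 dimnames = list(sprintf("F%05d", seq_len(n_features)), ids))
  feature_matrix(vals, layer = "protein")
}

# fabricate a minimal diff_fit carrying given log2FCs and q-values
fake_fit <- function(log2FC, q) {
  ids <- sprintf("F%03d", seq_along(log2FC))
  structure(list(feature_id = ids,
                 log2FC = stats::setNames(log2FC, ids),
                 t = stats::setNames(log2FC * 10, ids),
                 p_value = stats::setNames(q, ids),
                 q_value = stats::setNames(q, ids),
                 contrast = c("mck1del", "WT"), phase = "PDS",
                 layer = "protein"),
            class = "diff_fit")
}
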