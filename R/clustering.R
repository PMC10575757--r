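#' Pairwise CDR3 sequence identity
#'
#' Fraction of identical aligned positions under global alignment with
#' match = 1, mismatch = 0 and a linear gap penalty of -1, divided by the
#' longer sequence length. Among score-optimal alignments the traceback
#' maximising the number of identical positions is used, so the value is
#' deterministic. Dividing by `max(len)` penalises length mismatch, the
#' usual convention for CDR3 family definitions.
#'
#' @param a,b Character vectors of equal length (recycled if length 1);
#'   non-empty amino-acid strings.
#' @return Numeric vector of identities in `[0, 1]`; `1` iff `a == b`.
#' @export
pairwise_identity <- function(a, b) {
  check_aa(a, "sequence a", allow_empty = FALSE)
  check_aa(b, "sequence b", allow_empty = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  cpp_identity(a, b)
}

#' Cluster a repertoire by CDR3 identity
#'
#' Greedy abundance-ordered centroid clustering (CD-HIT style): candidates
#' are visited in descending total read count (ties broken by lexicographic
#' CDR3 order), each joining the first existing cluster whose centroid CDR3
#' identity is at least `threshold`, otherwise founding a new cluster with
#' its own CDR3 as centroid. The result is a deterministic partition of the
#' input; every member has identity >= `threshold` to its cluster centroid.
#'
#' @param x Repertoire tibble (see [as_repertoire()]).
#' @param threshold Identity threshold in `(0, 1]`; default `0.5`, the
#'   conventional CDR3-family cutoff for clonal clustering.
#' @return The input tibble with `cluster_id` (integer, 1 = first-founded)
#'   and `centroid_cdr3` columns added; attribute `threshold` records the
#'   cutoff. Class `vhh_clusters`.
#' @export
cluster_by_cdr3 <- function(x, threshold = 0.5) {
  x <- as_repertoire(x)
  if (nrow(x) == 0) abort("empty repertoire")
  stopifnot(threshold > 0, threshold <= 1)
  count_cols <- grep("^count_r[0-9]+$", names(x), value = TRUE)
  total <- rowSums(as.matrix(x[, count_cols, drop = FALSE]))
  ord <- order(-total, x$cdr3, x$cdr1, x$cdr2)
  centroids <- character(0)
  cluster_id <- integer(nrow(x))
  for (i in ord) {
    cdr3 <- x$cdr3[i]
    assigned <- 0L
    if (length(centroids) > 0) {
      ident <- cpp_identity_one_many(cdr3, centroids)
      hit <- which(ident >= threshold)
      if (length(hit) > 0) assigned <- hit[1]
    }
    if (assigned == 0L) {
      centroids <- c(centroids, cdr3)
      assigned <- length(centroids)
    }
    cluster_id[i] <- assigned
  }
  out <- x
  out$cluster_id <- cluster_id
  out$centroid_cdr3 <- centroids[cluster_id]
  attr(out, "threshold") <- threshold
  class(out) <- c("vhh_clusters", class(out))
  out
}

#' Per-cluster summary of a clustered repertoire
#'
#' @param x Output of [cluster_by_cdr3()].
#' @return Tibble with one row per cluster: `cluster_id`, `centroid_cdr3`,
#'   `n_members`, and aggregated per-round counts.
#' @export
cluster_summary <- function(x) {
  stopifnot(inherits(x, "vhh_clusters"))
  count_cols <- grep("^count_r[0-9]+$", names(x), value = TRUE)
  x %>%
    as_tibble() %>%
    group_by(.data$cluster_id, .data$centroid_cdr3) %>%
    summarise(n_members = dplyr::n(), across(all_of(count_cols), sum),
              .groups = "drop") %>%
    arrange(.data$cluster_id)
}
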