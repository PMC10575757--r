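#' Pseudocount-stabilised enrichment factor between two sorting rounds
#'
#' `EF = ((n_sel + 1) / (t_sel + 1)) / ((n_base + 1) / (t_base + 1))`: the
#' fold change of a cluster's relative read abundance from a baseline FACS
#' round to a selected round, with +1 pseudocounts keeping the ratio finite
#' when a cluster is unobserved in the baseline pool. High EF flags
#' rare-but-improving binders that plain frequency ranking misses.
#'
#' @param n_sel,t_sel Cluster reads and total reads in the selected round.
#' @param n_base,t_base Cluster reads and total reads in the baseline round.
#' @param round_to_integer If `TRUE`, round to the nearest integer (the
#'   conventional reporting form); the unrounded value is the default.
#' @return Positive numeric vector of enrichment factors.
#' @export
enrichment_factor <- function(n_sel, t_sel, n_base, t_base,
                              round_to_integer = FALSE) {
  if (any(c(n_sel, t_sel, n_base, t_base) < 0)) abort("counts must be >= 0")
  if (any(n_sel > t_sel) || any(n_base > t_base)) {
    abort("cluster reads exceed round total")
  }
  ef <- ((n_sel + 1) / (t_sel + 1)) / ((n_base + 1) / (t_base + 1))
  if (round_to_integer) round(ef) else ef
}

#' Rank clusters by frequency or enrichment
#'
#' Frequency mode sorts clusters by their selected-round read count;
#' enrichment mode sorts by the enrichment factor of the selected round
#' over the baseline round. Round totals are taken over the whole clustered
#' input. Ties break by ascending `cluster_id`.
#'
#' @param x Output of [cluster_by_cdr3()].
#' @param mode `"frequency"` or `"enrichment"`.
#' @param sel_round,base_round Round indices (`base_round` is ignored in
#'   frequency mode).
#' @return Tibble of enrichment records ordered by rank: `cluster_id`,
#'   `centroid_cdr3`, `n_base`, `t_base`, `n_sel`, `t_sel`, `ef`,
#'   `ef_rounded`, `rank`.
#' @export
rank_clusters <- function(x, mode = c("enrichment", "frequency"),
                          sel_round = 2, base_round = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "vhh_clusters"))
  cs <- cluster_summary(x)
  sel_col <- sprintf("count_r%d", sel_round)
  base_col <- sprintf("count_r%d", base_round)
  if (!sel_col %in% names(cs)) abort(sprintf("unknown round %d", sel_round))
  if (mode == "enrichment" && !base_col %in% names(cs)) {
    abort(sprintf("unknown round %d", base_round))
  }
  t_sel <- sum(cs[[sel_col]])
  t_base <- if (base_col %in% names(cs)) sum(cs[[base_col]]) else NA_integer_
  rec <- tibble(
    cluster_id = cs$cluster_id,
    centroid_cdr3 = cs$centroid_cdr3,
    n_base = if (base_col %in% names(cs)) cs[[base_col]] else NA_integer_,
    t_base = t_base,
    n_sel = cs[[sel_col]],
    t_sel = t_sel
  )
  rec$ef <- if (base_col %in% names(cs)) {
    enrichment_factor(rec$n_sel, rec$t_sel, rec$n_base, rec$t_base)
  } else {
    NA_real_
  }
  rec$ef_rounded <- round(rec$ef)
  key <- if (mode == "frequency") rec$n_sel else rec$ef
  rec <- rec[order(-key, rec$cluster_id), , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  rec
}

# count-weighted region matrix over sequences of the modal region length;
# returns list(members kept, excluded fraction, length)
modal_members <- function(members, region, weights) {
  lens <- nchar(members[[region]])
  if (sum(weights) == 0) abort("no reads in the requested round")
  wl <- tapply(weights, lens, sum)
  modal_len <- as.integer(names(wl)[which.max(wl)])
  keep <- lens == modal_len
  list(keep = keep, modal_len = modal_len,
       excluded = 1 - sum(weights[keep]) / sum(weights))
}

#' Per-residue frequency matrix for one CDR region
#'
#' Count-weighted residue frequencies at each position of the region,
#' computed over the sequences whose region length equals the
#' count-weighted modal length (fixed column positions; sequences of other
#' lengths are excluded and their weight fraction reported in the
#' `excluded_fraction` attribute). Rows sum to one.
#'
#' @param members Repertoire tibble (typically one cluster).
#' @param round_index Round whose read counts weight the frequencies.
#' @param region `"cdr1"`, `"cdr2"`, `"cdr3"` or `"concatenated"`.
#' @return A `positional_matrix`: positions x 20 matrix with attributes
#'   `region`, `mode = "frequency"`, `excluded_fraction`.
#' @export
positional_frequency <- function(members, round_index, region = "cdr3") {
  region <- match.arg(region, c("cdr1", "cdr2", "cdr3", "concatenated"))
  df <- as_tibble(members)
  if (region == "concatenated") {
    df$concatenated <- paste0(df$cdr1, df$cdr2, df$cdr3)
  }
  cc <- sprintf("count_r%d", round_index)
  if (!cc %in% names(df)) abort(sprintf("unknown round %d", round_index))
  w <- df[[cc]]
  mm <- modal_members(df, region, w)
  df <- df[mm$keep, , drop = FALSE]
  w <- w[mm$keep]
  if (nrow(df) == 0 || sum(w) == 0) abort("no sequences after length filtering")
  aa <- amino_acids()
  mat <- matrix(0, nrow = mm$modal_len, ncol = 20,
                dimnames = list(NULL, aa))
  chars <- do.call(rbind, strsplit(df[[region]], ""))
  for (p in seq_len(mm$modal_len)) {
    tab <- tapply(w, factor(chars[, p], levels = aa), sum)
    tab[is.na(tab)] <- 0
    mat[p, ] <- tab / sum(w)
  }
  structure(mat, region = region, mode = "frequency",
            excluded_fraction = mm$excluded, class = "positional_matrix")
}

#' Per-residue enrichment-ratio matrix between two rounds
#'
#' `(f_sel + pseudo) / (f_base + pseudo)` where `f` are the count-weighted
#' per-position residue frequencies of [positional_frequency()] in the
#' selected and baseline rounds. Entries above one mark residues observed
#' at higher relative frequency after the selected round. The default
#' pseudocount, one over the smaller round's total reads, keeps every
#' entry positive and shrinks ratios at low coverage; it is symmetric in
#' the two rounds, so swapping rounds gives the entrywise reciprocal.
#'
#' @param members Repertoire tibble (typically one cluster).
#' @param sel_round,base_round Round indices.
#' @param pseudo Pseudocount; `NULL` for the default.
#' @param region As in [positional_frequency()].
#' @return A `positional_matrix` with `mode = "enrichment"`; all entries
#'   are strictly positive.
#' @export
positional_enrichment <- function(members, sel_round, base_round,
                                  pseudo = NULL, region = "cdr3") {
  f_sel <- positional_frequency(members, sel_round, region)
  f_base <- positional_frequency(members, base_round, region)
  if (!identical(dim(f_sel), dim(f_base))) {
    abort("modal region length differs between rounds; cannot form ratio")
  }
  if (is.null(pseudo)) {
    cc_sel <- sum(members[[sprintf("count_r%d", sel_round)]])
    cc_base <- sum(members[[sprintf("count_r%d", base_round)]])
    pseudo <- 1 / min(cc_sel, cc_base)
  }
  stopifnot(pseudo > 0)
  mat <- (unclass(f_sel) + pseudo) / (unclass(f_base) + pseudo)
  structure(mat, region = attr(f_sel, "region"), mode = "enrichment",
            pseudo = pseudo, class = "positional_matrix")
}

#' @export
print.positional_matrix <- function(x, ...) {
  cat(sprintf("<positional_matrix> %s, mode=%s, %d positions\n",
              attr(x, "region"), attr(x, "mode"), nrow(x)))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Tidy a positional matrix into long form
#'
#' @param x A `positional_matrix`.
#' @param ... Unused.
#' @return Tibble with `position`, `residue`, `value`, `region`, `mode`.
#' @export
tidy.positional_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    position = rep(seq_len(nrow(m)), times = ncol(m)),
    residue = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    region = attr(x, "region"),
    mode = attr(x, "mode")
  )
}

#' Heatmap of a positional matrix
#'
#' Frequency matrices are drawn on the unit scale; enrichment matrices on
#' the log2 ratio scale centred at zero.
#'
#' @param object A `positional_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.positional_matrix <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = amino_acids())
  if (attr(object, "mode") == "enrichment") {
    df$value <- log2(df$value)
    lab <- "log2 enrichment"
    sc <- ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                        high = "#1b7837", name = lab)
  } else {
    sc <- ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                       name = "frequency")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    sc +
    ggplot2::labs(x = sprintf("%s position", attr(object, "region")),
                  y = NULL) +
    ggplot2::theme_minimal()
}
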