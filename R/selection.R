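#' Candidate-selection configuration
#'
#' Operationalises the four nomination criteria used when picking a small
#' panel per cluster for synthesis: (1) at least `min_from_top100`
#' best-NLL sequences from the top 100 ranks; (2) additional sequences
#' spanning the NLL range; (3) coverage of a pI range; (4) per-cluster
#' liability-free variants and representation of both the NGS and sampled
#' sources. Descriptor cutoffs are hard constraints on every chosen
#' sequence.
#'
#' @param max_per_cluster Panel size ceiling per cluster.
#' @param min_from_top100 Minimum picks from ranks <= 100.
#' @param nll_spread Also pick sequences near spread anchor points across
#'   the NLL range.
#' @param nll_spread_points Explicit NLL anchor values; `NULL` derives the
#'   two tercile boundaries of the passing candidates' NLL range at call
#'   time (explicit anchors make the selection independent of candidates
#'   that are neither chosen nor anchor-defining).
#' @param descriptor_cutoffs Named numeric vector of hard maxima, e.g.
#'   `c(cdr_hydropathy = 2, cdr_positive_charge = 3)`.
#' @param pi_bins pI bin boundaries (pH units); default bins
#'   `<6.5, 6.5-7.5, 7.5-8.5, >8.5`.
#' @param require_liability_free_variant Add a variant clearing any
#'   moderate/low flag category carried by a chosen sequence.
#' @param require_both_sources Ensure NGS and sampled sources are both
#'   represented when both exist among passing candidates.
#' @return A `selection_config` list.
#' @export
selection_config <- function(max_per_cluster = 10L, min_from_top100 = 3L,
                             nll_spread = TRUE, nll_spread_points = NULL,
                             descriptor_cutoffs = numeric(0),
                             pi_bins = c(6.5, 7.5, 8.5),
                             require_liability_free_variant = TRUE,
                             require_both_sources = TRUE) {
  stopifnot(max_per_cluster >= min_from_top100)
  structure(list(
    max_per_cluster = as.integer(max_per_cluster),
    min_from_top100 = as.integer(min_from_top100),
    nll_spread = isTRUE(nll_spread),
    nll_spread_points = nll_spread_points,
    descriptor_cutoffs = descriptor_cutoffs,
    pi_bins = sort(pi_bins),
    require_liability_free_variant = isTRUE(require_liability_free_variant),
    require_both_sources = isTRUE(require_both_sources)
  ), class = "selection_config")
}

# flag categories at moderate/low severity carried by a profile row
soft_flag_categories <- function(flag_string) {
  if (!nzchar(flag_string)) return(character(0))
  parts <- strsplit(strsplit(flag_string, ";")[[1]], ":")
  cats <- vapply(parts, function(p) p[4], character(1))
  sevs <- vapply(parts, function(p) p[5], character(1))
  unique(cats[sevs %in% c("moderate", "low")])
}

all_flag_categories <- function(flag_string) {
  if (!nzchar(flag_string)) return(character(0))
  parts <- strsplit(strsplit(flag_string, ";")[[1]], ":")
  unique(vapply(parts, function(p) p[4], character(1)))
}

#' Nominate candidates for synthesis from a ranked, profiled pool
#'
#' Deterministic greedy fill over an NLL-ascending candidate list with
#' developability profiles attached (see [rank_pool()] and
#' [assess_developability()]):
#' tagged `top_nll` picks satisfy the top-100 quota; `nll_spread` picks
#' are the passing sequences nearest each NLL anchor; `pi_diversity`
#' picks fill empty pI bins; `liability_free_variant` picks clear soft
#' flag categories carried by the panel; `source_balance` swaps in the
#' best passing sequence of a missing source. Filling stops at
#' `max_per_cluster`. Candidates failing a hard descriptor cutoff are
#' excluded with reason `descriptor_cutoff:<name>`; if nothing passes,
#' the selection is empty rather than an error.
#'
#' @param candidates Tibble sorted ascending by `nll` with columns
#'   `cdr1`, `cdr2`, `cdr3`, `source`, `nll` and profile columns.
#' @param config A [selection_config()].
#' @return A `selection_report`: list with `selected` (chosen rows plus
#'   `rationale`), `excluded` (rows with `reason`), and `config`.
#' @export
select_candidates <- function(candidates, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  cand <- as_tibble(candidates)
  if (is.unsorted(cand$nll)) abort("candidates must be sorted ascending by NLL")
  cand$.rank <- seq_len(nrow(cand))

  # hard descriptor cutoffs
  fail_reason <- rep(NA_character_, nrow(cand))
  for (d in names(config$descriptor_cutoffs)) {
    if (!d %in% names(cand)) abort(sprintf("missing descriptor column %s", d))
    bad <- is.na(fail_reason) & cand[[d]] > config$descriptor_cutoffs[[d]]
    fail_reason[bad] <- paste0("descriptor_cutoff:", d)
  }
  excluded <- cand[!is.na(fail_reason), , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- fail_reason[!is.na(fail_reason)]
  pass <- cand[is.na(fail_reason), , drop = FALSE]

  chosen <- integer(0)   # row indices into pass
  rationale <- character(0)
  room <- function() length(chosen) < config$max_per_cluster
  add <- function(i, tag) {
    if (length(i) == 1 && !is.na(i) && !(i %in% chosen) && room()) {
      chosen <<- c(chosen, i)
      rationale <<- c(rationale, tag)
    }
  }

  if (nrow(pass) > 0) {
    # (1) best-NLL picks from ranks <= 100
    top100 <- which(pass$.rank <= 100)
    for (i in top100) {
      if (sum(rationale == "top_nll") >= config$min_from_top100) break
      add(i, "top_nll")
    }
    # (2) NLL spread anchors
    if (config$nll_spread && room()) {
      anchors <- config$nll_spread_points
      if (is.null(anchors)) {
        rng <- range(pass$nll)
        anchors <- rng[1] + diff(rng) * c(1, 2) / 3
      }
      for (a in anchors) {
        if (!room()) break
        free <- setdiff(seq_len(nrow(pass)), chosen)
        if (length(free) == 0) break
        i <- free[which.min(abs(pass$nll[free] - a))]
        add(i, "nll_spread")
      }
    }
    # (3) pI bin coverage
    if ("pI" %in% names(pass) && length(config$pi_bins) > 0 && room()) {
      bin_of <- function(v) findInterval(v, config$pi_bins)
      covered <- unique(bin_of(pass$pI[chosen]))
      for (bn in sort(setdiff(unique(bin_of(pass$pI)), covered))) {
        if (!room()) break
        free <- setdiff(which(bin_of(pass$pI) == bn), chosen)
        if (length(free) > 0) add(free[1], "pi_diversity")
      }
    }
    # (4) liability-free variants for soft-flagged picks
    if (config$require_liability_free_variant && "flags" %in% names(pass) &&
        room()) {
      soft <- unique(unlist(lapply(pass$flags[chosen], soft_flag_categories)))
      for (categ in soft) {
        if (!room()) break
        clean <- vapply(pass$flags, function(f)
          !(categ %in% all_flag_categories(f)), logical(1))
        free <- setdiff(which(clean), chosen)
        if (length(free) > 0 &&
            !any(vapply(pass$flags[chosen], function(f)
              !(categ %in% all_flag_categories(f)), logical(1)))) {
          add(free[1], "liability_free_variant")
        }
      }
    }
    # (5) top off with the best remaining NLL ranks up to the panel size
    for (i in seq_len(nrow(pass))) {
      if (!room()) break
      add(i, "top_nll")
    }
    # (6) source balance: swap in the best passing sequence of a missing source
    if (config$require_both_sources && length(chosen) > 0) {
      have <- unique(pass$source[chosen])
      missing_src <- setdiff(unique(pass$source), have)
      if (length(missing_src) == 1) {
        cand_i <- which(pass$source == missing_src)[1]
        if (!is.na(cand_i)) {
          if (room()) {
            add(cand_i, "source_balance")
          } else {
            # replace the worst-NLL non-quota pick
            worst <- chosen[which.max(pass$nll[chosen])]
            swapped <- pass[worst, , drop = FALSE]
            swapped$reason <- "swapped_out:source_balance"
            excluded <- bind_rows(excluded, swapped)
            keep <- chosen != worst
            chosen <- c(chosen[keep], cand_i)
            rationale <- c(rationale[keep], "source_balance")
          }
        }
      }
    }
  }

  selected <- pass[chosen, , drop = FALSE]
  if (nrow(selected) > 0) {
    selected$rationale <- rationale
    selected <- selected %>% arrange(.data$nll)
  } else {
    selected$rationale <- character(0)
  }
  selected$.rank <- NULL
  if (nrow(excluded) > 0) excluded$.rank <- NULL
  structure(list(selected = selected, excluded = excluded, config = config),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d selected, %d excluded\n",
              nrow(x$selected), nrow(x$excluded)))
  if (nrow(x$selected) > 0) {
    print(x$selected[, intersect(c("cdr3", "source", "nll", "rationale"),
                                 names(x$selected))])
  }
  invisible(x)
}

#' @describeIn select_candidates Selected rows as a tibble.
#' @param x,... Method arguments.
#' @export
tidy.selection_report <- function(x, ...) as_tibble(x$selected)

#' @describeIn select_candidates One-row summary (counts per source and
#'   rationale).
#' @export
glance.selection_report <- function(x, ...) {
  tibble(
    n_selected = nrow(x$selected),
    n_excluded = nrow(x$excluded),
    n_ngs = sum(x$selected$source == "ngs"),
    n_sampled = sum(x$selected$source == "sampled"),
    nll_min = if (nrow(x$selected)) min(x$selected$nll) else NA_real_,
    nll_max = if (nrow(x$selected)) max(x$selected$nll) else NA_real_
  )
}
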