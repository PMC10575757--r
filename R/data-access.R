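#' Published NKp46 VHH campaign tables
#'
#' Small bundled tables from a published anti-NKp46 VHH discovery
#' campaign (humanised CDR3-grafted yeast-display library, two FACS
#' rounds, MiSeq NGS), used as reference inputs for validating the
#' workflow:
#'
#' * `nkp46_cluster_reads()` -- per-round NGS read counts of the four
#'   CDR3 clusters carried into generative modelling, with the reported
#'   enrichment factors (round 2 vs round 0).
#' * `nkp46_round_totals()` -- total reads per FACS round.
#' * `nkp46_representatives()` -- the most-occurring CDR1-3 sequence of
#'   the five most-enriched and five most-frequent CDR3 clusters (eight
#'   distinct clusters; two occur in both sets) with binding affinities.
#' * `nkp46_panel()` -- the 37 synthesised VHHs grouped by CDR3 cluster,
#'   with source (NGS vs generative sampling), NLL score and affinity.
#' * `nkp46_degradation()` -- forced oxidation/deamidation outcomes
#'   (percent modified species per CDR) for one potent sequence per
#'   cluster.
#'
#' @return A tibble.
#' @name nkp46_data
NULL

read_extdata <- function(file) {
  readr::read_csv(system.file("extdata", file, package = "vhhmine"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname nkp46_data
#' @export
nkp46_cluster_reads <- function() read_extdata("nkp46_cluster_reads.csv")

#' @rdname nkp46_data
#' @export
nkp46_round_totals <- function() read_extdata("nkp46_round_totals.csv")

#' @rdname nkp46_data
#' @export
nkp46_representatives <- function() read_extdata("nkp46_representatives.csv")

#' @rdname nkp46_data
#' @export
nkp46_panel <- function() read_extdata("nkp46_panel.csv")

#' @rdname nkp46_data
#' @export
nkp46_degradation <- function() read_extdata("nkp46_degradation.csv")
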