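#' Default pKa table (EMBOSS values)
#'
#' Side-chain and termini pKa values used by [isoelectric_point()],
#' shipped as a plain data file so an independent check can read the same
#' source.
#'
#' @return Tibble with `group`, `pka`, `charge`.
#' @export
default_pka_table <- function() {
  readr::read_csv(system.file("extdata", "pka_emboss.csv",
                              package = "vhhmine"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Residue hydropathy scale
#'
#' @param name Scale name; `"kyte_doolittle"` is shipped.
#' @return Named numeric vector over the 20 amino acids (higher = more
#'   hydrophobic).
#' @export
hydropathy_scale <- function(name = "kyte_doolittle") {
  f <- system.file("extdata", sprintf("hydropathy_%s.csv", name),
                   package = "vhhmine")
  if (!nzchar(f)) abort(sprintf("unknown hydropathy scale '%s'", name))
  df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  setNames(df$value, df$residue)
}

# default liability motif tiers; all configurable through detect_liabilities
liability_motif_config <- function() {
  list(
    deamidation_high = c("NG"),
    deamidation_moderate = c("NS", "NT", "NN", "ND", "NH"),
    isomerization_high = c("DG"),
    isomerization_moderate = c("DS", "DT", "DD")
  )
}

#' Scan CDRs for chemical liability and PTM motifs
#'
#' Flags every CDR asparagine (deamidation), aspartate (isomerisation),
#' methionine (oxidation) and cysteine (unpaired cysteine), plus N-X-S/T
#' glycosylation sequons with X != P. Severity tiers: `high` for NG, DG,
#' any Met, any Cys and sequons; `moderate` for N followed by S/T/N/D/H
#' and D followed by S/T/D; `low` otherwise (for example Asn-Tyr, a
#' non-canonical motif that still deamidates measurably and is therefore
#' flagged, never silently ignored). The motif string is the dipeptide
#' (or tripeptide for sequons); a terminal N/D with no successor is
#' reported as the single residue at `low` severity.
#'
#' @param cdr1,cdr2,cdr3 Amino-acid strings (one sequence).
#' @param motifs Motif tier configuration, see `liability_motif_config()`.
#' @return Tibble with `region`, `position` (1-based within region),
#'   `motif`, `category`, `severity`.
#' @export
detect_liabilities <- function(cdr1, cdr2, cdr3,
                               motifs = liability_motif_config()) {
  regions <- list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3)
  rows <- list()
  for (rn in names(regions)) {
    s <- regions[[rn]]
    check_aa(s, rn)
    if (!nzchar(s)) next
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    for (p in seq_len(L)) {
      r <- ch[p]
      nxt <- if (p < L) ch[p + 1] else ""
      di <- paste0(r, nxt)
      if (r == "N") {
        sev <- if (di %in% motifs$deamidation_high) "high"
               else if (di %in% motifs$deamidation_moderate) "moderate"
               else "low"
        rows[[length(rows) + 1]] <- tibble(
          region = rn, position = p, motif = if (nzchar(nxt)) di else r,
          category = "deamidation", severity = sev)
        # N-X-S/T sequon, X != P
        if (p + 2 <= L && ch[p + 1] != "P" && ch[p + 2] %in% c("S", "T")) {
          rows[[length(rows) + 1]] <- tibble(
            region = rn, position = p,
            motif = paste0(ch[p], ch[p + 1], ch[p + 2]),
            category = "glycosylation_sequon", severity = "high")
        }
      } else if (r == "D") {
        sev <- if (di %in% motifs$isomerization_high) "high"
               else if (di %in% motifs$isomerization_moderate) "moderate"
               else "low"
        rows[[length(rows) + 1]] <- tibble(
          region = rn, position = p, motif = if (nzchar(nxt)) di else r,
          category = "isomerization", severity = sev)
      } else if (r == "M") {
        rows[[length(rows) + 1]] <- tibble(
          region = rn, position = p, motif = r,
          category = "oxidation", severity = "high")
      } else if (r == "C") {
        rows[[length(rows) + 1]] <- tibble(
          region = rn, position = p, motif = r,
          category = "unpaired_cysteine", severity = "high")
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(region = character(0), position = integer(0),
                  motif = character(0), category = character(0),
                  severity = character(0)))
  }
  bind_rows(rows)
}

# net Henderson-Hasselbalch charge of a sequence at a given pH
net_charge <- function(sequence, ph, pka = default_pka_table()) {
  ch <- strsplit(sequence, "")[[1]]
  counts <- table(factor(ch, levels = amino_acids()))
  pk <- setNames(pka$pka, pka$group)
  sign <- setNames(pka$charge, pka$group)
  q <- 0
  for (g in pka$group) {
    n_g <- switch(g, n_terminus = 1, c_terminus = 1,
                  as.numeric(counts[g]))
    if (is.na(n_g) || n_g == 0) next
    if (sign[g] == "positive") {
      q <- q + n_g / (1 + 10^(ph - pk[g]))
    } else {
      q <- q - n_g / (1 + 10^(pk[g] - ph))
    }
  }
  q
}

#' Isoelectric point by bisection
#'
#' pH at which the net Henderson-Hasselbalch charge (N/C termini plus
#' D, E, C, Y, H, K, R side chains) crosses zero, located by bisection on
#' `[0, 14]` to a tolerance of 1e-4 pH units. A sequence without ionisable
#' side chains still has a defined pI from its termini.
#'
#' @param sequence Amino-acid string.
#' @param pka pKa table as in [default_pka_table()].
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = default_pka_table()) {
  check_aa(sequence, "sequence", allow_empty = FALSE)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximum windowed CDR hydropathy
#'
#' Sequence-level surrogate for structure-based aggregation-propensity
#' scores: the maximum over all sliding windows (within each CDR
#' independently; a CDR shorter than the window contributes its
#' full-length mean) of the mean residue hydropathy under a published
#' scale. Higher values mean a more hydrophobic (aggregation-prone) CDR
#' patch.
#'
#' @param cdr1,cdr2,cdr3 Amino-acid strings.
#' @param window Window width in residues.
#' @param scale Named residue scale; default Kyte-Doolittle.
#' @return Numeric score (dimensionless, scale units).
#' @export
cdr_hydropathy <- function(cdr1, cdr2, cdr3, window = 5,
                           scale = hydropathy_scale()) {
  stopifnot(window >= 1)
  best <- -Inf
  for (s in c(cdr1, cdr2, cdr3)) {
    check_aa(s, "cdr")
    if (!nzchar(s)) next
    v <- unname(scale[strsplit(s, "")[[1]]])
    if (length(v) <= window) {
      best <- max(best, mean(v))
    } else {
      cs <- cumsum(c(0, v))
      means <- (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
      best <- max(best, max(means))
    }
  }
  best
}

#' CDR positive-charge surrogate
#'
#' Count of arginine and lysine residues across the three CDRs plus 0.1
#' per histidine: a sequence-level stand-in for structure-based positive
#' patch energies, preserving their filtering role against non-specific
#' binding.
#'
#' @param cdr1,cdr2,cdr3 Amino-acid strings.
#' @return Non-negative numeric score.
#' @export
cdr_positive_charge <- function(cdr1, cdr2, cdr3) {
  s <- paste0(cdr1, cdr2, cdr3)
  check_aa(s, "cdr")
  ch <- strsplit(s, "")[[1]]
  sum(ch %in% c("R", "K")) + 0.1 * sum(ch == "H")
}

#' Framework human-likeness
#'
#' Percent identical positions between a framework sequence and a human
#' germline under the package's global alignment, divided by the
#' alignment length.
#'
#' @param framework,germline Non-empty amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
framework_identity <- function(framework, germline) {
  check_aa(framework, "framework", allow_empty = FALSE)
  check_aa(germline, "germline", allow_empty = FALSE)
  st <- cpp_alignment_stats(framework, germline)
  100 * st$matches / st$columns
}

#' Reference descriptor statistics for traffic-light cutoffs
#'
#' Mean and standard deviation per descriptor over a user-supplied
#' reference set (for example a panel of marketed antibodies, which is not
#' shipped). Used to colour descriptor values green (within one SD of the
#' mean), yellow (within two) or red (beyond).
#'
#' @param df Data frame of descriptor values (one row per reference
#'   molecule) or a data frame with `descriptor`, `mean`, `sd` columns.
#' @return A `reference_stats` tibble with `descriptor`, `mean`, `sd`.
#' @export
reference_stats <- function(df) {
  df <- as_tibble(df)
  if (all(c("descriptor", "mean", "sd") %in% names(df))) {
    out <- df[, c("descriptor", "mean", "sd")]
  } else {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    out <- tibble(
      descriptor = num,
      mean = vapply(num, function(v) mean(df[[v]]), numeric(1)),
      sd = vapply(num, function(v) stats::sd(df[[v]]), numeric(1))
    )
  }
  if (any(!is.na(out$sd) & out$sd <= 0)) {
    abort("reference SD must be > 0 for every traffic-lit descriptor")
  }
  structure(out, class = c("reference_stats", class(out)))
}

# descriptors that are traffic-lit, all in the "low is good" direction;
# pI is reported but not lit (a diversity axis, not a cutoff)
lit_descriptors <- function() c("cdr_hydropathy", "cdr_positive_charge")

traffic_light <- function(value, mean, sd) {
  dplyr::case_when(
    value <= mean + sd ~ "green",
    value <= mean + 2 * sd ~ "yellow",
    TRUE ~ "red"
  )
}

#' Sequence-level developability profile
#'
#' Aggregates all sequence-level descriptors and liability flags for each
#' sequence of a repertoire: isoelectric point of the concatenated CDRs
#' (or of framework + CDRs when a framework is given), maximum windowed
#' CDR hydropathy, CDR positive-charge count, optional framework
#' human-likeness, liability flags, and traffic lights for the
#' cutoff-bearing descriptors relative to a [reference_stats()] object.
#' Without a reference the lights are omitted and the raw values still
#' reported. These are declared sequence-level surrogates for
#' structure-based profiling; the descriptor definitions are recorded in
#' the `surrogate_descriptors` attribute of the result.
#'
#' @param x Repertoire-like tibble with `cdr1`, `cdr2`, `cdr3`.
#' @param reference Optional [reference_stats()].
#' @param germline Optional human germline framework string; requires a
#'   `framework` column or attribute to score human-likeness.
#' @param framework Optional fixed framework sequence shared by all rows.
#' @return The input with descriptor columns (`pI`, `cdr_hydropathy`,
#'   `cdr_positive_charge`, `framework_identity_pct`), `flags`
#'   (semicolon-joined `region:pos:motif:category:severity`),
#'   `n_high_flags`, and `light_*` columns when a reference is given.
#' @export
assess_developability <- function(x, reference = NULL, germline = NULL,
                                  framework = NULL) {
  x <- as_tibble(x)
  n <- nrow(x)
  pI <- numeric(n); hyd <- numeric(n); chg <- numeric(n)
  flags <- character(n); nhigh <- integer(n)
  for (i in seq_len(n)) {
    c1 <- x$cdr1[i]; c2 <- x$cdr2[i]; c3 <- x$cdr3[i]
    full <- if (is.null(framework)) paste0(c1, c2, c3)
            else paste0(framework, c1, c2, c3)
    pI[i] <- isoelectric_point(full)
    hyd[i] <- cdr_hydropathy(c1, c2, c3)
    chg[i] <- cdr_positive_charge(c1, c2, c3)
    fl <- detect_liabilities(c1, c2, c3)
    flags[i] <- paste(sprintf("%s:%d:%s:%s:%s", fl$region, fl$position,
                              fl$motif, fl$category, fl$severity),
                      collapse = ";")
    nhigh[i] <- sum(fl$severity == "high")
  }
  out <- x
  out$pI <- pI
  out$cdr_hydropathy <- hyd
  out$cdr_positive_charge <- chg
  out$framework_identity_pct <- if (!is.null(germline) && !is.null(framework)) {
    framework_identity(framework, germline)
  } else {
    NA_real_
  }
  out$flags <- flags
  out$n_high_flags <- nhigh
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "reference_stats"))
    for (d in intersect(lit_descriptors(), reference$descriptor)) {
      r <- reference[reference$descriptor == d, ]
      out[[paste0("light_", d)]] <- traffic_light(out[[d]], r$mean, r$sd)
    }
  }
  attr(out, "surrogate_descriptors") <- c(
    cdr_hydropathy = "max sliding-window mean Kyte-Doolittle hydropathy over CDRs",
    cdr_positive_charge = "count of R+K (+0.1 per H) across CDRs"
  )
  out
}
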