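#' Read an annotated VHH repertoire table
#'
#' Reads a CSV/TSV table of pre-annotated CDR sequences with per-round read
#' counts. The delimiter is chosen from the file extension (`.csv` comma,
#' `.tsv`/`.txt` tab); a header row is required. Rows sharing an identical
#' (CDR1, CDR2, CDR3) triplet are merged by summing their counts: the merged
#' table defines the unique-sequence universe used by all downstream stages.
#'
#' @param path Path to the table.
#' @param schema Named list mapping the expected fields (`seq_id`, `cdr1`,
#'   `cdr2`, `cdr3`) to column names in the file. Defaults to identical
#'   names. Count columns are found by `count_pattern`.
#' @param count_pattern Regular expression with one capture group extracting
#'   the round index from a count column name (default matches
#'   `count_r0`, `count_r1`, ...).
#' @return A repertoire tibble with columns `seq_id`, `cdr1`, `cdr2`,
#'   `cdr3`, one `count_r<k>` column per round, and `source`
#'   (`"ngs"` or `"sampled"`).
#' @export
read_repertoire <- function(path,
                            schema = list(seq_id = "seq_id", cdr1 = "cdr1",
                                          cdr2 = "cdr2", cdr3 = "cdr3"),
                            count_pattern = "^count_r([0-9]+)$") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- unlist(schema[c("seq_id", "cdr1", "cdr2", "cdr3")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  count_cols <- grep(count_pattern, names(raw), value = TRUE)
  if (length(count_cols) == 0) abort("no count columns found")
  df <- tibble(
    seq_id = as.character(raw[[schema$seq_id]]),
    cdr1 = toupper(as.character(raw[[schema$cdr1]])),
    cdr2 = toupper(as.character(raw[[schema$cdr2]])),
    cdr3 = toupper(as.character(raw[[schema$cdr3]]))
  )
  df$cdr1[is.na(df$cdr1)] <- ""
  df$cdr2[is.na(df$cdr2)] <- ""
  df$cdr3[is.na(df$cdr3)] <- ""
  for (cc in count_cols) {
    v <- raw[[cc]]
    if (any(is.na(suppressWarnings(as.numeric(v))))) {
      abort(sprintf("malformed count in column %s, row %d", cc,
                    which(is.na(suppressWarnings(as.numeric(v))))[1]))
    }
    df[[cc]] <- as.integer(round(as.numeric(v)))
  }
  if ("source" %in% names(raw)) {
    df$source <- as.character(raw$source)
  } else {
    df$source <- "ngs"
  }
  as_repertoire(df)
}

#' Validate and normalise a repertoire tibble
#'
#' Checks the amino-acid alphabet, non-negative counts and the presence of
#' at least one non-empty CDR per row, then merges duplicate CDR triplets by
#' summing counts. A merged row keeps the first `seq_id` and the `ngs`
#' source wins over `sampled`.
#'
#' @param df Data frame with `seq_id`, `cdr1`, `cdr2`, `cdr3`, `count_r*`
#'   columns and optionally `source`.
#' @return A validated repertoire tibble.
#' @export
as_repertoire <- function(df) {
  df <- as_tibble(df)
  if (!all(c("cdr1", "cdr2", "cdr3") %in% names(df))) {
    abort("repertoire needs cdr1/cdr2/cdr3 columns")
  }
  if (!"seq_id" %in% names(df)) df$seq_id <- sprintf("seq%05d", seq_len(nrow(df)))
  if (!"source" %in% names(df)) df$source <- "ngs"
  if (!all(df$source %in% c("ngs", "sampled"))) {
    abort("source must be 'ngs' or 'sampled'")
  }
  for (region in c("cdr1", "cdr2", "cdr3")) check_aa(df[[region]], region)
  empty <- !nzchar(df$cdr1) & !nzchar(df$cdr2) & !nzchar(df$cdr3)
  if (any(empty)) {
    abort(sprintf("row %d has no CDR sequence", which(empty)[1]))
  }
  count_cols <- grep("^count_r[0-9]+$", names(df), value = TRUE)
  if (length(count_cols) == 0) abort("no count_r<k> columns present")
  for (cc in count_cols) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) abort(sprintf("negative count in %s", cc))
    df[[cc]][is.na(df[[cc]])] <- 0L
    df[[cc]] <- as.integer(df[[cc]])
  }
  out <- df %>%
    group_by(.data$cdr1, .data$cdr2, .data$cdr3) %>%
    summarise(
      seq_id = first(.data$seq_id),
      source = if (any(.data$source == "ngs")) "ngs" else "sampled",
      across(all_of(count_cols), sum),
      .groups = "drop"
    ) %>%
    select(all_of(c("seq_id", "cdr1", "cdr2", "cdr3", count_cols, "source")))
  # keep original row order by first appearance
  key <- paste(df$cdr1, df$cdr2, df$cdr3, sep = "|")
  okey <- paste(out$cdr1, out$cdr2, out$cdr3, sep = "|")
  out[order(match(okey, unique(key))), , drop = FALSE]
}

#' Write a repertoire tibble to CSV/TSV
#'
#' Inverse of [read_repertoire()]: `read_repertoire(write_repertoire(x, p))`
#' returns `x` (after canonical merging).
#'
#' @param x Repertoire tibble.
#' @param path Output path; extension picks the delimiter.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Per-round read totals
#'
#' @param x Repertoire tibble.
#' @return Tibble with `round` (integer) and `total_reads`, satisfying the
#'   conservation invariant that each total equals the column sum of the
#'   member counts.
#' @export
repertoire_rounds <- function(x) {
  count_cols <- grep("^count_r[0-9]+$", names(x), value = TRUE)
  tibble(
    round = as.integer(sub("^count_r", "", count_cols)),
    total_reads = unname(vapply(count_cols, function(cc) sum(x[[cc]]),
                                numeric(1)))
  ) %>% arrange(.data$round)
}

#' Framework anchor set
#'
#' The four fixed framework segments flanking the CDRs of a
#' fixed-framework (humanised) VHH library. Anchors must occur exactly
#' once, in order, in any full-length sequence they are applied to.
#'
#' @param fr1,fr2,fr3,fr4 Non-empty amino-acid strings.
#' @return An object of class `framework_anchors`.
#' @export
framework_anchors <- function(fr1, fr2, fr3, fr4) {
  frs <- list(fr1 = fr1, fr2 = fr2, fr3 = fr3, fr4 = fr4)
  for (nm in names(frs)) {
    check_aa(frs[[nm]], nm, allow_empty = FALSE)
  }
  structure(frs, class = "framework_anchors")
}

#' Extract CDRs from full-length sequences by framework anchoring
#'
#' Exact substring matching against the fixed framework: CDR1 lies between
#' `fr1` and `fr2`, CDR2 between `fr2` and `fr3`, CDR3 between `fr3` and
#' `fr4`. A missing anchor or an anchor occurring more than once is an
#' error (a repeated anchor signals corrupt input in a fixed-framework
#' library, so no first-match fallback is attempted).
#'
#' @param sequences Character vector of full-length amino-acid sequences.
#' @param anchors A [framework_anchors()] object.
#' @return Tibble with columns `cdr1`, `cdr2`, `cdr3`.
#' @export
extract_cdrs <- function(sequences, anchors) {
  stopifnot(inherits(anchors, "framework_anchors"))
  check_aa(sequences, "full sequence", allow_empty = FALSE)
  one <- function(s) {
    pos <- integer(4)
    for (k in 1:4) {
      nm <- names(anchors)[k]
      hits <- gregexpr(anchors[[k]], s, fixed = TRUE)[[1]]
      if (hits[1] == -1) abort(sprintf("%s not found", nm))
      if (length(hits) > 1) abort(sprintf("ambiguous anchor %s", nm))
      pos[k] <- hits[1]
    }
    ends <- pos + vapply(anchors, nchar, integer(1)) - 1L
    if (any(diff(pos) <= 0) || any(pos[-1] <= ends[-4])) {
      bad <- names(anchors)[which(c(FALSE, pos[-1] <= ends[-4]))[1]]
      abort(sprintf("anchor %s out of order", bad))
    }
    c(substr(s, ends[1] + 1, pos[2] - 1),
      substr(s, ends[2] + 1, pos[3] - 1),
      substr(s, ends[3] + 1, pos[4] - 1))
  }
  m <- t(vapply(sequences, one, character(3)))
  tibble(cdr1 = m[, 1], cdr2 = m[, 2], cdr3 = m[, 3])
}
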