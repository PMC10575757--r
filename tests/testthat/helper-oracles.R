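# Independent oracles, deliberately written without reference to the
# package internals they check.

# Global alignment identity: match 1 / mismatch 0 / linear gap -1,
# maximising (score, matches) lexicographically; identity = matches/max len.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1); M <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  for (i in 1:n) for (j in 1:m) {
    mt <- as.integer(A[i] == B[j])
    best <- S[i, j] + mt; bm <- M[i, j] + mt
    s2 <- S[i, j + 1] - 1; m2 <- M[i, j + 1]
    if (s2 > best || (s2 == best && m2 > bm)) { best <- s2; bm <- m2 }
    s2 <- S[i + 1, j] - 1; m2 <- M[i + 1, j]
    if (s2 > best || (s2 == best && m2 > bm)) { best <- s2; bm <- m2 }
    S[i + 1, j + 1] <- best; M[i + 1, j + 1] <- bm
  }
  M[n + 1, m + 1] / max(n, m)
}

# Fine-grid scan for the isoelectric point.
oracle_pi <- function(sequence, pka = default_pka_table()) {
  ch <- strsplit(sequence, "")[[1]]
  grid <- seq(0, 14, by = 5e-4)
  charge <- rep(0, length(grid))
  pk <- stats::setNames(pka$pka, pka$group)
  sgn <- stats::setNames(pka$charge, pka$group)
  for (g in pka$group) {
    ng <- if (g %in% c("n_terminus", "c_terminus")) 1 else sum(ch == g)
    if (ng == 0) next
    if (sgn[g] == "positive") {
      charge <- charge + ng / (1 + 10^(grid - pk[g]))
    } else {
      charge <- charge - ng / (1 + 10^(pk[g] - grid))
    }
  }
  grid[which.min(abs(charge))]
}

# Exhaustive regex-based liability scan.
oracle_liabilities <- function(cdr1, cdr2, cdr3) {
  out <- list()
  for (rn in c("cdr1", "cdr2", "cdr3")) {
    s <- get(rn)
    if (!nzchar(s)) next
    ch <- strsplit(s, "")[[1]]
    for (p in seq_along(ch)) {
      nxt <- if (p < length(ch)) ch[p + 1] else ""
      di <- paste0(ch[p], nxt)
      if (ch[p] == "N") {
        sev <- if (di == "NG") "high"
        else if (di %in% c("NS", "NT", "NN", "ND", "NH")) "moderate" else "low"
        out[[length(out) + 1]] <- data.frame(
          region = rn, position = p, motif = if (nzchar(nxt)) di else "N",
          category = "deamidation", severity = sev)
        if (p + 2 <= length(ch) && ch[p + 1] != "P" &&
            ch[p + 2] %in% c("S", "T")) {
          out[[length(out) + 1]] <- data.frame(
            region = rn, position = p,
            motif = paste0(ch[p], ch[p + 1], ch[p + 2]),
            category = "glycosylation_sequon", severity = "high")
        }
      }
      if (ch[p] == "D") {
        sev <- if (di == "DG") "high"
        else if (di %in% c("DS", "DT", "DD")) "moderate" else "low"
        out[[length(out) + 1]] <- data.frame(
          region = rn, position = p, motif = if (nzchar(nxt)) di else "D",
          category = "isomerization", severity = sev)
      }
      if (ch[p] == "M") out[[length(out) + 1]] <- data.frame(
        region = rn, position = p, motif = "M",
        category = "oxidation", severity = "high")
      if (ch[p] == "C") out[[length(out) + 1]] <- data.frame(
        region = rn, position = p, motif = "C",
        category = "unpaired_cysteine", severity = "high")
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

random_aa <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(amino_acids(), len, replace = TRUE), collapse = ""),
    character(1))
}

# partition agreement: do two labellings induce the same co-membership?
same_partition <- function(a, b) {
  ca <- outer(a, a, "==")
  cb <- outer(b, b, "==")
  all(ca == cb)
}
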