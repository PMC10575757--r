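# small repertoire builders used across tests

toy_repertoire <- function() {
  tibble::tibble(
    seq_id = c("a", "b", "c", "d", "e"),
    cdr1 = c("GFTFSSYAIS", "GFTFSSYAIS", "GRTFSNYAIS", "GGTFGSYAIS", "GRTLGNYAIS"),
    cdr2 = c("SSGSNTAA", "SSGSNTAA", "RGGDNTAA", "RSGGSTAA", "WGGSRTAT"),
    cdr3 = c("VFTPTDTVVFTNKEPYNY", "VFTPTDTVVFTNKGPYNY", "VFTPTDTVVFINKEPYNY",
             "AGGMGSTTVVVSTIPYKY", "SLTYDQTTVYVSPLAYVD"),
    count_r0 = c(5L, 3L, 0L, 2L, 1L),
    count_r1 = c(9L, 4L, 2L, 8L, 1L),
    count_r2 = c(20L, 6L, 4L, 30L, 2L),
    source = "ngs"
  )
}

# a tiny trainable cluster: PWM-free, a consensus with light mutations
tiny_cluster <- function(n = 40, seed = 21) {
  set.seed(seed)
  cons <- "AGGMGSTTVVVSTIPYKY"
  aa <- amino_acids()
  cdr3 <- vapply(seq_len(n), function(i) {
    ch <- strsplit(cons, "")[[1]]
    k <- sample(length(ch), 2)
    ch[k] <- sample(aa, 2, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  tibble::tibble(
    seq_id = sprintf("t%03d", seq_len(n)),
    cdr1 = "GGTFGSYAIS", cdr2 = "RSGGSTAA", cdr3 = cdr3,
    count_r0 = 1L, count_r1 = 2L,
    count_r2 = as.integer(sample(1:20, n, replace = TRUE)),
    source = "ngs"
  )
}
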