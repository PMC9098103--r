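# In-code fixtures: tiny manifests, cohorts and tracks built fresh per test.

# manifest with n probes per chromosome at 1 kb spacing; first `n_typeI` of
# each chromosome alternate typeI_grn/typeI_red, the rest are typeII
tiny_manifest <- function(n = 20, chroms = "chr1", n_typeI = 6) {
  rows <- lapply(chroms, function(ch) {
    design <- rep("typeII", n)
    if (n_typeI > 0) {
      design[seq_len(min(n_typeI, n))] <-
        rep(c("typeI_grn", "typeI_red"), length.out = min(n_typeI, n))
    }
    data.frame(chrom = ch, pos = seq_len(n) * 1000L, design = design,
               arm = paste0(sub("chr", "", ch), "p"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  probe_manifest(sprintf("p%03d", seq_len(nrow(df))), df$chrom, df$pos,
                 df$design, df$arm)
}

# track from a list of per-sample value vectors (probe order = manifest order)
make_track <- function(manifest, values, mask = NULL) {
  m <- do.call(cbind, values)
  colnames(m) <- names(values)
  lrr_track(manifest, m, mask)
}

# minimal valid segment table row set
seg_df <- function(sample, chrom, start, end, num_mark, seg_mean,
                   state = NA_character_) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             num_mark = num_mark, seg_mean = seg_mean, state = state,
             stringsAsFactors = FALSE)
}

# random valid segment table (sorted, non-overlapping per sample/chrom)
random_segment_table <- function(n_samples = 2, n_chroms = 2, max_segs = 4) {
  rows <- list()
  for (s in paste0("S", seq_len(n_samples))) {
    for (ch in paste0("chr", seq_len(n_chroms))) {
      k <- sample(1:max_segs, 1)
      pts <- sort(sample(1e6, 2 * k))
      for (i in seq_len(k)) {
        rows[[length(rows) + 1L]] <- seg_df(
          s, ch, pts[2 * i - 1], pts[2 * i], sample(1:5000, 1),
          round(rnorm(1, 0, 0.6), 6),
          sample(c("loss", "neutral", "gain"), 1))
      }
    }
  }
  segment_table(do.call(rbind, rows))
}

write_sheet_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
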