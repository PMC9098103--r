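# Independent brute-force oracles used to check interval arithmetic and the
# recall statistic. These operate on explicit per-base integer sets and
# never call the package's interval engine.

base_sets <- function(df) {
  out <- list()
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    out[[ch]] <- union(out[[ch]], seq.int(df$start[i], df$end[i]))
  }
  out
}

# number of query intervals sharing >= 1 base with the subject set
oracle_overlap_count <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) return(0L)
  sb <- base_sets(subject)
  hits <- 0L
  for (i in seq_len(nrow(query))) {
    bases <- sb[[query$chrom[i]]]
    if (!is.null(bases) && any(seq.int(query$start[i], query$end[i]) %in% bases)) {
      hits <- hits + 1L
    }
  }
  hits
}

# disjoint merged intervals covering the union of bases of a and b
oracle_union <- function(a, b) {
  all_bases <- base_sets(rbind(a[, c("chrom", "start", "end")],
                               b[, c("chrom", "start", "end")]))
  rows <- list()
  for (ch in names(all_bases)) {
    v <- sort(all_bases[[ch]])
    run_start <- v[c(TRUE, diff(v) != 1)]
    run_end <- v[c(diff(v) != 1, TRUE)]
    rows[[ch]] <- data.frame(chrom = ch, start = run_start, end = run_end,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the recall statistic computed from base sets, mirroring its definition
oracle_recall <- function(calls, n_ref, t_ref, mode) {
  neutral <- calls[calls$state %in% c("neutral", "2"), , drop = FALSE]
  nonneutral <- calls[!calls$state %in% c("neutral", "2"), , drop = FALSE]
  if (mode == "state_matched") {
    on <- oracle_overlap_count(n_ref, neutral)
    ot <- oracle_overlap_count(t_ref, nonneutral)
  } else {
    on <- oracle_overlap_count(n_ref, calls)
    ot <- oracle_overlap_count(t_ref, calls)
  }
  ont <- oracle_overlap_count(t_ref, n_ref)
  tr <- nrow(oracle_union(n_ref, t_ref))
  list(ON = on, OT = ot, ONT = ont, TR = tr,
       recall = min(1, max(0, (on + (ot - ont)) / tr)))
}

# random non-overlapping sorted interval set on small coordinates
random_interval_set <- function(n_max = 5, max_coord = 10000,
                                chroms = c("chr1", "chr2")) {
  rows <- list()
  for (ch in chroms) {
    n <- sample(0:n_max, 1)
    if (n == 0) next
    pts <- sort(sample(max_coord, 2 * n))
    rows[[ch]] <- data.frame(chrom = ch,
                             start = pts[seq(1, 2 * n, 2)],
                             end = pts[seq(2, 2 * n, 2)],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
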