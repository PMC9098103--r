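# Overlap-based recall benchmark against gold-standard segment sets, plus
# the large-scale-event reference-sample classifier.

#' Construct a reference set
#'
#' Gold-standard normal (N) and tumor (T) interval collections for
#' benchmarking. N and T may mutually overlap; the ONT term of the recall
#' statistic accounts for that.
#'
#' @param normal,tumor Data frames with `chrom`, `start`, `end` columns
#'   (1-based closed intervals).
#' @param provenance Free-text origin of the reference.
#' @return Object of class `reference_set` with elements `N` and `T`.
#' @export
reference_set <- function(normal, tumor, provenance = "") {
  check <- function(df, nm) {
    if (nrow(df) && any(df$start > df$end)) {
      stop("malformed interval in ", nm, ": start > end")
    }
    df[, c("chrom", "start", "end"), drop = FALSE]
  }
  structure(list(N = check(normal, "N"), T = check(tumor, "T"),
                 provenance = provenance),
            class = "reference_set")
}

#' Build a per-sample reference set from a gold-standard table
#'
#' N is the sample's neutral gold segments; T its non-neutral segments.
#'
#' @param gold A state-called [segment_table()] gold standard.
#' @param sample Sample name.
#' @return A [reference_set()].
#' @export
reference_from_gold <- function(gold, sample) {
  sub <- as.data.frame(gold)[as.data.frame(gold)$sample == sample, , drop = FALSE]
  if (nrow(sub) == 0) stop("sample ", sample, " absent from gold standard")
  reference_set(sub[is_neutral_state(sub$state), , drop = FALSE],
                sub[!is_neutral_state(sub$state), , drop = FALSE],
                provenance = paste0("gold:", sample))
}

#' Count query intervals overlapping any subject interval
#'
#' Overlap means at least one shared base on the same chromosome; both sides
#' use 1-based closed coordinates, and each query interval is counted at
#' most once.
#'
#' @param query,subject Data frames with `chrom`, `start`, `end`.
#' @return Integer count.
#' @export
count_overlaps_any <- function(query, subject) {
  if (nrow(query) && any(query$start > query$end)) stop("malformed query interval")
  if (nrow(subject) && any(subject$start > subject$end)) stop("malformed subject interval")
  if (nrow(query) == 0 || nrow(subject) == 0) return(0L)
  q <- intervals_to_granges(query)
  s <- intervals_to_granges(subject)
  sum(suppressWarnings(GenomicRanges::countOverlaps(q, s)) > 0)
}

#' Union of two interval collections as disjoint merged intervals
#'
#' Returns the minimal set of disjoint intervals covering exactly the union
#' of bases; abutting closed intervals (e.g. 100-200 and 201-300) merge.
#'
#' @param a,b Data frames with `chrom`, `start`, `end`.
#' @return Data frame of merged disjoint intervals.
#' @export
range_union <- function(a, b) {
  gr <- suppressWarnings(c(intervals_to_granges(a), intervals_to_granges(b)))
  granges_to_intervals(GenomicRanges::reduce(gr))
}

#' Recall of a call set against a gold-standard reference
#'
#' The recall statistic is
#' `R = (ON + (OT - ONT)) / TR`, where ON is the number of normal-reference
#' segments overlapping calls (the true negatives), OT the number of
#' tumor-reference segments overlapping calls, ONT the number of
#' tumor-reference segments overlapping the normal reference (subtracted
#' because true negatives are prioritized over true positives), and TR the
#' number of merged intervals in the union of N and T. In `state_matched`
#' mode ON counts overlaps with neutral-state calls only and OT with
#' non-neutral calls only; `literal` mode matches any call on both sides.
#' R is clamped to [0, 1], with a warning when `OT - ONT < 0`.
#'
#' @param calls A state-called [segment_table()].
#' @param ref A [reference_set()].
#' @param mode `"state_matched"` (default) or `"literal"`.
#' @return Object of class `recall_result` with fields `ON, OT, ONT, TR,
#'   recall, mode`.
#' @export
compute_recall <- function(calls, ref, mode = c("state_matched", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "reference_set"))
  df <- as.data.frame(calls)
  tr_iv <- range_union(ref$N, ref$T)
  tr <- nrow(tr_iv)
  if (tr == 0) stop("empty reference: TR = 0")
  if (mode == "state_matched") {
    if (nrow(df) && any(is.na(df$state))) {
      stop("state_matched recall requires state-called segments")
    }
    calls_for_on <- df[is_neutral_state(df$state), , drop = FALSE]
    calls_for_ot <- df[!is_neutral_state(df$state), , drop = FALSE]
  } else {
    calls_for_on <- df
    calls_for_ot <- df
  }
  on <- count_overlaps_any(ref$N, calls_for_on)
  ot <- count_overlaps_any(ref$T, calls_for_ot)
  ont <- count_overlaps_any(ref$T, ref$N)
  if (ot - ont < 0) {
    warning("OT - ONT is negative (", ot - ont, "); recall clamped to [0, 1]")
  }
  recall <- min(1, max(0, (on + (ot - ont)) / tr))
  structure(list(ON = as.integer(on), OT = as.integer(ot),
                 ONT = as.integer(ont), TR = as.integer(tr),
                 recall = recall, mode = mode),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("recall: %g (mode %s; ON %d, OT %d, ONT %d, TR %d)\n",
              x$recall, x$mode, x$ON, x$OT, x$ONT, x$TR))
  invisible(x)
}

#' Classify reference samples by large-scale events on required arms
#'
#' Mirrors the labelling used to split a cohort into tumor-reference and
#' normal-reference samples when no adjacent-normal gold standard exists:
#' each segment gets copy state 1 if its mean is <= -0.2, 3 if >= 0.2, else
#' 2, and belongs to the arm containing its midpoint. A sample is
#' `tumor_ref` when every required arm harbors a state-1 segment with more
#' than `mark_min` marks (a large-scale event); `normal_ref` when every
#' required arm instead has such a large state-2 segment and no qualifying
#' state-1 segment exists on the required arms; otherwise `unclassified`.
#'
#' @param gold A [segment_table()] with mean LRR and mark counts.
#' @param arm_bounds Data frame of arm boundaries (`chrom, arm, start, end`),
#'   e.g. the `"arms"` attribute of a synthetic manifest.
#' @param required_arms Arms that must all carry the event; default
#'   `c("1p", "19q")`, the oligodendroglioma codeletion.
#' @param mark_min Large-scale-event threshold on `num_mark`; default 10000.
#' @return Data frame with columns `sample` and `label`.
#' @export
classify_reference_samples <- function(gold, arm_bounds,
                                       required_arms = c("1p", "19q"),
                                       mark_min = 10000) {
  missing <- setdiff(required_arms, arm_bounds$arm)
  if (length(missing)) {
    stop("arm(s) not in manifest: ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(gold)
  mid <- (df$start + df$end) %/% 2 + (df$start + df$end) %% 2  # midpoint (ceil)
  df$arm_label <- NA_character_
  for (i in seq_len(nrow(arm_bounds))) {
    hit <- df$chrom == arm_bounds$chrom[i] & mid >= arm_bounds$start[i] &
      mid <= arm_bounds$end[i]
    df$arm_label[hit] <- arm_bounds$arm[i]
  }
  df$cn <- ifelse(df$seg_mean <= -0.2, 1L, ifelse(df$seg_mean >= 0.2, 3L, 2L))
  labels <- vapply(unique(df$sample), function(s) {
    sub <- df[df$sample == s & df$arm_label %in% required_arms, , drop = FALSE]
    big <- sub[sub$num_mark > mark_min, , drop = FALSE]
    del_arms <- unique(big$arm_label[big$cn == 1L])
    neu_arms <- unique(big$arm_label[big$cn == 2L])
    if (all(required_arms %in% del_arms)) {
      "tumor_ref"
    } else if (all(required_arms %in% neu_arms) && length(del_arms) == 0) {
      "normal_ref"
    } else {
      "unclassified"
    }
  }, character(1))
  data.frame(sample = unique(df$sample), label = unname(labels),
             stringsAsFactors = FALSE)
}
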