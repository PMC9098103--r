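# Circular binary segmentation of per-sample LRR tracks, plus the exhaustive
# brute-force segmenter used as a test oracle.

#' Circular binary segmentation parameters
#'
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Number of permutations per split test (>= 100).
#' @param min_width Minimum probes per segment (>= 2).
#' @param undo_sd Merge adjacent segments whose means differ by less than
#'   `undo_sd` times the residual SD.
#' @param seed RNG seed for the permutation stream; fixes the output.
#' @return A validated list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, nperm = 1000, min_width = 2,
                       undo_sd = 1.0, seed = 42L) {
  p <- list(alpha = alpha, nperm = as.integer(nperm),
            min_width = as.integer(min_width), undo_sd = undo_sd,
            seed = as.integer(seed))
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must be in (0, 1)")
  if (p$nperm < 100) stop("nperm must be >= 100")
  if (p$min_width < 2) stop("min_width must be >= 2")
  class(p) <- "cbs_params"
  p
}

# Recursive changepoint search on one vector; returns sorted breakpoint
# indices b meaning a boundary between positions b and b+1.
cbs_recurse <- function(x, params) {
  n <- length(x)
  if (n < 2 * params$min_width) return(integer(0))
  if (sd(x) < 1e-12) return(integer(0))
  sc <- cbs_scan(x, params$min_width)
  if (sc$i < 0) return(integer(0))
  perm <- cbs_perm_max(x, params$nperm, params$min_width)
  thr <- quantile(perm, 1 - params$alpha, names = FALSE, type = 1)
  if (!(sc$stat > thr)) return(integer(0))
  i <- sc$i; j <- sc$j
  bps <- c(if (i > 0) i, if (j < n) j)
  pieces <- rbind(c(1, i), c(i + 1, j), c(j + 1, n))
  sub <- integer(0)
  for (r in seq_len(nrow(pieces))) {
    a <- pieces[r, 1]; b <- pieces[r, 2]
    if (b >= a) sub <- c(sub, a - 1L + cbs_recurse(x[a:b], params))
  }
  sort(unique(c(as.integer(bps), sub)))
}

# Undo: merge adjacent segments whose mean difference is below
# undo_sd * residual SD (residual SD fixed from the initial fit).
cbs_undo <- function(x, bps, undo_sd) {
  if (length(bps) == 0) return(bps)
  seg_means_of <- function(bps) {
    bounds <- c(0L, bps, length(x))
    vapply(seq_len(length(bounds) - 1L), function(k) {
      mean(x[(bounds[k] + 1L):bounds[k + 1L]])
    }, numeric(1))
  }
  fitted <- function(bps) {
    bounds <- c(0L, bps, length(x))
    m <- seg_means_of(bps)
    rep(m, diff(bounds))
  }
  rsd <- sd(x - fitted(bps))
  if (!is.finite(rsd)) rsd <- 0
  repeat {
    if (length(bps) == 0) break
    m <- seg_means_of(bps)
    diffs <- abs(diff(m))
    k <- which.min(diffs)
    if (diffs[k] < undo_sd * rsd) bps <- bps[-k] else break
  }
  bps
}

#' Segment LRR tracks by circular binary segmentation
#'
#' Per sample and chromosome, recursively finds the circular arc maximizing
#' a two-sample t-like contrast between in-arc and out-of-arc values,
#' accepts the split when the observed statistic exceeds the
#' `(1 - alpha)` quantile of `nperm` permutation maxima, recurses on the
#' resulting pieces, then merges adjacent segments whose means differ by
#' less than `undo_sd` times the residual SD. Emitted segments tile all
#' unmasked probes; coordinates are the positions of the first and last
#' member probes.
#'
#' @param track An `lrr_track`.
#' @param params A [cbs_params()].
#' @param center If `TRUE`, subtract each sample's median LRR before
#'   segmentation (used by the z-score route; off by default — baseline
#'   handling belongs to the autocorrection stage).
#' @return A [segment_table()] with `state = NA` (call states separately).
#' @export
cbs_segment <- function(track, params = cbs_params(), center = FALSE) {
  manifest <- track$manifest
  chroms <- unique(manifest$chrom)
  samples <- colnames(track$values)
  rows <- list()
  with_local_seed(params$seed, {
    for (s in samples) {
      vals <- track$values[, s]
      if (center) {
        use_all <- !track$mask[, s]
        vals[use_all] <- vals[use_all] - median(vals[use_all])
      }
      for (ch in chroms) {
        on_chrom <- manifest$chrom == ch & !track$mask[, s]
        if (!any(on_chrom)) next
        ord <- order(manifest$pos[on_chrom])
        pos <- manifest$pos[on_chrom][ord]
        x <- vals[on_chrom][ord]
        if (any(!is.finite(x))) stop("non-finite unmasked values in sample ", s)
        bps <- if (length(x) >= 2 * params$min_width) {
          cbs_undo(x, cbs_recurse(x, params), params$undo_sd)
        } else {
          integer(0)
        }
        bounds <- c(0L, bps, length(x))
        for (k in seq_len(length(bounds) - 1L)) {
          idx <- (bounds[k] + 1L):bounds[k + 1L]
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, chrom = ch,
            start = pos[idx[1]], end = pos[idx[length(idx)]],
            num_mark = length(idx), seg_mean = mean(x[idx]),
            state = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  })
  segment_table(if (length(rows)) do.call(rbind, rows) else data.frame(),
                routine = "cbs",
                params = unclass(params))
}

#' Exhaustive minimum-RSS segmentation (test oracle)
#'
#' Enumerates every placement of up to `max_segments - 1` breakpoints per
#' sample and chromosome and returns the placement minimizing the residual
#' sum of squares, preferring fewer segments on (near-)ties. Exponential in
#' cost; refuses chromosomes with more than 60 probes. Used only as an
#' independent oracle in tests.
#'
#' @param track An `lrr_track`.
#' @param max_segments Maximum number of segments per chromosome.
#' @return A [segment_table()] with `state = NA`.
#' @export
brute_force_segment <- function(track, max_segments = 3) {
  manifest <- track$manifest
  rows <- list()
  for (s in colnames(track$values)) {
    for (ch in unique(manifest$chrom)) {
      on_chrom <- manifest$chrom == ch & !track$mask[, s]
      if (!any(on_chrom)) next
      ord <- order(manifest$pos[on_chrom])
      pos <- manifest$pos[on_chrom][ord]
      x <- track$values[on_chrom, s][ord]
      n <- length(x)
      if (n > 60) stop("brute_force_segment is limited to <= 60 probes per chromosome")
      best_rss <- Inf; best_bps <- integer(0)
      rss_of <- function(bps) {
        bounds <- c(0L, bps, n)
        sum(vapply(seq_len(length(bounds) - 1L), function(k) {
          seg <- x[(bounds[k] + 1L):bounds[k + 1L]]
          sum((seg - mean(seg))^2)
        }, numeric(1)))
      }
      for (nb in 0:(max_segments - 1L)) {
        if (nb > n - 1L) break
        combos <- if (nb == 0) list(integer(0)) else {
          asplit(combn(n - 1L, nb), 2)
        }
        for (bps in combos) {
          r <- rss_of(as.integer(bps))
          if (r < best_rss - 1e-10) {  # prefer fewer segments on ties
            best_rss <- r
            best_bps <- as.integer(bps)
          }
        }
      }
      bounds <- c(0L, best_bps, n)
      for (k in seq_len(length(bounds) - 1L)) {
        idx <- (bounds[k] + 1L):bounds[k + 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = ch,
          start = pos[idx[1]], end = pos[idx[length(idx)]],
          num_mark = length(idx), seg_mean = mean(x[idx]),
          state = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  segment_table(if (length(rows)) do.call(rbind, rows) else data.frame(),
                routine = "brute_force")
}
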