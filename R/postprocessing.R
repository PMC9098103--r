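# Postprocessing: density-peak baseline autocorrection, copy-state calling
# (threshold and formula modes), and cross-sample consensus regions.

#' State-calling parameters
#'
#' @param mode `"threshold"` (LRR cuts) or `"formula"`
#'   (`state = round(2^seg_mean * 2)`, an integer copy number).
#' @param loss_cut,gain_cut LRR thresholds (log2 units). A segment is a loss
#'   when `seg_mean <= loss_cut` and a gain when `seg_mean >= gain_cut`;
#'   in-between is neutral. Defaults are the liberal -0.2 / +0.2 cuts.
#' @return A validated list of class `state_call_params`.
#' @export
state_call_params <- function(mode = c("threshold", "formula"),
                              loss_cut = -0.2, gain_cut = 0.2) {
  mode <- match.arg(mode)
  if (loss_cut >= gain_cut) stop("loss_cut must be < gain_cut")
  structure(list(mode = mode, loss_cut = loss_cut, gain_cut = gain_cut),
            class = "state_call_params")
}

# Weighted quantile (type-1 style: first value whose cumulative weight
# reaches q).
weighted_quantile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= q)[1]]
}

# Mode of the mark-weighted Gaussian KDE of segment means. Bandwidth is
# Silverman's rule with weighted moments and effective sample size; the
# evaluation grid has 2048 points spanning [min - 0.5, max + 0.5] so the
# grid shifts exactly with the data (shift-equivariance is exact). Ties
# between equal-height peaks break toward the peak nearest 0.
weighted_density_peak <- function(x, w) {
  if (length(x) == 1 || diff(range(x)) < 1e-12) return(x[1])
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(sum(w * (x - mu)^2))
  iqrw <- weighted_quantile(x, w, 0.75) - weighted_quantile(x, w, 0.25)
  sig <- min(sdw, iqrw / 1.34)
  if (!is.finite(sig) || sig <= 0) sig <- sdw
  if (!is.finite(sig) || sig <= 0) return(x[which.max(w)])
  n_eff <- 1 / sum(w^2)
  bw <- 0.9 * sig * n_eff^(-1 / 5)
  grid <- seq(min(x) - 0.5, max(x) + 0.5, length.out = 2048)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  peak_idx <- which(dens >= max(dens) * (1 - 1e-12))
  grid[peak_idx][which.min(abs(grid[peak_idx]))]
}

#' Re-baseline segment means by their density peak
#'
#' Per sample, estimates the mark-weighted Gaussian kernel density of the
#' segment means, locates its highest peak — the modal, presumed
#' copy-neutral level — and subtracts the peak location from every segment
#' mean of that sample, so the neutral level sits at 0. Coordinates and
#' mark counts are unchanged. The correction is idempotent and equivariant
#' under shifts of a sample's means (up to KDE grid resolution).
#'
#' @param table A [segment_table()] (at least one segment per sample).
#' @param weighted Weight the density by `num_mark` (default) or treat all
#'   segments equally.
#' @return The corrected [segment_table()]; per-sample offsets are stored in
#'   the `"offsets"` attribute.
#' @export
autocorrect_baseline <- function(table, weighted = TRUE) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("autocorrect_baseline needs at least one segment")
  offsets <- numeric(0)
  for (s in unique(df$sample)) {
    rows <- df$sample == s
    x <- df$seg_mean[rows]
    w <- if (weighted) as.numeric(df$num_mark[rows]) else rep(1, sum(rows))
    if (length(x) == 1) {
      warning("sample ", s, " has a single segment; centering it to 0")
      off <- x
    } else {
      off <- weighted_density_peak(x, w)
    }
    df$seg_mean[rows] <- x - off
    offsets[s] <- off
  }
  out <- segment_table(df, routine = attr(table, "routine"),
                       params = attr(table, "params"))
  attr(out, "offsets") <- offsets
  out
}

#' Assign copy states to segments
#'
#' Threshold mode labels `loss` / `neutral` / `gain` from the LRR cuts
#' (boundaries inclusive: `<= loss_cut` is loss, `>= gain_cut` is gain).
#' Formula mode assigns the integer copy number
#' `round(2^seg_mean * 2)` with half-up rounding, stored as character
#' (e.g. a seg_mean of 0 gives `"2"`).
#'
#' @param table A [segment_table()].
#' @param params A [state_call_params()].
#' @return The table with its `state` column filled.
#' @export
call_states <- function(table, params = state_call_params()) {
  df <- as.data.frame(table)
  if (nrow(df) && any(!is.finite(df$seg_mean))) stop("seg_mean must be finite")
  if (params$mode == "threshold") {
    df$state <- ifelse(df$seg_mean <= params$loss_cut, "loss",
                       ifelse(df$seg_mean >= params$gain_cut, "gain", "neutral"))
  } else {
    df$state <- as.character(as.integer(floor(2^df$seg_mean * 2 + 0.5)))
  }
  segment_table(df, routine = attr(table, "routine"),
                params = c(attr(table, "params"), unclass(params)))
}

is_neutral_state <- function(state) state %in% c("neutral", "2")

# Union-find connected components of the reciprocal-overlap graph.
reciprocal_clusters <- function(iv, rho) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      ov <- min(iv$end[a], iv$end[b]) - max(iv$start[a], iv$start[b]) + 1
      if (ov <= 0) next
      la <- iv$end[a] - iv$start[a] + 1
      lb <- iv$end[b] - iv$start[b] + 1
      if (ov >= rho * la && ov >= rho * lb) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cross-sample consensus regions of recurrent CNV calls
#'
#' Gains and losses form separate pools. Within each pool and chromosome,
#' calls are clustered by single linkage on reciprocal overlap (two calls
#' are linked when their shared length is at least `rho` times the length
#' of each). Within each cluster's extent, maximal subregions where the
#' fraction of cohort samples covering every base is at least `density` are
#' emitted. With `est_recur`, a region is flagged recurrent when its support
#' beats a one-sided binomial test at 0.05 against the genome-wide
#' background rate (the fraction of each sample's covered extent that is
#' non-neutral, averaged over samples).
#'
#' @param tables List of state-called [segment_table()]s (one per sample, or
#'   tables holding several samples).
#' @param density Minimum supporting fraction of the cohort, in (0, 1].
#' @param rho Reciprocal-overlap fraction for clustering, in (0, 1].
#' @param est_recur Flag regions as recurrent by the binomial test.
#' @return Data frame with columns `chrom, start, end, state, n_support,
#'   support_frac, recurrent`.
#' @export
consensus_regions <- function(tables, density = 0.1, rho = 0.5,
                              est_recur = TRUE) {
  if (density <= 0 || density > 1 || rho <= 0 || rho > 1) {
    stop("density and rho must be in (0, 1]")
  }
  if (inherits(tables, "segment_table")) tables <- list(tables)
  calls <- do.call(rbind, lapply(tables, as.data.frame))
  if (is.null(calls) || nrow(calls) == 0) stop("consensus needs segment calls")
  if (any(is.na(calls$state))) stop("tables must be state-called first")
  samples <- unique(calls$sample)
  n_cohort <- length(samples)
  if (n_cohort < 2) stop("consensus needs at least 2 samples")
  k_min <- ceiling(density * n_cohort)

  # background rate for the recurrence test
  bg <- mean(vapply(samples, function(s) {
    sub <- calls[calls$sample == s, , drop = FALSE]
    covered <- sum(GenomicRanges::width(GenomicRanges::reduce(intervals_to_granges(sub))))
    nn <- sub[!is_neutral_state(sub$state), , drop = FALSE]
    nn_cov <- if (nrow(nn)) {
      sum(GenomicRanges::width(GenomicRanges::reduce(intervals_to_granges(nn))))
    } else 0
    if (covered == 0) 0 else nn_cov / covered
  }, numeric(1)))

  out <- list()
  nonneutral <- calls[!is_neutral_state(calls$state), , drop = FALSE]
  cn_num <- suppressWarnings(as.numeric(nonneutral$state))
  nonneutral$pool <- ifelse(nonneutral$state == "loss", "loss",
                            ifelse(nonneutral$state == "gain", "gain",
                                   ifelse(!is.na(cn_num) & cn_num < 2,
                                          "loss", "gain")))
  for (pool in unique(nonneutral$pool)) {
    pc <- nonneutral[nonneutral$pool == pool, , drop = FALSE]
    for (ch in unique(pc$chrom)) {
      iv <- pc[pc$chrom == ch, , drop = FALSE]
      cl <- reciprocal_clusters(iv, rho)
      for (g in unique(cl)) {
        members <- iv[cl == g, , drop = FALSE]
        # one reduced range set per sample, so coverage counts samples
        per_sample <- lapply(unique(members$sample), function(s) {
          IRanges::reduce(IRanges::IRanges(
            start = members$start[members$sample == s],
            end = members$end[members$sample == s]))
        })
        cvg <- IRanges::coverage(do.call(c, per_sample))
        views <- IRanges::slice(cvg, lower = k_min)
        if (length(views) == 0) next
        n_sup <- IRanges::viewMins(views)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = IRanges::start(views), end = IRanges::end(views),
          state = pool, n_support = as.integer(n_sup),
          support_frac = as.integer(n_sup) / n_cohort,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      state = character(), n_support = integer(),
                      support_frac = numeric(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$recurrent <- if (est_recur) {
    pbinom(res$n_support - 1, n_cohort, bg, lower.tail = FALSE) < 0.05
  } else {
    NA
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "background_rate") <- bg
  attr(res, "recurrence_test") <- "one-sided binomial vs genome-wide background (package-defined)"
  res
}
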