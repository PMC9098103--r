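# Preprocessing: background correction from out-of-band fluorescence,
# dye-bias correction, detection-p masking, reference construction, and the
# LRR / z-score computations.

#' Construct an LRR track
#'
#' @param manifest A [probe_manifest()].
#' @param values Numeric matrix (probe x sample) of log2 ratios.
#' @param mask Logical matrix; `TRUE` = excluded.
#' @param route Provenance: `"standard"` or `"zscore"`.
#' @param reference_mode Provenance: how the reference was built.
#' @return Object of class `lrr_track`.
#' @export
lrr_track <- function(manifest, values, mask = NULL,
                      route = "standard", reference_mode = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(manifest)) stop("values must have one row per probe")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values))) stop("mask dimensions differ")
  if (any(!is.finite(values[!mask]))) stop("unmasked LRR values must be finite")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  dimnames(mask) <- list(manifest$probe_id, colnames(values))
  rownames(values) <- manifest$probe_id
  structure(list(manifest = manifest, values = values, mask = mask,
                 route = route, reference_mode = reference_mode),
            class = "lrr_track")
}

# Per-sample out-of-band background pool: unmasked oob entries of type I
# probes (their opposite channel carries no target signal, only background).
oob_pool <- function(cohort, s) {
  typeI <- cohort$manifest$design %in% c("typeI_grn", "typeI_red")
  v <- cohort$oob[typeI, s]
  v[!cohort$mask[typeI, s] & is.finite(v)]
}

#' Background-correct a cohort using out-of-band fluorescence
#'
#' A simplified noob-style correction: the per-sample background level is
#' estimated as the median of that sample's out-of-band pool and subtracted
#' from both in-band channels, floored at zero. The subtraction is monotone
#' per channel, so in-band signal ordering is preserved.
#'
#' @param cohort An [intensity_cohort()].
#' @return The corrected cohort.
#' @export
background_correct <- function(cohort) {
  for (s in cohort$sample_names) {
    pool <- oob_pool(cohort, s)
    if (length(pool) == 0 || all(pool == 0)) {
      warning("no out-of-band signal for sample ", s,
              "; channels passed through")
      next
    }
    b <- median(pool)
    cohort$meth[, s] <- pmax(cohort$meth[, s] - b, 0)
    cohort$unmeth[, s] <- pmax(cohort$unmeth[, s] - b, 0)
  }
  cohort
}

#' Correct red/green dye bias by quantile matching
#'
#' Per sample, the red (unmethylated) channel's empirical distribution over
#' unmasked type II probes is mapped onto the green (methylated) channel's
#' distribution by monotone interpolation between sorted quantiles; the
#' green channel is unchanged. With fewer than 100 unmasked type II probes
#' the map degenerates, so the red channel is rescaled by the median
#' green/red ratio instead (with a warning). Rank order within the red
#' channel is never changed.
#'
#' @param cohort An [intensity_cohort()].
#' @return The corrected cohort.
#' @export
dye_bias_correct <- function(cohort) {
  typeII <- cohort$manifest$design == "typeII"
  for (s in cohort$sample_names) {
    use <- typeII & !cohort$mask[, s]
    red <- cohort$unmeth[use, s]
    grn <- cohort$meth[use, s]
    if (sum(use) < 100) {
      warning("fewer than 100 unmasked type II probes for sample ", s,
              "; falling back to median-ratio scaling")
      ratio <- median(grn) / median(red)
      if (!is.finite(ratio) || ratio <= 0) ratio <- 1
      cohort$unmeth[, s] <- cohort$unmeth[, s] * ratio
      next
    }
    sr <- sort(red); sg <- sort(grn)
    cohort$unmeth[, s] <- stats::approx(sr, sg, xout = cohort$unmeth[, s],
                                        rule = 2, ties = "ordered")$y
  }
  cohort
}

#' Mask probes by empirical detection p-value
#'
#' A simplified pOOBAH-style detection test: for each probe and sample the
#' detection p-value is the fraction of that sample's out-of-band background
#' pool at or above the probe's total in-band intensity (the empirical
#' survival function). Entries with p above `p_threshold` are masked;
#' previously masked entries stay masked.
#'
#' @param cohort An [intensity_cohort()].
#' @param p_threshold Detection p-value cutoff in (0, 1); default 0.05.
#' @return The cohort with an updated mask.
#' @export
mask_probes <- function(cohort, p_threshold = 0.05) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  for (s in cohort$sample_names) {
    pool <- sort(oob_pool(cohort, s))
    if (length(pool) == 0 || all(pool == 0)) {
      warning("empty out-of-band pool for sample ", s, "; no masking applied")
      next
    }
    tot <- cohort$meth[, s] + cohort$unmeth[, s]
    n_below <- findInterval(tot, pool, left.open = TRUE)  # pool values < tot
    p <- (length(pool) - n_below) / length(pool)
    cohort$mask[, s] <- cohort$mask[, s] | (p > p_threshold)
  }
  cohort
}

#' Build a per-probe reference intensity vector
#'
#' @param cohort An [intensity_cohort()].
#' @param sheet The [read_sample_sheet()] sheet matching the cohort.
#' @param mode Reference construction mode: `"median_controls"` (per-probe
#'   median total intensity over control samples), `"pooled_controls"`
#'   (per-probe mean over controls), `"cohort_median"` (median over all
#'   samples, controls not required), or `"matched_normal"` (per-sample
#'   reference from the sheet's `matched_normal` column; returns a matrix).
#' @return Numeric vector of per-probe reference intensities (or a
#'   probe x sample matrix for `matched_normal`). Probes whose reference is
#'   zero or not computable are reported via the `"zero_reference"`
#'   attribute and should be masked cohort-wide (done by [compute_lrr()]).
#' @export
build_reference <- function(cohort, sheet,
                            mode = c("median_controls", "pooled_controls",
                                     "cohort_median", "matched_normal")) {
  mode <- match.arg(mode)
  tot <- total_intensity(cohort)
  controls <- sheet$sample_name[sheet$group == "control"]
  controls <- intersect(controls, cohort$sample_names)
  if (mode %in% c("median_controls", "pooled_controls") && length(controls) < 1) {
    stop("reference mode ", mode, " requires at least one control sample")
  }
  i_r <- switch(mode,
    median_controls = apply(tot[, controls, drop = FALSE], 1, median, na.rm = TRUE),
    pooled_controls = rowMeans(tot[, controls, drop = FALSE], na.rm = TRUE),
    cohort_median = apply(tot, 1, median, na.rm = TRUE),
    matched_normal = {
      if (!"matched_normal" %in% names(sheet)) {
        stop("matched_normal mode requires a matched_normal sample-sheet column")
      }
      ref <- matrix(NA_real_, nrow(tot), ncol(tot),
                    dimnames = dimnames(tot))
      for (s in cohort$sample_names) {
        row <- sheet[sheet$sample_name == s, , drop = FALSE]
        mn <- row$matched_normal[1]
        if (is.na(mn) || mn == "" || !mn %in% cohort$sample_names) mn <- s
        ref[, s] <- tot[, mn]
      }
      ref
    })
  i_r[is.na(i_r)] <- 0
  attr(i_r, "zero_reference") <- if (is.matrix(i_r)) {
    rowSums(i_r == 0) > 0
  } else {
    i_r == 0
  }
  attr(i_r, "mode") <- mode
  i_r
}

#' Compute the log R ratio track
#'
#' `LRR = log2(I_T / I_R)` where `I_T` is the total (methylated +
#' unmethylated) in-band intensity of the test sample and `I_R` the
#' reference intensity from [build_reference()]. Probes with `I_T = 0` are
#' masked per sample; probes with `I_R = 0` are masked cohort-wide.
#'
#' @param cohort An [intensity_cohort()].
#' @param i_r Per-probe reference vector (or matrix) from [build_reference()].
#' @return An `lrr_track`.
#' @export
compute_lrr <- function(cohort, i_r) {
  tot <- total_intensity(cohort)
  ref <- if (is.matrix(i_r)) i_r else matrix(i_r, nrow(tot), ncol(tot))
  zero_ref <- attr(i_r, "zero_reference") %||% (if (is.matrix(i_r))
    rowSums(ref == 0) > 0 else as.vector(ref == 0))
  mask <- cohort$mask | is.na(tot) | tot == 0 | matrix(zero_ref, nrow(tot), ncol(tot))
  values <- matrix(0, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  ok <- !mask
  values[ok] <- log2(tot[ok] / ref[ok])
  lrr_track(cohort$manifest, values, mask, route = "standard",
            reference_mode = attr(i_r, "mode") %||% NA_character_)
}

#' Z-transform a track per sample
#'
#' Per sample, unmasked values are centred by their mean and scaled by their
#' sample (n-1) standard deviation, so each sample has mean 0 and SD 1.
#' Affine transforms of a sample's values leave its z-scores unchanged.
#'
#' @param track An `lrr_track` (or any matrix-bearing track).
#' @return The transformed track with `route = "zscore"`.
#' @export
zscore_transform <- function(track) {
  for (s in colnames(track$values)) {
    use <- !track$mask[, s]
    if (sum(use) < 2) stop("sample ", s, " has fewer than 2 unmasked values")
    x <- track$values[use, s]
    sdev <- sd(x)
    if (!is.finite(sdev) || sdev == 0) {
      stop("sample ", s, " has zero within-sample SD; cannot z-transform")
    }
    track$values[use, s] <- (x - mean(x)) / sdev
  }
  track$route <- "zscore"
  track
}
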