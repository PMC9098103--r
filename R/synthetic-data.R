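# Synthetic cohorts with implanted copy-number truth. The generator stands in
# for array IDAT content: it emits two-channel intensities whose expected
# total at probe p, sample s is baseline_p * (CN/2) * dye/noise factors, plus
# a matching SNP6-style gold-standard segment table.

#' Default synthetic chromosome layout
#'
#' Three 100-Mb chromosomes (chr1, chr3, chr19) with the centromere at 50 Mb,
#' so each p arm spans bases 1..50e6 and each q arm 50e6+1..100e6. These are
#' synthetic constants, not real cytobands: only arm-level semantics matter
#' to arm-scale CNV calling.
#'
#' @return Data frame with columns `chrom`, `length`, `centromere`.
#' @export
default_chroms <- function() {
  data.frame(
    chrom = c("chr1", "chr3", "chr19"),
    length = rep(100e6, 3),
    centromere = rep(50e6, 3),
    stringsAsFactors = FALSE
  )
}

arm_table <- function(chroms) {
  do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$chrom[i]
    num <- sub("^chr", "", ch)
    data.frame(
      chrom = ch,
      arm = paste0(num, c("p", "q")),
      start = c(1, chroms$centromere[i] + 1),
      end = c(chroms$centromere[i], chroms$length[i]),
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulation configuration
#'
#' @param n_tumor,n_control Sample counts (each >= 1).
#' @param probes_per_chrom Probes per chromosome, evenly spaced.
#' @param chroms Chromosome layout as from [default_chroms()].
#' @param baseline_log_intensity Named vector `c(mean=, sd=)` of the per-probe
#'   log-scale baseline intensity (natural-log lognormal parameters). The
#'   baseline is drawn once per manifest and shared across samples.
#' @param noise_sd Per-observation log2 noise SD. The default 0.25 makes
#'   segment detection nontrivial but reliable.
#' @param dye_bias Multiplicative factor applied to the red (unmethylated)
#'   channel, exercising dye-bias correction.
#' @param baseline_offset Additive LRR offset (log2 units) applied to all
#'   tumor samples, exercising baseline autocorrection.
#' @param deletion_cn Copy number inside implanted deletion events (1 =
#'   hemizygous, the default; 0 = homozygous).
#' @param background_mean Mean of the out-of-band background intensity
#'   distribution (0 disables background draws).
#' @param background_in_band If `TRUE`, background draws are also added to
#'   the in-band channels (to exercise background correction); by default
#'   in-band signal is background-free so expected intensities follow the
#'   baseline * CN/2 model exactly.
#' @param seed RNG seed; fixes the full output deterministically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 10, n_control = 5, probes_per_chrom = 200,
                       chroms = default_chroms(),
                       baseline_log_intensity = c(mean = log(4000), sd = 0.4),
                       noise_sd = 0.25, dye_bias = 1, baseline_offset = 0,
                       deletion_cn = 1L, background_mean = 100,
                       background_in_band = FALSE, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_control = as.integer(n_control),
              probes_per_chrom = as.integer(probes_per_chrom), chroms = chroms,
              baseline_log_intensity = baseline_log_intensity,
              noise_sd = noise_sd, dye_bias = dye_bias,
              baseline_offset = baseline_offset,
              deletion_cn = as.integer(deletion_cn),
              background_mean = background_mean,
              background_in_band = isTRUE(background_in_band),
              seed = as.integer(seed))
  if (cfg$n_tumor < 1 || cfg$n_control < 0 || cfg$probes_per_chrom < 1) {
    stop("sample and probe counts must be positive")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$dye_bias <= 0) stop("dye_bias must be > 0")
  if (!cfg$deletion_cn %in% c(0L, 1L)) stop("deletion_cn must be 0 or 1")
  class(cfg) <- "sim_config"
  cfg
}

scenario_events <- function(scenario, arms, deletion_cn) {
  pick_arm <- function(a) {
    row <- arms[arms$arm == a, , drop = FALSE]
    if (nrow(row) == 0) {
      stop("scenario requires arm ", a, " which is absent from the manifest")
    }
    row
  }
  switch(scenario,
    neutral = arms[0, , drop = FALSE][, c("chrom", "start", "end")],
    kirc_3p = {
      a <- pick_arm("3p")
      data.frame(chrom = a$chrom, start = a$start, end = a$end,
                 copy_number = deletion_cn, stringsAsFactors = FALSE)
    },
    oligo_1p19q = {
      a1 <- pick_arm("1p"); a2 <- pick_arm("19q")
      data.frame(chrom = c(a1$chrom, a2$chrom),
                 start = c(a1$start, a2$start), end = c(a1$end, a2$end),
                 copy_number = 1L, stringsAsFactors = FALSE)
    },
    stop("unknown scenario: ", scenario)
  )
}

# SNP6-style marker count: ~1 marker / 1.5 kb, the density at which arm-scale
# events carry the >10,000 marks required by large-scale-event filters.
snp6_marks <- function(start, end) pmax(1L, as.integer((end - start + 1) %/% 1500))

# Segment mean on the LRR scale for an integer copy number; homozygous
# deletions are floored at -3 (log2(0/2) is unbounded below).
cn_seg_mean <- function(cn) ifelse(cn == 0, -3, log2(cn / 2))

#' Simulate an intensity cohort with known copy-number truth
#'
#' Tumor samples carry the scenario's events: `kirc_3p` implants a deep
#' deletion (CN = `deletion_cn`) over the whole 3p arm, emulating clear cell
#' renal cell carcinoma; `oligo_1p19q` implants CN = 1 over all of 1p and all
#' of 19q, emulating the codeletion that molecularly defines classical
#' oligodendroglioma; `neutral` implants nothing. Controls are copy-neutral
#' throughout.
#'
#' The intensity model: a per-probe lognormal baseline shared across samples
#' is multiplied by CN/2 and per-observation log-normal noise, then split
#' into channels by a per-probe methylated fraction drawn Uniform(0.1, 0.9)
#' (the split is a nuisance parameter: the CNV signal is the channel total).
#' The red channel is further multiplied by `dye_bias`, and all tumor totals
#' by `2^baseline_offset`.
#'
#' @param config A [sim_config()].
#' @param scenario One of `"kirc_3p"`, `"oligo_1p19q"`, `"neutral"`.
#' @return A list with elements `cohort` ([intensity_cohort()]),
#'   `sheet` (sample sheet), `truth` (data frame of truth events:
#'   sample/chrom/start/end/copy_number), and `gold` (a [segment_table()]
#'   gold standard with one row per truth event plus neutral rows tiling the
#'   remainder of every chromosome, SNP6-style marker counts).
#' @export
simulate_cohort <- function(config, scenario = c("kirc_3p", "oligo_1p19q", "neutral")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "sim_config"))
  arms <- arm_table(config$chroms)
  events <- scenario_events(scenario, arms, config$deletion_cn)

  with_local_seed(config$seed, {
    # manifest: evenly spaced probes, random design mix
    manifest_rows <- lapply(seq_len(nrow(config$chroms)), function(i) {
      pos <- unique(as.integer(round(
        seq(1000, config$chroms$length[i] - 1000,
            length.out = config$probes_per_chrom))))
      data.frame(chrom = config$chroms$chrom[i], pos = pos,
                 stringsAsFactors = FALSE)
    })
    md <- do.call(rbind, manifest_rows)
    np <- nrow(md)
    design <- sample(PROBE_DESIGNS, np, replace = TRUE,
                     prob = c(0.15, 0.15, 0.70))
    arm_of <- character(np)
    for (i in seq_len(nrow(arms))) {
      hit <- md$chrom == arms$chrom[i] & md$pos >= arms$start[i] &
        md$pos <= arms$end[i]
      arm_of[hit] <- arms$arm[i]
    }
    manifest <- probe_manifest(sprintf("cg%06d", seq_len(np)), md$chrom,
                               md$pos, design, arm_of, arms = arms)

    tumor_names <- sprintf("T%02d", seq_len(config$n_tumor))
    control_names <- if (config$n_control > 0) {
      sprintf("C%02d", seq_len(config$n_control))
    } else character(0)
    samples <- c(tumor_names, control_names)
    ns <- length(samples)

    # copy-number matrix and truth table
    cn <- matrix(2L, np, ns, dimnames = list(manifest$probe_id, samples))
    truth <- data.frame(sample = character(), chrom = character(),
                        start = integer(), end = integer(),
                        copy_number = integer(), stringsAsFactors = FALSE)
    if (nrow(events)) {
      for (s in tumor_names) {
        for (k in seq_len(nrow(events))) {
          hit <- manifest$chrom == events$chrom[k] &
            manifest$pos >= events$start[k] & manifest$pos <= events$end[k]
          cn[hit, s] <- events$copy_number[k]
        }
      }
      truth <- do.call(rbind, lapply(tumor_names, function(s) {
        data.frame(sample = s, chrom = events$chrom,
                   start = as.integer(events$start),
                   end = as.integer(events$end),
                   copy_number = as.integer(events$copy_number),
                   stringsAsFactors = FALSE)
      }))
    }

    baseline <- rlnorm(np, meanlog = config$baseline_log_intensity[["mean"]],
                       sdlog = config$baseline_log_intensity[["sd"]])
    frac <- runif(np, 0.1, 0.9)
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(np * ns, 0, config$noise_sd), np, ns)
    } else {
      matrix(0, np, ns)
    }
    total <- baseline * (cn / 2) * 2^noise
    if (config$baseline_offset != 0) {
      total[, tumor_names] <- total[, tumor_names] * 2^config$baseline_offset
    }
    meth <- frac * total
    unmeth <- (1 - frac) * total * config$dye_bias
    oob <- if (config$background_mean > 0) {
      matrix(rlnorm(np * ns, meanlog = log(config$background_mean), sdlog = 0.5),
             np, ns)
    } else {
      matrix(0, np, ns)
    }
    if (config$background_in_band && config$background_mean > 0) {
      meth <- meth + matrix(
        rlnorm(np * ns, log(config$background_mean), 0.5), np, ns)
      unmeth <- unmeth + matrix(
        rlnorm(np * ns, log(config$background_mean), 0.5), np, ns)
    }

    cohort <- intensity_cohort(manifest, meth, unmeth, oob,
                               sample_names = samples)
    sheet <- validate_sample_sheet(data.frame(
      sample_name = samples,
      intensity_path = paste0("synthetic://", samples),
      group = c(rep("tumor", length(tumor_names)),
                rep("control", length(control_names))),
      platform = "450k-like",
      stringsAsFactors = FALSE
    ))
    gold <- build_gold_standard(truth, config$chroms, samples)
    list(cohort = cohort, sheet = sheet, truth = truth, gold = gold)
  })
}

# Gold standard: per sample and chromosome, truth-event rows verbatim plus
# neutral rows tiling the rest of the chromosome. Neutral remainders are
# split at the arm boundary so that, as on real SNP arrays, copy-neutral
# samples carry one large segment per arm (arm-midpoint classification then
# sees both arms).
build_gold_standard <- function(truth, chroms, samples) {
  rows <- list()
  for (s in samples) {
    for (i in seq_len(nrow(chroms))) {
      ch <- chroms$chrom[i]; len <- chroms$length[i]
      cen <- chroms$centromere[i]
      ev <- truth[truth$sample == s & truth$chrom == ch, , drop = FALSE]
      ev <- ev[order(ev$start), , drop = FALSE]
      add <- function(start, end, cn) {
        data.frame(sample = s, chrom = ch, start = as.integer(start),
                   end = as.integer(end), num_mark = snp6_marks(start, end),
                   seg_mean = cn_seg_mean(cn),
                   state = if (cn < 2) "loss" else if (cn > 2) "gain" else "neutral",
                   stringsAsFactors = FALSE)
      }
      add_neutral <- function(start, end) {
        out <- list()
        if (start <= cen && end > cen) {
          out[[1]] <- add(start, cen, 2L)
          out[[2]] <- add(cen + 1, end, 2L)
        } else {
          out[[1]] <- add(start, end, 2L)
        }
        out
      }
      cursor <- 1
      for (k in seq_len(nrow(ev))) {
        if (ev$start[k] > cursor) {
          rows <- c(rows, add_neutral(cursor, ev$start[k] - 1))
        }
        rows[[length(rows) + 1L]] <- add(ev$start[k], ev$end[k], ev$copy_number[k])
        cursor <- ev$end[k] + 1
      }
      if (cursor <= len) rows <- c(rows, add_neutral(cursor, len))
    }
  }
  segment_table(if (length(rows)) do.call(rbind, rows) else data.frame(),
                routine = "synthetic_gold_standard")
}

#' Shift the log-scale baseline of selected samples
#'
#' On an LRR track, adds `offset` (log2 units) to every unmasked value of the
#' listed samples. On an intensity cohort, multiplies both in-band channels
#' of those samples by `2^offset`, which is the same shift seen through any
#' downstream LRR computation whose reference excludes the shifted samples.
#' Truth annotations are unaffected.
#'
#' @param x An [intensity_cohort()] or an `lrr_track`.
#' @param samples Character vector of sample names to shift.
#' @param offset Finite additive offset in log2 units.
#' @return Object of the same class with shifted values.
#' @export
inject_baseline_offset <- function(x, samples, offset) {
  if (!is.finite(offset)) stop("offset must be finite")
  UseMethod("inject_baseline_offset")
}

#' @export
inject_baseline_offset.intensity_cohort <- function(x, samples, offset) {
  unknown <- setdiff(samples, x$sample_names)
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  x$meth[, samples] <- x$meth[, samples, drop = FALSE] * 2^offset
  x$unmeth[, samples] <- x$unmeth[, samples, drop = FALSE] * 2^offset
  x
}

#' @export
inject_baseline_offset.lrr_track <- function(x, samples, offset) {
  unknown <- setdiff(samples, colnames(x$values))
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  x$values[, samples] <- x$values[, samples, drop = FALSE] + offset
  x
}
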