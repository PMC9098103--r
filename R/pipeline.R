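# Route presets tying the stages together, plus run configuration,
# performance recording, structured logging and the state-matrix export.

#' Run configuration
#'
#' @param route Preset: `"standard"` (background -> dye -> mask ->
#'   median-control reference -> LRR -> CBS -> threshold states),
#'   `"zscore"` (z-transformed tumor minus z-transformed control reference,
#'   mean-centred before segmentation), `"standard_median_ref"` (standard
#'   with a cohort-median reference; no controls needed) or `"custom"`
#'   (standard plus density-peak baseline autocorrection before state
#'   calling).
#' @param cbs A [cbs_params()].
#' @param states A [state_call_params()].
#' @param mask_p Detection p-value threshold for probe masking.
#' @param consensus List with `density`, `rho`, `est_recur`.
#' @param seed Seed forwarded to the CBS permutation stream.
#' @param autocorrect_weighted Weight the autocorrection density by mark
#'   counts (custom route only).
#' @return A list of class `run_config`, serializable to YAML.
#' @export
run_config <- function(route = c("standard", "zscore", "standard_median_ref",
                                 "custom"),
                       cbs = cbs_params(), states = state_call_params(),
                       mask_p = 0.05,
                       consensus = list(density = 0.1, rho = 0.5,
                                        est_recur = TRUE),
                       seed = 1L, autocorrect_weighted = TRUE) {
  route <- match.arg(route)
  cbs$seed <- as.integer(seed)
  structure(list(route = route, cbs = cbs, states = states, mask_p = mask_p,
                 consensus = consensus, seed = as.integer(seed),
                 autocorrect_weighted = isTRUE(autocorrect_weighted)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the restored [run_config()].
#' @export
write_run_config <- function(config, path) {
  lst <- list(route = config$route, cbs = unclass(config$cbs),
              states = unclass(config$states), mask_p = config$mask_p,
              consensus = config$consensus, seed = config$seed,
              autocorrect_weighted = config$autocorrect_weighted)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  run_config(route = lst$route,
             cbs = do.call(cbs_params, lst$cbs[setdiff(names(lst$cbs), "seed")]),
             states = do.call(state_call_params, lst$states),
             mask_p = lst$mask_p, consensus = lst$consensus,
             seed = lst$seed, autocorrect_weighted = lst$autocorrect_weighted)
}

reference_mode_for_route <- function(route) {
  switch(route,
         standard = "median_controls",
         custom = "median_controls",
         zscore = "median_controls",
         standard_median_ref = "cohort_median")
}

#' Run a route preset end to end
#'
#' Executes the preset's stage sequence on a cohort and sample sheet and
#' returns the common-format segment table, consensus regions and a
#' performance record. When `out_dir` is given, writes `segments.csv`,
#' `consensus.csv`, `perf.csv`, `config.yaml` and a JSON-lines run log.
#'
#' @param config A [run_config()].
#' @param sheet A validated sample sheet matching the cohort.
#' @param cohort An [intensity_cohort()].
#' @param out_dir Optional output directory.
#' @return List with `segments` ([segment_table()]), `consensus` (data
#'   frame), `perf` (data frame: route, wall_time_s, peak_memory_mb,
#'   n_samples, n_probes), `lrr` (the segmented track) and `log` (list of
#'   per-stage records).
#' @export
run_pipeline <- function(config, sheet, cohort, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  route <- config$route
  needs_controls <- route %in% c("standard", "custom", "zscore")
  if (needs_controls && !any(sheet$group == "control")) {
    stop("route ", route, " requires at least one control sample")
  }
  if (!any(sheet$group == "tumor")) stop("at least one tumor sample is required")

  t0 <- Sys.time()
  gc(reset = TRUE)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  cohort <- background_correct(cohort)
  note("background_correct", n_probes = nrow(cohort$manifest))
  cohort <- dye_bias_correct(cohort)
  note("dye_bias_correct")
  cohort <- mask_probes(cohort, config$mask_p)
  note("mask_probes", p_threshold = config$mask_p,
       masked = sum(cohort$mask))

  ref_mode <- reference_mode_for_route(route)
  i_r <- build_reference(cohort, sheet, ref_mode)
  track <- compute_lrr(cohort, i_r)
  note("compute_lrr", reference_mode = ref_mode)

  tumors <- sheet$sample_name[sheet$group == "tumor"]
  center <- FALSE
  if (route == "zscore") {
    # z-transform tumors and the control-derived reference track, segment
    # the difference with per-sample mean-centering
    tumor_track <- lrr_track(track$manifest,
                             track$values[, tumors, drop = FALSE],
                             track$mask[, tumors, drop = FALSE],
                             route = "zscore", reference_mode = ref_mode)
    tumor_track <- zscore_transform(tumor_track)
    track <- tumor_track
    center <- TRUE
  } else {
    track <- lrr_track(track$manifest,
                       track$values[, tumors, drop = FALSE],
                       track$mask[, tumors, drop = FALSE],
                       route = track$route, reference_mode = ref_mode)
  }

  segments <- cbs_segment(track, config$cbs, center = center)
  note("cbs_segment", n_segments = nrow(segments))
  if (route == "custom") {
    segments <- autocorrect_baseline(segments,
                                     weighted = config$autocorrect_weighted)
    note("autocorrect_baseline",
         offsets = as.list(attr(segments, "offsets")))
  }
  segments <- call_states(segments, config$states)
  note("call_states", mode = config$states$mode)

  consensus <- if (length(tumors) >= 2) {
    consensus_regions(segments, density = config$consensus$density,
                      rho = config$consensus$rho,
                      est_recur = isTRUE(config$consensus$est_recur))
  } else {
    NULL
  }
  note("consensus_regions", n_regions = if (is.null(consensus)) 0L else nrow(consensus))

  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  gs <- gc()
  peak_mb <- sum(gs[, "max used"] * c(56, 8)) / 2^20  # Ncells/Vcells in bytes
  perf <- data.frame(route = route, wall_time_s = wall,
                     peak_memory_mb = peak_mb,
                     n_samples = length(cohort$sample_names),
                     n_probes = nrow(cohort$manifest))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segments(segments, file.path(out_dir, "segments.csv"))
    cons_out <- consensus %||% data.frame(
      chrom = character(), start = integer(), end = integer(),
      state = character(), n_support = integer(), support_frac = numeric(),
      recurrent = logical())
    write.csv(cons_out, file.path(out_dir, "consensus.csv"), row.names = FALSE)
    write.csv(perf, file.path(out_dir, "perf.csv"), row.names = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    writeLines(vapply(log, function(rec) {
      paste0("{", paste(sprintf('"%s":"%s"', names(rec),
                                vapply(rec, function(v) paste(format(v), collapse = ";"),
                                       character(1))),
                        collapse = ","), "}")
    }, character(1)), file.path(out_dir, "run.log"))
  }
  list(segments = segments, consensus = consensus, perf = perf,
       lrr = track, log = log)
}

#' Export per-sample copy states on a fixed genomic grid
#'
#' Bins each chromosome into `bin_size`-bp windows; each bin's code is the
#' state of the segment covering the bin midpoint (-1 loss, 0 neutral,
#' +1 gain in threshold mode; the integer copy number in formula mode).
#' Bins covered by no segment get `NA`. This is the matrix behind a CNV
#' heatmap.
#'
#' @param tables List of state-called [segment_table()]s (or one table).
#' @param bin_size Bin width in bp (> 0).
#' @return Numeric matrix (sample x bin) with `chrom:start-end` column names.
#' @export
export_state_matrix <- function(tables, bin_size) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (inherits(tables, "segment_table")) tables <- list(tables)
  calls <- do.call(rbind, lapply(tables, as.data.frame))
  if (is.null(calls) || nrow(calls) == 0) return(matrix(NA_real_, 0, 0))
  samples <- unique(calls$sample)
  state_code <- function(st) {
    if (is.na(st)) return(NA_real_)
    num <- suppressWarnings(as.numeric(st))
    if (!is.na(num)) return(num)
    switch(st, loss = -1, neutral = 0, gain = 1, NA_real_)
  }
  cols <- list(); codes <- list()
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, , drop = FALSE]
    last <- max(sub$end)
    n_bins <- ceiling(last / bin_size)
    starts <- (seq_len(n_bins) - 1L) * bin_size + 1L
    mids <- starts + bin_size %/% 2
    cols[[ch]] <- sprintf("%s:%d-%d", ch, starts,
                          pmin(starts + bin_size - 1L, last))
    m <- vapply(samples, function(s) {
      ss <- sub[sub$sample == s, , drop = FALSE]
      vapply(mids, function(m) {
        hit <- which(ss$start <= m & ss$end >= m)
        if (length(hit) == 0) NA_real_ else state_code(ss$state[hit[1]])
      }, numeric(1))
    }, numeric(n_bins))
    if (is.null(dim(m))) m <- matrix(m, nrow = n_bins)
    codes[[ch]] <- m
  }
  mat <- t(do.call(rbind, codes))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(samples))
  rownames(mat) <- samples
  colnames(mat) <- unlist(cols, use.names = FALSE)
  mat
}
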