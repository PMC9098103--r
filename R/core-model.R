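# Core data model: probe manifest, sample sheet, intensity cohort, and the
# common segment table that every routine consumes and produces.

PROBE_DESIGNS <- c("typeI_grn", "typeI_red", "typeII")
SEGMENT_COLUMNS <- c("sample", "chrom", "start", "end", "num_mark", "seg_mean", "state")

#' Construct a probe manifest
#'
#' The manifest is the coordinate backbone for every track: one row per probe
#' with its genomic placement, design type (which governs which fluorescence
#' channel carries signal and which is out-of-band) and chromosome-arm label.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chrom Chromosome label per probe (e.g. `"chr1"`).
#' @param pos 1-based base-pair coordinate of the interrogated CpG.
#' @param design One of `"typeI_grn"`, `"typeI_red"`, `"typeII"` per probe.
#' @param arm Chromosome-arm label per probe (e.g. `"3p"`).
#' @param arms Optional data frame of arm boundaries with columns
#'   `chrom`, `arm`, `start`, `end`; stored as the `"arms"` attribute and used
#'   by large-scale-event classification.
#' @return A `data.frame` of class `probe_manifest`, ordered by chromosome
#'   (first appearance) then position.
#' @export
probe_manifest <- function(probe_id, chrom, pos, design, arm, arms = NULL) {
  if (anyDuplicated(probe_id)) {
    stop("probe_id values must be unique")
  }
  if (any(pos < 1)) stop("probe positions must be >= 1")
  if (!all(design %in% PROBE_DESIGNS)) {
    stop("design must be one of: ", paste(PROBE_DESIGNS, collapse = ", "))
  }
  m <- data.frame(
    probe_id = as.character(probe_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    design = as.character(design),
    arm = as.character(arm),
    stringsAsFactors = FALSE
  )
  chrom_order <- unique(m$chrom)
  m <- m[order(match(m$chrom, chrom_order), m$pos), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "arms") <- arms
  class(m) <- c("probe_manifest", "data.frame")
  m
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps sample names to intensity sources and tumor/control
#' groups; the sheet path is independent of the intensity-file paths so one
#' sheet can drive every routine. Required columns: `sample_name`,
#' `intensity_path`, `group`. Extra columns (e.g. `platform`,
#' `matched_normal`) are preserved as metadata.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param df A data frame with at least `sample_name`, `intensity_path`,
#'   `group` columns.
#' @return `df` with class `sample_sheet` prepended.
#' @export
validate_sample_sheet <- function(df) {
  if (nrow(df) == 0) stop("sample sheet is empty")
  required <- c("sample_name", "intensity_path", "group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unique(df$sample_name[duplicated(df$sample_name)])
  if (length(dup)) {
    stop("duplicated sample_name in sample sheet: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(df$group) | df$group == "")) {
    stop("every sample-sheet row needs a nonempty group")
  }
  bad <- setdiff(unique(df$group), c("tumor", "control"))
  if (length(bad)) {
    stop("unknown group value(s): ", paste(bad, collapse = ", "),
         " (expected tumor/control)")
  }
  class(df) <- unique(c("sample_sheet", class(df)))
  df
}

#' Construct an intensity cohort
#'
#' Per-probe, per-sample two-channel raw intensities plus a mask. Masked
#' entries never contribute to any downstream statistic, and the masked set
#' only grows through the preprocessing stages.
#'
#' @param manifest A [probe_manifest()].
#' @param meth,unmeth Numeric matrices (probe x sample) of nonnegative
#'   methylated (green) and unmethylated (red) channel intensities.
#' @param oob Matrix of out-of-band intensities (background fluorescence read
#'   from the opposite channel of type I probes); same shape.
#' @param mask Logical matrix, `TRUE` = excluded. Defaults to all-`FALSE`.
#' @param sample_names Column names; defaults to `colnames(meth)`.
#' @return An object of class `intensity_cohort`.
#' @export
intensity_cohort <- function(manifest, meth, unmeth, oob = NULL, mask = NULL,
                             sample_names = colnames(meth)) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  np <- nrow(manifest); ns <- ncol(meth)
  if (is.null(sample_names)) stop("sample names are required")
  if (nrow(meth) != np || nrow(unmeth) != np) {
    stop("intensity matrices must have one row per manifest probe")
  }
  if (!identical(dim(meth), dim(unmeth))) stop("meth/unmeth dimensions differ")
  if (is.null(oob)) oob <- matrix(0, np, ns)
  oob <- as.matrix(oob)
  if (!identical(dim(oob), dim(meth))) stop("oob dimensions differ from meth")
  if (is.null(mask)) mask <- matrix(FALSE, np, ns)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(meth))) stop("mask dimensions differ from meth")
  if (any(meth[!mask] < 0, na.rm = TRUE) || any(unmeth[!mask] < 0, na.rm = TRUE)) {
    stop("unmasked intensities must be >= 0")
  }
  dimnames(meth) <- dimnames(unmeth) <- dimnames(oob) <- dimnames(mask) <-
    list(manifest$probe_id, sample_names)
  structure(
    list(manifest = manifest, meth = meth, unmeth = unmeth, oob = oob,
         mask = mask, sample_names = sample_names),
    class = "intensity_cohort"
  )
}

#' Total in-band intensity per probe and sample
#'
#' The CNV signal is the combined methylated + unmethylated intensity; the
#' methylation fraction itself is never used for copy number.
#'
#' @param cohort An `intensity_cohort`.
#' @return Numeric matrix (probe x sample) with masked entries set to `NA`.
#' @export
total_intensity <- function(cohort) {
  tot <- cohort$meth + cohort$unmeth
  tot[cohort$mask] <- NA_real_
  tot
}

#' Construct and validate a segment table
#'
#' The common cross-routine segment format: one row per contiguous segment
#' with `sample, chrom, start, end, num_mark, seg_mean, state`. Coordinates
#' are 1-based fully-closed intervals; within one sample and chromosome
#' segments must be non-overlapping and ordered.
#'
#' @param df Data frame holding the seven segment columns (`state` may be
#'   `NA` before state calling).
#' @param routine Provenance: name of the routine that produced the table.
#' @param params Provenance: list of parameters used.
#' @return A `data.frame` of class `segment_table`.
#' @export
segment_table <- function(df, routine = NA_character_, params = list()) {
  if (nrow(df) == 0) {
    df <- data.frame(sample = character(), chrom = character(),
                     start = integer(), end = integer(),
                     num_mark = integer(), seg_mean = numeric(),
                     state = character(), stringsAsFactors = FALSE)
  }
  missing <- setdiff(SEGMENT_COLUMNS, names(df))
  if (length(missing)) {
    stop("segment table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, SEGMENT_COLUMNS, drop = FALSE]
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$num_mark <- as.integer(df$num_mark)
  df$seg_mean <- as.numeric(df$seg_mean)
  df$state <- as.character(df$state)
  if (nrow(df)) {
    if (any(df$start > df$end)) stop("segment start must be <= end")
    if (any(df$num_mark < 1)) stop("segments need num_mark >= 1")
    for (key in unique(paste(df$sample, df$chrom))) {
      sub <- df[paste(df$sample, df$chrom) == key, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
        stop("overlapping segments within ", key)
      }
    }
  }
  rownames(df) <- NULL
  attr(df, "routine") <- routine
  attr(df, "params") <- params
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Write a segment table to CSV
#'
#' Segment means are serialized at full precision (`%.17g`) so that
#' `read_segments(write_segments(x))` reproduces `x` field-for-field.
#'
#' @param table A [segment_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(table, path) {
  table <- segment_table(as.data.frame(table),
                         routine = attr(table, "routine"),
                         params = attr(table, "params"))
  out <- as.data.frame(table)
  out$seg_mean <- vapply(out$seg_mean, function(x) {
    if (is.na(x)) "NA" else sprintf("%.17g", x)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(SEGMENT_COLUMNS, collapse = ","), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a segment table from CSV
#'
#' @param path CSV path as written by [write_segments()].
#' @return A [segment_table()].
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sample = "character", chrom = "character",
                                start = "integer", end = "integer",
                                num_mark = "integer", seg_mean = "numeric",
                                state = "character"))
  segment_table(df)
}

#' Read a long-format intensity table into a cohort
#'
#' The plain-text reference input format: columns
#' `probe_id, sample, meth, unmeth, oob`, one row per probe/sample pair.
#'
#' @param path CSV path.
#' @param manifest The [probe_manifest()] giving probe order and placement.
#' @return An [intensity_cohort()].
#' @export
read_intensity_table <- function(path, manifest) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "sample", "meth", "unmeth", "oob")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("intensity table is missing column(s): ", paste(missing, collapse = ", "))
  }
  samples <- unique(df$sample)
  idx <- match(df$probe_id, manifest$probe_id)
  if (anyNA(idx)) stop("intensity table contains probes absent from the manifest")
  shape <- function(col) {
    m <- matrix(NA_real_, nrow(manifest), length(samples))
    m[cbind(idx, match(df$sample, samples))] <- df[[col]]
    if (anyNA(m)) stop("intensity table does not cover every probe/sample pair")
    m
  }
  intensity_cohort(manifest, shape("meth"), shape("unmeth"), shape("oob"),
                   sample_names = samples)
}

#' Write a cohort as a long-format intensity table
#'
#' @param cohort An [intensity_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(cohort, path) {
  ns <- length(cohort$sample_names)
  np <- nrow(cohort$manifest)
  df <- data.frame(
    probe_id = rep(cohort$manifest$probe_id, times = ns),
    sample = rep(cohort$sample_names, each = np),
    meth = as.vector(cohort$meth),
    unmeth = as.vector(cohort$unmeth),
    oob = as.vector(cohort$oob),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
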