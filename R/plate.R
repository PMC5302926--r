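#' Plate-file dialect configuration
#'
#' Instrument exports differ in delimiter, in the sentinel used for wells
#' that never crossed the fluorescence threshold, and in the maximum cycle
#' number of the run.  A dialect collects these choices; the defaults match
#' common real-time instrument exports ("Undetermined", 40 cycles).
#'
#' @param sep Field separator.  `NULL` (default) autodetects comma versus
#'   tab from the header line.
#' @param undetermined Character vector of sentinels in the `ct` column that
#'   denote non-amplification.  An empty cell is treated as undetermined as
#'   well.
#' @param max_cycles Maximum cycle number of the run.  A determined Ct above
#'   this value is reclassified as undetermined at parse time: weak signals
#'   past the run length are not reliable detections.
#' @param reference_gene Name of the methylation-independent input-reference
#'   amplicon (default `"COL2A1"`).
#'
#' @return A list of class `"plate_dialect"`.
#' @export
plate_dialect <- function(sep = NULL,
                          undetermined = c("Undetermined", "Undet", "UNDETERMINED"),
                          max_cycles = 40,
                          reference_gene = "COL2A1") {
  stopifnot(is.numeric(max_cycles), length(max_cycles) == 1L, max_cycles > 0)
  structure(
    list(sep = sep, undetermined = as.character(undetermined),
         max_cycles = max_cycles, reference_gene = reference_gene),
    class = "plate_dialect"
  )
}

plate_columns <- c("sample_id", "gene", "role", "replicate", "ct")

#' Read a qPCR plate export
#'
#' Parses a delimited text export with one row per well.  Required columns:
#' `sample_id`, `gene`, `role` (`REFERENCE` or `TARGET`), `replicate`
#' (integer >= 1) and `ct`.  Optional columns `input_ng` and `cohort_label`
#' are carried through when present.  The `ct` column accepts either a
#' numeric cycle-threshold value or one of the dialect's undetermined
#' sentinels; any other non-numeric content is a format error, not a silent
#' undetermined.
#'
#' @param path Path to the plate file.
#' @param dialect A [plate_dialect()].
#'
#' @return A data frame of reaction records with columns `sample_id`,
#'   `gene`, `role`, `replicate`, `ct` (numeric; `NA` = undetermined) and,
#'   if present in the file, `input_ng` and `cohort_label`.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,gene,role,replicate,ct",
#'              "S1,COL2A1,REFERENCE,1,29.34",
#'              "S1,GFRA1,TARGET,1,Undetermined"), p)
#' read_plate(p)
read_plate <- function(path, dialect = plate_dialect()) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  stopifnot(inherits(dialect, "plate_dialect"))
  sep <- dialect$sep
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, strip.white = TRUE,
                   blank.lines.skip = TRUE, quote = "\"")
  missing_cols <- setdiff(plate_columns, names(df))
  if (length(missing_cols)) {
    stop("plate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  ct_raw <- df$ct
  is_undet <- ct_raw %in% dialect$undetermined | !nzchar(trimws(ct_raw))
  ct <- rep(NA_real_, nrow(df))
  if (any(!is_undet)) {
    parsed <- suppressWarnings(as.numeric(ct_raw[!is_undet]))
    bad <- is.na(parsed)
    if (any(bad)) {
      stop("malformed Ct value(s): ",
           paste(unique(ct_raw[!is_undet][bad]), collapse = ", "),
           " (use the configured sentinel for undetermined wells)")
    }
    if (any(parsed < 0)) stop("negative Ct value(s) in plate file")
    ct[!is_undet] <- parsed
  }
  # late weak signals beyond the run length are not trustworthy detections
  ct[!is.na(ct) & ct > dialect$max_cycles] <- NA_real_

  rec <- data.frame(
    sample_id = df$sample_id,
    gene = df$gene,
    role = toupper(df$role),
    replicate = as.integer(df$replicate),
    ct = ct,
    stringsAsFactors = FALSE
  )
  if (anyNA(rec$replicate) || any(rec$replicate < 1L)) {
    stop("replicate must be an integer >= 1")
  }
  if (!all(rec$role %in% c("REFERENCE", "TARGET"))) {
    stop("role must be REFERENCE or TARGET")
  }
  key <- paste(rec$sample_id, rec$gene, rec$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample_id, gene, replicate) record(s): ",
         paste(gsub("\r", "/", dup), collapse = "; "))
  }
  if ("input_ng" %in% names(df)) {
    rec$input_ng <- suppressWarnings(as.numeric(df$input_ng))
  }
  if ("cohort_label" %in% names(df)) rec$cohort_label <- df$cohort_label
  rec
}

#' Write reaction records to a plate file
#'
#' Inverse of [read_plate()]: undetermined wells (`NA` Ct) are written with
#' the dialect's first sentinel so that a read/write cycle is lossless.
#'
#' @param records A reaction-record data frame as returned by [read_plate()].
#' @param path Output path.
#' @param dialect A [plate_dialect()]; `sep = NULL` writes comma-separated.
#' @return `path`, invisibly.
#' @export
write_plate <- function(records, path, dialect = plate_dialect()) {
  stopifnot(is.data.frame(records), all(plate_columns %in% names(records)))
  out <- records
  out$ct <- ifelse(is.na(records$ct), dialect$undetermined[[1L]],
                   format(records$ct, trim = TRUE, scientific = FALSE))
  sep <- if (is.null(dialect$sep)) "," else dialect$sep
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate wells into per-(sample, gene) summaries
#'
#' Collapses reaction records to one row per sample and gene with the
#' replicate count, the number of determined wells, the arithmetic mean Ct
#' over determined wells only, and a detection class:
#' `FULL` (all replicates determined), `PARTIAL` (some), `NONE` (none).
#' The mean, not the median, is used within a sample, as is conventional
#' when the reference-gene Ct serves as the indicator of input-template
#' amount.
#'
#' @param records Reaction-record data frame ([read_plate()] output or
#'   equivalent).  May be empty, giving an empty summary.
#' @return Data frame with columns `sample_id`, `gene`, `role`, `n_total`,
#'   `n_detected`, `mean_ct` (`NA` when `n_detected` is 0) and `detection`.
#' @export
aggregate_replicates <- function(records) {
  cols <- c("sample_id", "gene", "role", "n_total", "n_detected",
            "mean_ct", "detection")
  if (is.null(records) || nrow(records) == 0L) {
    out <- data.frame(sample_id = character(), gene = character(),
                      role = character(), n_total = integer(),
                      n_detected = integer(), mean_ct = numeric(),
                      detection = character(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  stopifnot(all(plate_columns %in% names(records)))
  key <- paste(records$sample_id, records$gene, sep = "\r")
  # role must be consistent within a (sample, gene) group
  role_chk <- tapply(records$role, key, function(r) length(unique(r)))
  if (any(role_chk > 1L)) {
    stop("inconsistent role within a (sample_id, gene) replicate set")
  }
  # order-stable aggregation keyed on first appearance
  ord <- !duplicated(key)
  groups <- key[ord]
  idx <- split(seq_len(nrow(records)), factor(key, levels = groups))
  res <- lapply(idx, function(i) {
    ct <- records$ct[i]
    n_det <- sum(!is.na(ct))
    data.frame(
      sample_id = records$sample_id[i[1L]],
      gene = records$gene[i[1L]],
      role = records$role[i[1L]],
      n_total = length(i),
      n_detected = n_det,
      mean_ct = if (n_det >= 1L) mean(ct, na.rm = TRUE) else NA_real_,
      detection = if (n_det == length(i)) "FULL"
                  else if (n_det == 0L) "NONE" else "PARTIAL",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[cols]
}

#' DNA concentration from an absorbance reading
#'
#' Converts a (dilution-corrected) A260 absorbance into ng/uL using the
#' standard spectrophotometric factors: 33 for single-stranded DNA
#' (bisulfite-converted templates) and 50 for double-stranded genomic DNA.
#'
#' @param a260_times_dilution A260 reading already multiplied by any
#'   dilution factor; must be >= 0.
#' @param strandedness `"single"` or `"double"`.
#' @return Concentration in ng/uL.
#' @export
#' @examples
#' dna_concentration(1.0, "single")  # 33
#' dna_concentration(1.0, "double")  # 50
dna_concentration <- function(a260_times_dilution,
                              strandedness = c("single", "double")) {
  strandedness <- match.arg(strandedness)
  if (!is.numeric(a260_times_dilution) || any(a260_times_dilution < 0)) {
    stop("absorbance must be a non-negative number")
  }
  factor <- if (strandedness == "single") 33 else 50
  a260_times_dilution * factor
}
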