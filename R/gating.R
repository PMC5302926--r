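#' Gate a sample by its reference-gene Ct
#'
#' A sample is methylation-informative when its mean reference Ct is at or
#' below the policy threshold (boundary inclusive: `Ct <= threshold`), i.e.
#' it contains at least the minimum input template.  A higher Ct marks the
#' sample non-informative: a negative methylation call on it is a potential
#' false negative.  A reference that never amplified is reported as a
#' distinct assay failure (`NO_REFERENCE`), not as non-informative.
#'
#' @param ref_summary One row of [aggregate_replicates()] output for the
#'   reference gene (or any list/row with `mean_ct` and `detection`).
#' @param policy A `"tait_policy"` with a `ct_threshold`.
#' @return `"INFORMATIVE"`, `"NON_INFORMATIVE"` or `"NO_REFERENCE"`.
#' @export
#' @examples
#' pol <- derive_policy(0.15, 0.016, 4,
#'                      data.frame(total_ng = 9.39, mean_ref_ct = 29.34))
#' gate_sample(list(mean_ct = 29.3, detection = "FULL"), pol)
gate_sample <- function(ref_summary, policy) {
  stopifnot(inherits(policy, "tait_policy"))
  if (is.na(policy$ct_threshold)) {
    stop("policy carries no ct_threshold; derive it with standard points")
  }
  gate_ct(ref_summary$mean_ct, ref_summary$detection, policy$ct_threshold)
}

# vectorised core shared by gate_sample() and score_cohort()
gate_ct <- function(mean_ct, detection, threshold) {
  ifelse(detection == "NONE" | is.na(mean_ct), "NO_REFERENCE",
         ifelse(mean_ct <= threshold, "INFORMATIVE", "NON_INFORMATIVE"))
}

#' Call methylation from a replicate summary
#'
#' A target is methylation-positive only when its signal was consistently
#' detected, i.e. determined in every replicate (`FULL`); partial detection
#' and complete dropout are both negative.  No quantitative cutoff is
#' applied at this stage.  Set `partial` to `"indeterminate"` to keep
#' partially detected targets as a separate class instead of folding them
#' into negative.
#'
#' @param target_summary Row(s) of [aggregate_replicates()] output for a
#'   target gene, or anything with a `detection` field.
#' @param partial How to treat `PARTIAL` detection: `"negative"` (default)
#'   or `"indeterminate"`.
#' @return `"POSITIVE"`, `"NEGATIVE"` (or `"INDETERMINATE"`).
#' @export
call_methylation <- function(target_summary,
                             partial = c("negative", "indeterminate")) {
  partial <- match.arg(partial)
  det <- if (is.list(target_summary) || is.data.frame(target_summary)) {
    target_summary$detection
  } else {
    target_summary
  }
  stopifnot(all(det %in% c("FULL", "PARTIAL", "NONE")))
  out <- ifelse(det == "FULL", "POSITIVE", "NEGATIVE")
  if (partial == "indeterminate") out[det == "PARTIAL"] <- "INDETERMINATE"
  out
}

#' Percent of methylated reference (PMR)
#'
#' Quantifies the methylated-allele fraction of a sample relative to a
#' fully methylated calibrator:
#' `100 * E^-((target_ct - ref_ct) - (cal_target_ct - cal_ref_ct))`
#' with amplification base `E` (2 for textbook doubling).  Values above 100
#' indicate more target signal than the calibrator and are permitted (a
#' warning flags them).
#'
#' @param target_ct,ref_ct Sample target and reference mean Ct (determined).
#' @param calibrator_target_ct,calibrator_ref_ct Calibrator Ct pair.
#' @param efficiency Per-cycle amplification factor, default 2.
#' @return PMR in percent (numeric, vectorised).
#' @export
#' @examples
#' pmr(33, 28, 33, 28)      # 100
#' pmr(34, 28, 33, 28)      # 50
pmr <- function(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct,
                efficiency = 2) {
  args <- list(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct)
  if (any(vapply(args, function(a) any(is.na(a)), logical(1)))) {
    stop("all Ct values must be determined to compute a PMR")
  }
  stopifnot(is.numeric(efficiency), efficiency > 1)
  ddct <- (target_ct - ref_ct) - (calibrator_target_ct - calibrator_ref_ct)
  out <- 100 * efficiency^(-ddct)
  if (any(out > 100 + 1e-9)) {
    warning("PMR above 100%: sample shows more methylated signal than the ",
            "fully methylated calibrator")
  }
  out
}

#' Score a cohort plate against a gating policy
#'
#' Aggregates replicates, gates every sample by its reference-gene Ct and
#' calls methylation for every target gene.  For externally called assays
#' (MSP, DHPLC) supply `external_calls` instead of relying on replicate
#' detection; the same reference-Ct gate is applied either way.
#'
#' @param records Reaction-record data frame ([read_plate()] format).
#' @param policy A `"tait_policy"`.
#' @param reference_gene Reference gene name (default from the records'
#'   `role` column: the gene marked `REFERENCE`).
#' @param cohort_label Label stored on every row (default `""` or the
#'   records' `cohort_label`).
#' @param assay_kind `"METHYLIGHT"`, `"MSP"` or `"DHPLC"`.
#' @param pass_index 1 for a first analysis, 2 for a re-analysis.
#' @param external_calls Optional data frame `sample_id`, `gene`, `call`
#'   with externally supplied binary calls (used for MSP/DHPLC readouts).
#' @return Data frame of class `"sample_assay_results"`: one row per sample
#'   and target gene with columns `sample_id`, `cohort_label`, `assay_kind`,
#'   `pass_index`, `ref_ct`, `informative`, `gene`, `call`.
#' @export
score_cohort <- function(records, policy, reference_gene = NULL,
                         cohort_label = NULL,
                         assay_kind = c("METHYLIGHT", "MSP", "DHPLC"),
                         pass_index = 1L, external_calls = NULL) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(inherits(policy, "tait_policy"))
  summ <- aggregate_replicates(records)
  if (is.null(reference_gene)) {
    ref_genes <- unique(summ$gene[summ$role == "REFERENCE"])
    if (length(ref_genes) != 1L) {
      stop("cannot infer the reference gene; pass reference_gene=")
    }
    reference_gene <- ref_genes
  }
  ref <- summ[summ$gene == reference_gene, , drop = FALSE]
  tgt <- summ[summ$gene != reference_gene, , drop = FALSE]
  if (!nrow(ref)) stop("no reference-gene records for ", reference_gene)

  ref_ct <- setNames(ref$mean_ct, ref$sample_id)
  ref_det <- setNames(ref$detection, ref$sample_id)
  samples_missing_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(samples_missing_ref)) {
    stop("samples without reference reactions: ",
         paste(samples_missing_ref, collapse = ", "))
  }

  if (is.null(cohort_label)) {
    cohort_label <- if ("cohort_label" %in% names(records)) {
      lab <- setNames(records$cohort_label, records$sample_id)
      lab[!duplicated(names(lab))]
    } else ""
  }
  lab_for <- function(id) {
    if (length(cohort_label) == 1L && is.null(names(cohort_label))) {
      rep(cohort_label, length(id))
    } else {
      unname(cohort_label[id])
    }
  }

  if (is.null(external_calls)) {
    calls <- call_methylation(tgt$detection)
    out <- data.frame(
      sample_id = tgt$sample_id,
      cohort_label = lab_for(tgt$sample_id),
      assay_kind = assay_kind,
      pass_index = as.integer(pass_index),
      ref_ct = unname(ref_ct[tgt$sample_id]),
      informative = gate_ct(ref_ct[tgt$sample_id], ref_det[tgt$sample_id],
                            policy$ct_threshold),
      gene = tgt$gene,
      call = calls,
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("sample_id", "gene", "call") %in% names(external_calls)))
    out <- data.frame(
      sample_id = external_calls$sample_id,
      cohort_label = lab_for(external_calls$sample_id),
      assay_kind = assay_kind,
      pass_index = as.integer(pass_index),
      ref_ct = unname(ref_ct[external_calls$sample_id]),
      informative = gate_ct(ref_ct[external_calls$sample_id],
                            ref_det[external_calls$sample_id],
                            policy$ct_threshold),
      gene = external_calls$gene,
      call = external_calls$call,
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  class(out) <- c("sample_assay_results", class(out))
  out
}

#' Re-analysis of non-informative samples at boosted input template
#'
#' Implements the countermeasure workflow: samples gated `NON_INFORMATIVE`
#' in a first pass are re-assayed with more input DNA; the same gate and
#' call rules are applied to the new plate, and the positive rate among the
#' re-analysed subset is compared before and after.  A re-assayed sample
#' that is *still* above the Ct threshold is flagged and excluded from the
#' pass-2 rate (its negative call remains unreliable).
#'
#' @param pass1 A `"sample_assay_results"` data frame (pass 1).
#' @param reassay_records Reaction records for the re-assay; must cover
#'   every pass-1 `NON_INFORMATIVE` sample.
#' @param policy The `"tait_policy"` in force.
#' @param ... Passed to [score_cohort()] for the re-assay plate.
#' @return List of class `"reanalysis"`: `results` (pass-2 rows),
#'   `summary` (per gene: n re-analysed, positive rate before/after among
#'   samples informative in pass 2), `still_non_informative` (sample ids).
#' @export
reanalyze <- function(pass1, reassay_records, policy, ...) {
  stopifnot(is.data.frame(pass1), inherits(policy, "tait_policy"))
  noninf <- unique(pass1$sample_id[pass1$informative == "NON_INFORMATIVE"])
  if (!length(noninf)) {
    empty <- pass1[0, , drop = FALSE]
    empty$pass_index <- integer(0)
    return(structure(list(results = empty,
                          summary = data.frame(gene = character(),
                                               n_reanalyzed = integer(),
                                               rate_before = numeric(),
                                               rate_after = numeric()),
                          still_non_informative = character()),
                     class = "reanalysis"))
  }
  reassay_samples <- unique(reassay_records$sample_id)
  missing <- setdiff(noninf, reassay_samples)
  if (length(missing)) {
    stop("re-assay plate is missing non-informative sample(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(reassay_samples, noninf)
  if (length(extra)) {
    reassay_records <-
      reassay_records[reassay_records$sample_id %in% noninf, , drop = FALSE]
  }
  pass2 <- score_cohort(reassay_records, policy, pass_index = 2L, ...)

  still <- unique(pass2$sample_id[pass2$informative != "INFORMATIVE"])
  genes <- unique(pass2$gene)
  summary <- do.call(rbind, lapply(genes, function(g) {
    before <- pass1[pass1$gene == g & pass1$sample_id %in% noninf, ,
                    drop = FALSE]
    after <- pass2[pass2$gene == g & pass2$informative == "INFORMATIVE", ,
                   drop = FALSE]
    data.frame(
      gene = g,
      n_reanalyzed = length(unique(pass2$sample_id[pass2$gene == g])),
      rate_before = if (nrow(before)) positive_rate(before$call) else NA_real_,
      rate_after = if (nrow(after)) positive_rate(after$call) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(results = pass2, summary = summary,
                 still_non_informative = still),
            class = "reanalysis")
}

#' @export
print.reanalysis <- function(x, ...) {
  cat("Re-analysis of non-informative samples\n")
  if (!nrow(x$summary)) {
    cat("  (no non-informative samples; nothing re-analysed)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-8s n=%d  positive rate %.1f%% -> %.1f%%\n",
                s$gene, s$n_reanalyzed, s$rate_before, s$rate_after))
  }
  if (length(x$still_non_informative)) {
    cat("  still non-informative after boost:",
        length(x$still_non_informative), "sample(s)\n")
  }
  invisible(x)
}
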