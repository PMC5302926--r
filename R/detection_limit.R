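#' Estimate the methylated-template detection limit of an assay
#'
#' Implements the full-replicate rule: the detection limit is the smallest
#' net methylated-DNA amount present in the dilution array such that every
#' condition at or above that amount — across all carrier-DNA and buffer
#' backgrounds — was detected in the entire replicate set (`FULL`).
#' Conditions below the limit may show any behaviour (stochastic dropout is
#' expected there).  No interpolation between dilution steps is performed:
#' the limit is always an amount that was actually tested.
#'
#' @param measurements Long-format array measurements (one row per
#'   condition and gene) with columns `net_meth_ng`, `gene` and `detection`
#'   (`FULL`/`PARTIAL`/`NONE`); see [reference_dilution_array()] and
#'   [simulate_dilution_array()].
#' @param gene Target gene to estimate the limit for.
#'
#' @return An object of class `"detection_limit"`: a list with `gene`,
#'   `limit_ng`, `n_conditions_at_limit` and `conditions` (the
#'   `(net_meth_ng, detection)` pairs considered).
#' @export
#' @examples
#' arr <- reference_dilution_array()
#' estimate_detection_limit(arr, "GFRA1")$limit_ng  # 0.15
estimate_detection_limit <- function(measurements, gene) {
  stopifnot(is.data.frame(measurements),
            all(c("net_meth_ng", "gene", "detection") %in% names(measurements)))
  m <- measurements[measurements$gene == gene, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for gene ", gene)
  if (length(unique(m$net_meth_ng)) < 2L) {
    stop("need at least 2 distinct net methylated amounts")
  }
  if (!all(m$detection %in% c("FULL", "PARTIAL", "NONE"))) {
    stop("detection must be FULL, PARTIAL or NONE")
  }
  amounts <- sort(unique(m$net_meth_ng))
  ok <- vapply(amounts, function(a) {
    all(m$detection[m$net_meth_ng >= a] == "FULL")
  }, logical(1))
  if (!any(ok)) {
    bad <- m[m$detection != "FULL" &
               m$net_meth_ng >= max(amounts), , drop = FALSE]
    err <- structure(
      class = c("methylgate_no_limit_error", "error", "condition"),
      list(message = paste0(
             "no reliable detection limit for ", gene,
             ": replicate dropout persists at the largest tested amount (",
             format(max(amounts)), " ng)"),
           call = sys.call(-1),
           offending = bad)
    )
    stop(err)
  }
  limit <- min(amounts[ok])
  structure(
    list(gene = gene,
         limit_ng = limit,
         n_conditions_at_limit = sum(m$net_meth_ng == limit),
         conditions = m[order(m$net_meth_ng),
                        c("net_meth_ng", "detection"), drop = FALSE]),
    class = "detection_limit"
  )
}

#' @export
print.detection_limit <- function(x, ...) {
  cat("Detection limit (full-replicate rule)\n")
  cat("  gene:            ", x$gene, "\n")
  cat("  limit:           ", format(x$limit_ng), "ng methylated DNA/reaction\n")
  cat("  conditions at limit:", x$n_conditions_at_limit, "\n")
  invisible(x)
}

#' Derive a minimum input-template (TAIT) gating policy
#'
#' Turns a detection limit into an operational gating rule.  If at least a
#' fraction `cutoff_fraction` of a sample's alleles must be methylated for
#' the sample to count as positive, then a reaction containing
#' `limit_ng / cutoff_fraction` ng of total bisulfite DNA still carries the
#' limit amount of methylated template at the cutoff — the minimum TAIT.
#' The reference-gene Ct threshold equivalent to that amount is read from a
#' standard series of (total ng, mean reference Ct) points: the point whose
#' amount is within 5% of the minimum TAIT is used directly (matching bench
#' practice of reading the threshold off the nearest dilution row);
#' otherwise the Ct is linearly interpolated against log2(amount).  The
#' total DNA requirement is the minimum TAIT times the number of reactions
#' the protocol runs per sample, rounded up to whole nanograms.
#'
#' @param limit A `"detection_limit"` object, or a single numeric ng value.
#' @param cutoff_fraction Methylated-allele proportion defining a positive
#'   sample, in (0, 1); e.g. 0.016.
#' @param n_reactions Reactions per sample the DNA must cover (targets plus
#'   reference), >= 1.
#' @param standard_points Data frame with columns `total_ng` and
#'   `mean_ref_ct` (e.g. [standard_points()]).  May be empty, in which case
#'   no Ct threshold is assigned.
#'
#' @return An object of class `"tait_policy"`: list with
#'   `detection_limit_ng`, `cutoff_fraction`, `min_tait_ng` (full
#'   precision; print shows 1 decimal), `ct_threshold` (1 decimal),
#'   `n_reactions` and `total_requirement_ng`.
#' @export
#' @examples
#' arr <- reference_dilution_array()
#' lim <- estimate_detection_limit(arr, "GFRA1")
#' derive_policy(lim, 0.016, 4, standard_points(arr))
derive_policy <- function(limit, cutoff_fraction, n_reactions = 1L,
                          standard_points = NULL) {
  limit_ng <- if (inherits(limit, "detection_limit")) limit$limit_ng
              else as.numeric(limit)
  stopifnot(is.numeric(limit_ng), length(limit_ng) == 1L, limit_ng > 0)
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 ||
      cutoff_fraction > 1) {
    stop("cutoff_fraction must lie in (0, 1]")
  }
  n_reactions <- as.integer(n_reactions)
  stopifnot(n_reactions >= 1L)

  min_tait <- limit_ng / cutoff_fraction

  ct_threshold <- NA_real_
  if (!is.null(standard_points) && nrow(standard_points) > 0L) {
    stopifnot(all(c("total_ng", "mean_ref_ct") %in% names(standard_points)))
    sp <- standard_points[order(standard_points$total_ng), , drop = FALSE]
    if (is.unsorted(rev(sp$mean_ref_ct))) {
      warning("standard points are not monotone (Ct should decrease with ",
              "amount); interpolating on log2(amount) anyway")
    }
    rel <- abs(sp$total_ng - min_tait) / min_tait
    if (min(rel) <= 0.05) {
      ct <- sp$mean_ref_ct[which.min(rel)]
    } else if (nrow(sp) >= 2L) {
      ct <- approx(log2(sp$total_ng), sp$mean_ref_ct,
                   xout = log2(min_tait), rule = 2)$y
    } else {
      ct <- sp$mean_ref_ct[[1L]]
    }
    ct_threshold <- round_dec(ct, 1)
  }

  structure(
    list(detection_limit_ng = limit_ng,
         cutoff_fraction = cutoff_fraction,
         min_tait_ng = min_tait,
         ct_threshold = ct_threshold,
         n_reactions = n_reactions,
         total_requirement_ng = ceiling(min_tait * n_reactions)),
    class = "tait_policy"
  )
}

#' @export
print.tait_policy <- function(x, ...) {
  cat("Minimum-TAIT gating policy\n")
  cat("  detection limit:   ", format(x$detection_limit_ng),
      "ng methylated DNA/reaction\n")
  cat("  cutoff fraction:   ", sprintf("%.1f%%", 100 * x$cutoff_fraction), "\n")
  cat("  minimum TAIT:      ", sprintf("%.1f", round_dec(x$min_tait_ng, 1)),
      "ng/reaction\n")
  if (!is.na(x$ct_threshold)) {
    cat("  reference Ct gate:  Ct <=", sprintf("%.1f", x$ct_threshold), "\n")
  } else {
    cat("  reference Ct gate:  (no standard points supplied)\n")
  }
  cat("  total DNA required:", x$total_requirement_ng, "ng for",
      x$n_reactions, "reaction(s)\n")
  invisible(x)
}

#' Write / read a gating policy as a key-value file
#'
#' Plain `key=value` text so a policy derived once can be shared between
#' runs and consumed by the command-line interface.
#'
#' @param policy A `"tait_policy"`.
#' @param path File path.
#' @return `write_policy`: `path` invisibly; `read_policy`: the policy.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "tait_policy"))
  fields <- c("detection_limit_ng", "cutoff_fraction", "min_tait_ng",
              "ct_threshold", "n_reactions", "total_requirement_ng")
  lines <- vapply(fields, function(f) {
    paste0(f, "=", format(policy[[f]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(
    lapply(kv, function(p) suppressWarnings(as.numeric(trimws(p[[2L]])))),
    vapply(kv, function(p) trimws(p[[1L]]), character(1))
  )
  structure(
    list(detection_limit_ng = vals$detection_limit_ng,
         cutoff_fraction = vals$cutoff_fraction,
         min_tait_ng = vals$min_tait_ng,
         ct_threshold = vals$ct_threshold,
         n_reactions = as.integer(vals$n_reactions),
         total_requirement_ng = vals$total_requirement_ng),
    class = "tait_policy"
  )
}
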