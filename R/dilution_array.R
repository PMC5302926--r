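#' Parse dilution fractions written as "1/4"
#'
#' Dilution axes are conventionally written as retained fractions
#' ("1", "1/2", ..., "1/64").  Accepts numerics (passed through) or strings
#' of the form `"a/b"` or `"a"`.
#'
#' @param x Numeric or character vector.
#' @return Numeric vector of fractions in (0, 1].
#' @export
parse_fraction <- function(x) {
  if (is.numeric(x)) {
    frac <- x
  } else {
    frac <- vapply(as.character(x), function(s) {
      s <- trimws(s)
      if (grepl("^[0-9]+\\s*/\\s*[0-9]+$", s)) {
        parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1L]])
        parts[1L] / parts[2L]
      } else {
        v <- suppressWarnings(as.numeric(s))
        if (is.na(v)) stop("cannot parse dilution fraction: ", s)
        v
      }
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (any(!is.finite(frac)) || any(frac <= 0) || any(frac > 1)) {
    stop("dilution fractions must lie in (0, 1]")
  }
  frac
}

#' Decimal rounding as printed
#'
#' Rounds the exact binary value of `x` to `digits` decimal places, the way
#' `sprintf` formats numbers.  This differs from [base::round()] for values
#' whose decimal literal looks like a half-way tie but whose binary64
#' representation is not (e.g. `1.18/4` prints as 0.29, not 0.30): bench
#' tables are produced by printing, so the printed convention is the one a
#' dilution-array report must reproduce.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @keywords internal
round_dec <- function(x, digits) {
  out <- as.numeric(sprintf("%.*f", as.integer(digits), x))
  out[is.na(x)] <- NA_real_
  out
}

#' Rounding convention for DNA amounts
#'
#' Amounts are reported to 2 decimals; amounts whose 2-decimal rounding
#' falls below 0.01 ng are reported to 3 decimals instead so that the
#' smallest dilution steps remain distinguishable (0.005, 0.002 ng).
#'
#' @param x Amounts in ng.
#' @return Rounded amounts.
#' @keywords internal
round_amount <- function(x) {
  r2 <- round_dec(x, 2)
  small <- !is.na(r2) & r2 < 0.01
  r2[small] <- round_dec(x[small], 3)
  r2
}

#' Build a two-axis serial dilution array
#'
#' Designs the template array used to characterise a methylation assay's
#' detection limit: a fully methylated DNA stock is first diluted with
#' unmethylated carrier DNA at the same concentration (changing the
#' methylated fraction but not the total DNA per reaction), and each of
#' those mixtures is further diluted with TE buffer (changing the total and
#' the net methylated amount by the same factor, leaving the methylated
#' percentage unchanged).
#'
#' @param base_total_ng Total DNA per reaction in the undiluted condition
#'   (ng).
#' @param base_net_ng Methylated-cell DNA per reaction in the undiluted
#'   condition (ng); must not exceed `base_total_ng`.
#' @param meth_dilutions Fractions of methylated stock retained on the
#'   carrier-DNA axis, e.g. `c("1","1/2","1/4",...)` or numerics.
#' @param te_dilutions Fractions of total DNA retained on the buffer axis.
#' @return Data frame with one row per condition (Cartesian product of the
#'   axes): exact columns `total_ng`, `net_meth_ng`, `meth_pct` and printed
#'   columns `total_ng_printed`, `net_meth_ng_printed` (2 decimals, 3 below
#'   0.01 ng) and `meth_pct_printed` (1 decimal).
#' @export
#' @examples
#' a <- build_array(18.78, 1.18, c(1, 1/2, 1/4), c(1, 1/2))
#' subset(a, meth_dilution == 1/4 & te_dilution == 1/2)
build_array <- function(base_total_ng, base_net_ng,
                        meth_dilutions, te_dilutions) {
  stopifnot(is.numeric(base_total_ng), base_total_ng > 0,
            is.numeric(base_net_ng), base_net_ng >= 0)
  if (base_net_ng > base_total_ng) {
    stop("net methylated amount cannot exceed total DNA amount")
  }
  meth <- parse_fraction(meth_dilutions)
  te <- parse_fraction(te_dilutions)
  grid <- expand.grid(meth_dilution = meth, te_dilution = te,
                      KEEP.OUT.ATTRS = FALSE)
  total <- base_total_ng * grid$te_dilution
  net <- base_net_ng * grid$meth_dilution * grid$te_dilution
  pct <- 100 * net / total
  data.frame(
    meth_dilution = grid$meth_dilution,
    te_dilution = grid$te_dilution,
    total_ng = total,
    net_meth_ng = net,
    meth_pct = pct,
    total_ng_printed = round_amount(total),
    net_meth_ng_printed = round_amount(net),
    meth_pct_printed = round_dec(pct, 1),
    stringsAsFactors = FALSE
  )
}

#' DNA amount delivered to one reaction
#'
#' @param conc_ng_per_ul Working-solution concentration (ng/uL), > 0.
#' @param aliquot_ul Volume pipetted into the reaction (uL), > 0.
#' @return Nanograms per reaction.
#' @export
#' @examples
#' reaction_volume_amount(10, 1.7)  # 17 ng
reaction_volume_amount <- function(conc_ng_per_ul, aliquot_ul) {
  if (!is.numeric(conc_ng_per_ul) || any(conc_ng_per_ul <= 0)) {
    stop("concentration must be positive")
  }
  if (!is.numeric(aliquot_ul) || any(aliquot_ul <= 0)) {
    stop("aliquot volume must be positive")
  }
  conc_ng_per_ul * aliquot_ul
}

#' Bundled reference dilution array
#'
#' Loads the packaged measurement of a GFRA1/P16 MethyLight dilution array:
#' bisulfite-treated DNA from the fully methylated RKO cell line serially
#' diluted with unmethylated GES1 DNA (seven steps, 1 to 1/64) and with TE
#' buffer (four steps, 1 to 1/8), assayed in triplicate against the COL2A1
#' input reference.  Detection flags per target gene encode the triplicate
#' outcome: `FULL` (determined in all three wells), `PARTIAL` (undetermined
#' in one or two), `NONE` (undetermined in all three).
#'
#' @return A data frame with one row per (condition, gene): columns
#'   `meth_dilution`, `te_dilution`, `total_ng`, `net_meth_ng`, `meth_pct`,
#'   `gene`, `role`, `mean_ct`, `detection`.
#' @export
reference_dilution_array <- function() {
  path <- system.file("extdata", "gfra1_p16_dilution_array.csv",
                      package = "methylgate", mustWork = TRUE)
  raw <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    strip.white = TRUE)
  cond <- data.frame(
    meth_dilution = parse_fraction(raw$meth_dilution),
    te_dilution = parse_fraction(raw$te_dilution),
    total_ng = raw$total_ng,
    net_meth_ng = raw$net_meth_ng,
    meth_pct = raw$meth_pct,
    stringsAsFactors = FALSE
  )
  genes <- list(
    list(gene = "COL2A1", role = "REFERENCE",
         ct = raw$ct_col2a1, det = rep("FULL", nrow(raw))),
    list(gene = "GFRA1", role = "TARGET",
         ct = raw$ct_gfra1, det = raw$gfra1_detection),
    list(gene = "P16", role = "TARGET",
         ct = raw$ct_p16, det = raw$p16_detection)
  )
  out <- do.call(rbind, lapply(genes, function(g) {
    cbind(cond,
          data.frame(gene = g$gene, role = g$role,
                     mean_ct = suppressWarnings(as.numeric(g$ct)),
                     detection = g$det, stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Reference-gene standard points from an array measurement
#'
#' Extracts (total DNA, mean reference Ct) pairs for use as a standard
#' curve in [derive_policy()].  By default only the conditions without
#' carrier-DNA dilution are used (one condition per total amount), matching
#' the usual practice of reading the Ct threshold off the pure
#' buffer-dilution series.
#'
#' @param measurements Long-format array measurements as returned by
#'   [reference_dilution_array()] or [simulate_dilution_array()].
#' @param reference_gene Reference gene name (default `"COL2A1"`).
#' @param meth_dilution_only Retain only rows at this methylated-stock
#'   fraction (default 1, i.e. no carrier dilution); `NULL` averages across
#'   all carrier dilutions at each total amount.
#' @return Data frame with columns `total_ng`, `mean_ref_ct`, sorted by
#'   decreasing total amount.
#' @export
standard_points <- function(measurements, reference_gene = "COL2A1",
                            meth_dilution_only = 1) {
  m <- measurements[measurements$gene == reference_gene, , drop = FALSE]
  if (!nrow(m)) stop("no rows for reference gene ", reference_gene)
  if (!is.null(meth_dilution_only)) {
    m <- m[m$meth_dilution == meth_dilution_only, , drop = FALSE]
  }
  agg <- aggregate(m["mean_ct"], by = m["total_ng"], FUN = mean)
  out <- data.frame(total_ng = agg$total_ng, mean_ref_ct = agg$mean_ct)
  out[order(-out$total_ng), , drop = FALSE]
}
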