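#' Simulator parameterisation for a bisulfite-template qPCR assay
#'
#' The simulator is a single-molecule sampling model.  A reaction loaded
#' with `total_ng` of bisulfite DNA contains on average
#' `total_ng / ng_per_copy` amplifiable copies of the reference amplicon
#' (for a target amplicon, multiplied by the methylated fraction).  The
#' realised copy number is Poisson; each copy independently survives
#' bisulfite damage, strand loss and priming with probability `p_amp`.
#' Zero surviving copies give an undetermined well; otherwise
#' `Ct = ct_at_one_copy - log(K) / log(efficiency) + N(0, sigma_ct)`,
#' and a Ct beyond `max_cycles` is also undetermined.
#'
#' Defaults are calibrated once against the bundled reference dilution
#' array ([reference_dilution_array()]): `ng_per_copy = 0.0066`
#' (one haploid genome ~3.3 pg, a single strand amplifiable after
#' conversion), `efficiency = 1.74` (the reference-Ct column spans ~1.25
#' cycles per 2-fold step), `p_amp = 0.22` (places the 5-copy
#' reliable-detection point at 0.15 ng methylated DNA) and
#' `ct_at_one_copy = 39.7` (intercept reproducing the reference Ct 27.9 at
#' 18.78 ng).  They are calibration, not ground truth.
#'
#' @param ng_per_copy Bisulfite-template mass per amplifiable target copy
#'   (ng), > 0.
#' @param p_amp Per-molecule probability of successful amplification, in
#'   (0, 1].
#' @param efficiency Per-cycle amplification factor, in (1, 2].
#' @param ct_at_one_copy Ct intercept at a single effective copy.
#' @param sigma_ct Gaussian replicate noise on Ct, >= 0.
#' @param max_cycles Run length; later signals are undetermined.
#' @return List of class `"assay_sim_params"`.
#' @export
assay_sim_params <- function(ng_per_copy = 0.0066, p_amp = 0.22,
                             efficiency = 1.74, ct_at_one_copy = 39.7,
                             sigma_ct = 0.25, max_cycles = 40) {
  stopifnot(ng_per_copy > 0,
            p_amp > 0, p_amp <= 1,
            efficiency > 1, efficiency <= 2,
            sigma_ct >= 0, max_cycles > 0)
  structure(list(ng_per_copy = ng_per_copy, p_amp = p_amp,
                 efficiency = efficiency, ct_at_one_copy = ct_at_one_copy,
                 sigma_ct = sigma_ct, max_cycles = max_cycles),
            class = "assay_sim_params")
}

#' Analytic detection probability at low template
#'
#' Closed-form companion of the simulator: a reaction with Poisson mean
#' `lambda` template copies, each amplifying with probability `p_amp`,
#' is detected unless zero copies survive, so
#' `P(detected) = 1 - exp(-lambda * p_amp)`.
#'
#' @param lambda Mean template copies per reaction, >= 0.
#' @param p_amp Per-molecule amplification probability.
#' @return Detection probability in `[0, 1]`.
#' @export
#' @examples
#' detection_probability(log(2), 1)  # 0.5
detection_probability <- function(lambda, p_amp) {
  stopifnot(all(lambda >= 0), all(p_amp >= 0), all(p_amp <= 1))
  -expm1(-lambda * p_amp)
}

# derive a deterministic substream seed from a master seed and an index,
# kept within 32-bit signed range
substream_seed <- function(seed, index) {
  ((as.numeric(seed) %% 2147480009) * 31 + index * 10007) %% 2147483647 + 1
}

#' Simulate qPCR reactions at a given template load
#'
#' Draws `n` replicate wells from the single-molecule model in
#' [assay_sim_params()].  Uses the current RNG stream; wrap in
#' [withr::with_seed()]-style seeding or use the higher-level generators
#' ([simulate_dilution_array()], [simulate_cohort()]) for reproducible
#' plates.
#'
#' @param n Number of wells.
#' @param total_ng Total bisulfite DNA loaded per reaction (ng), >= 0.
#' @param meth_fraction Methylated-allele fraction in `[0, 1]`; ignored for
#'   the reference role.
#' @param gene_role `"REFERENCE"` (amplifies all templates) or `"TARGET"`
#'   (amplifies only methylated templates).
#' @param params An [assay_sim_params()].
#' @return Numeric vector of Ct values, `NA` = undetermined.
#' @export
simulate_reactions <- function(n, total_ng, meth_fraction = 1,
                               gene_role = c("TARGET", "REFERENCE"),
                               params = assay_sim_params()) {
  gene_role <- match.arg(gene_role)
  stopifnot(total_ng >= 0, meth_fraction >= 0, meth_fraction <= 1,
            inherits(params, "assay_sim_params"))
  frac <- if (gene_role == "REFERENCE") 1 else meth_fraction
  lambda <- total_ng / params$ng_per_copy * frac
  copies <- rpois(n, lambda)
  k <- rbinom(n, copies, params$p_amp)
  ct <- rep(NA_real_, n)
  det <- k > 0
  if (any(det)) {
    ct[det] <- params$ct_at_one_copy -
      log(k[det]) / log(params$efficiency) +
      rnorm(sum(det), 0, params$sigma_ct)
    ct[det][ct[det] > params$max_cycles] <- NA_real_
  }
  ct
}

#' @rdname simulate_reactions
#' @param sample_id,gene,replicate Identifiers for the single-well variant,
#'   which returns a one-row reaction-record data frame.
#' @export
simulate_reaction <- function(total_ng, meth_fraction = 1,
                              gene_role = c("TARGET", "REFERENCE"),
                              params = assay_sim_params(),
                              sample_id = "sim", gene = "SIM",
                              replicate = 1L) {
  gene_role <- match.arg(gene_role)
  ct <- simulate_reactions(1L, total_ng, meth_fraction, gene_role, params)
  data.frame(sample_id = sample_id, gene = gene, role = gene_role,
             replicate = as.integer(replicate), ct = ct,
             input_ng = total_ng, stringsAsFactors = FALSE)
}

#' Simulate a two-axis dilution-array measurement
#'
#' Generates the in-silico counterpart of [reference_dilution_array()]:
#' for every condition of [build_array()], the reference gene sees the
#' total DNA and each target gene sees only the net methylated DNA (the
#' unmethylated carrier contributes to the reference but not the target).
#' Per-condition RNG substreams are derived from the master seed, so the
#' measurement is reproducible regardless of evaluation order.
#'
#' @param base_total_ng,base_net_ng,meth_dilutions,te_dilutions As in
#'   [build_array()].
#' @param replicates Wells per condition and gene (>= 3 recommended).
#' @param params A single [assay_sim_params()] applied to every gene, or a
#'   named list of params keyed by gene name (reference included).
#' @param target_genes Names of the simulated target genes.
#' @param reference_gene Name of the reference gene.
#' @param seed Master seed (integer).
#' @return Long data frame matching [reference_dilution_array()]:
#'   condition columns plus `gene`, `role`, `mean_ct`, `detection`,
#'   `n_detected`, `n_total`.
#' @export
simulate_dilution_array <- function(base_total_ng, base_net_ng,
                                    meth_dilutions, te_dilutions,
                                    replicates = 3L,
                                    params = assay_sim_params(),
                                    target_genes = "GFRA1",
                                    reference_gene = "COL2A1",
                                    seed = 1L) {
  conditions <- build_array(base_total_ng, base_net_ng,
                            meth_dilutions, te_dilutions)
  genes <- c(setNames("REFERENCE", reference_gene),
             setNames(rep("TARGET", length(target_genes)), target_genes))
  params_for <- function(g) {
    if (inherits(params, "assay_sim_params")) params
    else if (!is.null(params[[g]])) params[[g]]
    else stop("no simulation params for gene ", g)
  }
  rows <- vector("list", nrow(conditions) * length(genes))
  k <- 0L
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    for (j in seq_along(genes)) {
      g <- names(genes)[[j]]
      role <- genes[[j]]
      k <- k + 1L
      set.seed(substream_seed(seed, (i - 1L) * length(genes) + j))
      frac <- if (role == "REFERENCE") 1 else {
        if (cond$total_ng > 0) cond$net_meth_ng / cond$total_ng else 0
      }
      ct <- simulate_reactions(replicates, cond$total_ng, frac, role,
                               params_for(g))
      n_det <- sum(!is.na(ct))
      rows[[k]] <- data.frame(
        meth_dilution = cond$meth_dilution,
        te_dilution = cond$te_dilution,
        total_ng = cond$total_ng,
        net_meth_ng = cond$net_meth_ng,
        meth_pct = cond$meth_pct,
        gene = g, role = role,
        mean_ct = if (n_det) mean(ct, na.rm = TRUE) else NA_real_,
        detection = if (n_det == replicates) "FULL"
                    else if (n_det == 0L) "NONE" else "PARTIAL",
        n_detected = n_det, n_total = replicates,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a patient cohort with TAIT-dependent dropout
#'
#' Generates per-sample plate records (reference plus target triplicates)
#' and a truth table, emulating cohorts in which the amount of input
#' template varies widely across samples and methylation-negative calls at
#' low input are often false negatives.  FFPE samples are drawn from a
#' lower-DNA regime than frozen samples; the per-reaction input in the
#' first pass is a fixed share of the available extract, i.e. no
#' input-DNA adjustment — exactly the situation the gating policy exists
#' to detect.
#'
#' @param n_samples Number of samples.
#' @param tissue_mix Named probabilities for `FFPE` and `FROZEN`.
#' @param fraction_distribution Function `n -> fractions in [0,1]`: true
#'   methylated-allele fractions.  Default: 70% of samples methylated with
#'   log-normal fractions (median 10%, log-sd 0.8, capped at 1), the rest 0.
#' @param dna_distribution Function `(n, tissue) -> ng` of available
#'   extract.  Default: log-normal, median 50 ng (FFPE) / 300 ng (FROZEN),
#'   log-sd 1.0 / 0.8.
#' @param aliquot_share Fraction of the available extract loaded per
#'   reaction in the unadjusted first pass (default 1/20).
#' @param params [assay_sim_params()] (single, or named list per gene).
#' @param genes Target gene name(s).
#' @param reference_gene Reference gene name.
#' @param replicates Wells per gene and sample.
#' @param seed Master seed; per-sample substreams keep plates reproducible.
#' @return List of class `"sim_cohort"`: `records` (plate data frame in
#'   [read_plate()] format) and `truth` (per sample and gene:
#'   `sample_id`, `tissue_label`, `available_dna_ng`, `input_ng`, `gene`,
#'   `true_meth_fraction`, `truly_methylated`).
#' @export
simulate_cohort <- function(n_samples,
                            tissue_mix = c(FFPE = 0.5, FROZEN = 0.5),
                            fraction_distribution = NULL,
                            dna_distribution = NULL,
                            aliquot_share = 1 / 20,
                            params = assay_sim_params(),
                            genes = "GFRA1",
                            reference_gene = "COL2A1",
                            replicates = 3L,
                            seed = 1L) {
  stopifnot(n_samples >= 1L, aliquot_share > 0, aliquot_share <= 1)
  tissue_mix <- tissue_mix / sum(tissue_mix)
  if (is.null(fraction_distribution)) {
    fraction_distribution <- function(n) {
      ifelse(runif(n) < 0.7, pmin(1, rlnorm(n, log(0.10), 0.8)), 0)
    }
  }
  if (is.null(dna_distribution)) {
    dna_distribution <- function(n, tissue) {
      meanlog <- ifelse(tissue == "FFPE", log(50), log(300))
      sdlog <- ifelse(tissue == "FFPE", 1.0, 0.8)
      rlnorm(n, meanlog, sdlog)
    }
  }
  params_for <- function(g) {
    if (inherits(params, "assay_sim_params")) params
    else if (!is.null(params[[g]])) params[[g]]
    else stop("no simulation params for gene ", g)
  }

  set.seed(substream_seed(seed, 0L))
  tissue <- sample(names(tissue_mix), n_samples, replace = TRUE,
                   prob = tissue_mix)
  available <- dna_distribution(n_samples, tissue)
  fractions <- matrix(nrow = n_samples, ncol = length(genes),
                      dimnames = list(NULL, genes))
  for (g in genes) fractions[, g] <- fraction_distribution(n_samples)
  input_ng <- available * aliquot_share

  ids <- sprintf("S%0*d", nchar(as.character(n_samples)), seq_len(n_samples))
  rec_list <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    set.seed(substream_seed(seed, i))
    ref_ct <- simulate_reactions(replicates, input_ng[i], 1, "REFERENCE",
                                 params_for(reference_gene))
    gene_ct <- lapply(genes, function(g) {
      simulate_reactions(replicates, input_ng[i], fractions[i, g], "TARGET",
                         params_for(g))
    })
    rec_list[[i]] <- data.frame(
      sample_id = ids[i],
      gene = rep(c(reference_gene, genes), each = replicates),
      role = rep(c("REFERENCE", rep("TARGET", length(genes))),
                 each = replicates),
      replicate = rep(seq_len(replicates), 1L + length(genes)),
      ct = c(ref_ct, unlist(gene_ct)),
      input_ng = input_ng[i],
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  truth <- do.call(rbind, lapply(genes, function(g) {
    data.frame(sample_id = ids, tissue_label = tissue,
               available_dna_ng = available, input_ng = input_ng,
               gene = g, true_meth_fraction = fractions[, g],
               truly_methylated = fractions[, g] > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(records = records, truth = truth,
                 genes = genes, reference_gene = reference_gene,
                 replicates = replicates, params = params, seed = seed),
            class = "sim_cohort")
}

#' Simulate the boosted-input re-assay of selected samples
#'
#' Re-draws reactions for the given samples with the per-reaction input
#' raised to `boost_factor` times the policy's minimum TAIT, keeping each
#' sample's true methylated fraction from the cohort truth table.
#'
#' @param cohort A `"sim_cohort"`.
#' @param sample_ids Samples to re-assay (typically the pass-1
#'   non-informative set).
#' @param policy The `"tait_policy"` in force.
#' @param boost_factor Multiple of `min_tait_ng` loaded per reaction
#'   (default 2: comfortably above the gate).
#' @param seed Master seed for the re-assay plate.
#' @return Plate records data frame for the re-assay.
#' @export
simulate_reassay <- function(cohort, sample_ids, policy, boost_factor = 2,
                             seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(policy, "tait_policy"),
            boost_factor > 0)
  truth <- cohort$truth[cohort$truth$sample_id %in% sample_ids, ,
                        drop = FALSE]
  if (!nrow(truth)) {
    return(cohort$records[0, , drop = FALSE])
  }
  boost_ng <- policy$min_tait_ng * boost_factor
  replicates <- cohort$replicates
  params_for <- function(g) {
    if (inherits(cohort$params, "assay_sim_params")) cohort$params
    else cohort$params[[g]]
  }
  ids <- unique(truth$sample_id)
  rec_list <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    set.seed(substream_seed(seed, 500000L + i))
    tr <- truth[truth$sample_id == id, , drop = FALSE]
    ref_ct <- simulate_reactions(replicates, boost_ng, 1, "REFERENCE",
                                 params_for(cohort$reference_gene))
    gene_ct <- lapply(seq_len(nrow(tr)), function(j) {
      simulate_reactions(replicates, boost_ng, tr$true_meth_fraction[j],
                         "TARGET", params_for(tr$gene[j]))
    })
    data.frame(
      sample_id = id,
      gene = rep(c(cohort$reference_gene, tr$gene), each = replicates),
      role = rep(c("REFERENCE", rep("TARGET", nrow(tr))), each = replicates),
      replicate = rep(seq_len(replicates), 1L + nrow(tr)),
      ct = c(ref_ct, unlist(gene_ct)),
      input_ng = boost_ng,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rec_list)
  rownames(out) <- NULL
  out
}
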