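# shared fixtures and independent oracles for the test suite

# write a small plate file and return its path
write_test_plate <- function(lines, sep = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

plate_lines <- function(rows) {
  c("sample_id,gene,role,replicate,ct", rows)
}

# brute-force oracle for the detection limit: try every tested amount as a
# candidate and verify the post-condition directly, condition by condition
oracle_detection_limit <- function(net, detection) {
  amounts <- sort(unique(net))
  for (a in amounts) {
    all_full <- TRUE
    for (i in seq_along(net)) {
      if (net[i] >= a && detection[i] != "FULL") all_full <- FALSE
    }
    if (all_full) return(a)
  }
  NA_real_
}

# random dilution-array measurement for property tests
random_array <- function(n_conditions) {
  net <- round(stats::runif(n_conditions, 0.001, 2), 4)
  detection <- sample(c("FULL", "PARTIAL", "NONE"), n_conditions,
                      replace = TRUE, prob = c(0.6, 0.25, 0.15))
  data.frame(net_meth_ng = net, gene = "G", detection = detection,
             stringsAsFactors = FALSE)
}

# textbook Pearson chi-square formula, written out longhand
oracle_chi_square <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# independent U statistic: count of (a, b) pairs with a > b, ties as 1/2
oracle_u_pairs <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_u_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  mu <- n_a * length(b) / 2
  u_obs <- oracle_u_pairs(a, b)
  combs <- utils::combn(n, n_a)
  us <- apply(combs, 2, function(idx) {
    oracle_u_pairs(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# canonical two-axis design shared across tests
table_axes <- list(
  meth = c("1", "1/2", "1/4", "1/8", "1/16", "1/32", "1/64"),
  te = c("1", "1/2", "1/4", "1/8")
)

reference_policy <- function() {
  arr <- reference_dilution_array()
  derive_policy(estimate_detection_limit(arr, "GFRA1"), 0.016, 4,
                standard_points(arr))
}
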