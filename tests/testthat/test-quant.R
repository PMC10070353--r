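tmt3 <- plex_design("p1", c("c1", "c2", "c3"))

zero_coa <- function(channels)
  data.frame(channel = channels, minus2 = 0, minus1 = 0, plus1 = 0,
             plus2 = 0, stringsAsFactors = FALSE)

random_coa <- function(channels, seed) {
  set.seed(seed)
  n <- length(channels)
  data.frame(channel = channels,
             minus2 = runif(n, 0, 0.5), minus1 = runif(n, 0, 2.5),
             plus1 = runif(n, 0, 7), plus2 = runif(n, 0, 0.8),
             stringsAsFactors = FALSE)
}

test_that("impurity matrix construction follows the series order", {
  expect_equal(unclass(build_impurity_matrix(zero_coa(tmt3$channels), tmt3)),
               diag(3), ignore_attr = TRUE)
  coa <- zero_coa(tmt3$channels)
  coa$plus1[1] <- 5
  M <- build_impurity_matrix(coa, tmt3)
  expect_equal(unname(M[, 1]), c(0.95, 0.05, 0))
  expect_equal(unname(M[, 2]), c(0, 1, 0))
  bad <- zero_coa(tmt3$channels); bad$plus1[2] <- 100
  expect_error(build_impurity_matrix(bad, tmt3), ">= 100%")
})

test_that("impurity columns conserve signal up to out-of-plex spill", {
  ch <- paste0("ch", 1:8)
  des <- plex_design("p", ch)
  for (seed in 1:10) {
    coa <- random_coa(ch, seed)
    M <- build_impurity_matrix(coa, des)
    for (j in seq_along(ch)) {
      row <- coa[j, ]
      spill <- 0
      if (j - 2 < 1) spill <- spill + row$minus2
      if (j - 1 < 1) spill <- spill + row$minus1
      if (j + 1 > 8) spill <- spill + row$plus1
      if (j + 2 > 8) spill <- spill + row$plus2
      expect_equal(sum(M[, j]), 1 - spill / 100, tolerance = 1e-12)
    }
  }
})

test_that("Cramer correction inverts forward mixing to machine precision", {
  expect_equal(unname(correct_reporters(c(3, 5, 7),
                                        build_impurity_matrix(
                                          zero_coa(tmt3$channels), tmt3))),
               c(3, 5, 7), ignore_attr = TRUE)
  ch <- paste0("ch", 1:10)
  des <- plex_design("p", ch)
  for (seed in 1:8) {
    M <- build_impurity_matrix(random_coa(ch, seed), des)
    set.seed(seed)
    x <- runif(10, 1e3, 1e6)
    obs <- as.numeric(unclass(M) %*% x)
    got <- correct_reporters(obs, M)
    expect_lt(max(abs(got - x) / x), 1e-10)
    # Cramer's rule agrees with the generic linear solver
    expect_lt(max(abs(got - solve(unclass(M), obs))), 1e-9 * max(x))
  }
})

test_that("negative corrected components are clamped and flagged", {
  coa <- zero_coa(tmt3$channels)
  coa$plus1 <- c(8, 8, 0)
  M <- build_impurity_matrix(coa, tmt3)
  # channel 2 sees spill from channel 1 but has almost no own signal
  got <- correct_reporters(c(1000, 10, 500), M)
  expect_true(attr(got, "clamped"))
  expect_true(all(got >= 0))
  expect_error(correct_reporters(c(1, 2, 3), matrix(1, 3, 3)), "singular")
})

test_that("the PSM quantitation filter applies the documented boundaries", {
  p <- psm_table(
    psm_row("keep", purity_pct = 50.0, delta_fr_score = 0.0),
    psm_row("lowpure", purity_pct = 49.9),
    psm_row("negfr", delta_fr_score = -0.1),
    psm_row("nolabel", tmt_labeled = FALSE))
  expect_identical(p$spectrum_id[psm_quant_filter(p)], "keep")
})

test_that("log2 ratios follow the denominator policy and zero handling", {
  v <- c(c1 = 100, c2 = 100, c3 = 100)
  expect_equal(unname(psm_log_ratios(v)), c(0, 0, 0))
  expect_equal(unname(psm_log_ratios(v, "reference-channel", "c1")),
               c(0, 0, 0))
  v2 <- c(c1 = 100, c2 = 200, c3 = 0)
  r <- psm_log_ratios(v2, "reference-channel", "c1")
  expect_equal(unname(r[2]), 1.0)
  expect_true(is.na(r[3]))
  r2 <- psm_log_ratios(c(c1 = 50, c2 = 100, c3 = 200))
  expect_equal(unname(r2), c(-1, 0, 1))
  z <- psm_log_ratios(c(c1 = 0, c2 = 0))
  expect_true(all(is.na(z)) && attr(z, "flagged"))
})

test_that("feature aggregation is the per-channel median with counts", {
  ratios <- rbind(c(1, 1), c(3, 2), c(NA, 9))
  colnames(ratios) <- c("c1", "c2")
  agg <- aggregate_feature_ratios(ratios, c("f", "f", "f"))
  expect_equal(unname(agg$matrix["f", ]), c(2, 2))
  expect_identical(unname(agg$ratio_counts["f", ]), c(2L, 3L))
  # random groupings against a direct split-median oracle
  set.seed(8)
  r <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("c", 1:6)))
  r[sample(600, 60)] <- NA
  f <- sample(letters[1:9], 100, TRUE)
  agg2 <- aggregate_feature_ratios(r, f)
  for (ff in unique(f)) for (j in 1:6) {
    expect_equal(agg2$matrix[ff, j],
                 median(r[f == ff, j], na.rm = TRUE) + 0,
                 tolerance = 1e-12)
  }
})

test_that("protein reporting requires 2 unique peptides and ratio counts", {
  m <- rbind(one = c(0.5, 0.2), two = c(0.1, -0.3), empty = c(NA, NA))
  colnames(m) <- c("c1", "c2")
  cnt <- rbind(one = c(5L, 5L), two = c(2L, 3L), empty = c(0L, 0L))
  colnames(cnt) <- c("c1", "c2")
  q <- list(matrix = m, ratio_counts = cnt)
  out <- quant_reporting_filter(q, c(one = 1L, two = 2L, empty = 4L))
  expect_identical(rownames(out$matrix), "two")
  empty_q <- list(matrix = m[0, , drop = FALSE],
                  ratio_counts = cnt[0, , drop = FALSE])
  expect_identical(nrow(quant_reporting_filter(empty_q, integer(0))$matrix),
                   0L)
})

test_that("median/MAD normalization centers, equalizes spread, idempotent", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rnorm(40 * 6, mean = runif(1, -2, 2), sd = runif(1, .5, 3)),
                40, 6)
    m[sample(length(m), 30)] <- NA
    n1 <- median_mad_normalize(m)
    meds <- apply(n1, 2, median, na.rm = TRUE)
    expect_lt(max(abs(meds)), 1e-12)
    mads <- apply(n1, 2, function(v)
      median(abs(v - median(v, na.rm = TRUE)), na.rm = TRUE))
    expect_lt(diff(range(mads)), 1e-9)
    expect_identical(is.na(n1), is.na(m))       # missing untouched
    n2 <- median_mad_normalize(n1)
    expect_equal(unclass(n2), unclass(n1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a channel with < 3 observations is centered only and flagged
  m2 <- cbind(a = rnorm(10), b = c(5, NA, rep(NA, 8)))
  n <- median_mad_normalize(m2)
  expect_identical(attr(n, "flagged_channels"), "b")
  expect_equal(unname(n[1, "b"]), 0)
})

test_that("variant features must spike exactly in carrier channels", {
  row <- c(0, 0.1, -0.1, 0, 3, 3.2, 0.05, -0.2)
  carriers <- c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 2))
  expect_true(saav_patient_consistency(row, carriers))
  # a non-carrier spiking as high kills the feature
  row2 <- row; row2[1] <- 3.1
  expect_false(saav_patient_consistency(row2, carriers))
  # a flat carrier kills the feature
  row3 <- row; row3[5] <- 0
  expect_false(saav_patient_consistency(row3, carriers))
  expect_error(saav_patient_consistency(row, rep(FALSE, 8)), "carrier")
})

test_that("the full quant stack recovers known per-feature fold changes", {
  cfg <- synthetic_quant_config(n_features = 40, psms_per_feature = 30)
  d <- generate_quant_dataset(cfg, seed = 5)
  q <- quantify_psms(d$psms, d$design, d$impurity_matrix)
  fc <- quant_fc_estimates(q, d$truth)
  err <- fc$est - fc$tru
  expect_lt(abs(mean(err)), 0.1)
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("co-isolation contamination compresses ratios monotonically", {
  sep <- vapply(c(0, 5e4, 2e5), function(bg) {
    d <- generate_quant_dataset(
      synthetic_quant_config(n_features = 30, psms_per_feature = 20,
                             contamination_intensity = bg), seed = 11)
    q <- quantify_psms(d$psms, d$design, d$impurity_matrix,
                       normalize = FALSE)
    fc <- quant_fc_estimates(q, d$truth)
    mean(fc$est * sign(fc$tru))    # signal magnitude in the true direction
  }, 0)
  expect_true(all(diff(sep) < 0))
  expect_true(all(sep > 0))
})
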