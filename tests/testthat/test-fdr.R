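test_that("estimate_fdr is the decoy/target ratio with defined edges", {
  targets <- psm_table(psm_row("a"), psm_row("b"))
  expect_equal(estimate_fdr(targets), 0)
  p <- do.call(rbind, c(lapply(1:199, function(i) psm_row(paste0("t", i))),
                        list(psm_row("d1", is_decoy = TRUE))))
  expect_equal(estimate_fdr(p), 1 / 199)
  expect_error(estimate_fdr(p[0, ]), "no accepted PSMs")
  expect_error(estimate_fdr(psm_row("d", is_decoy = TRUE)), "no targets")
})

test_that("FDR estimates agree with brute-force counting over sweeps", {
  p <- discrete_mixture(400, seed = 21)
  for (s in c(2, 6, 10)) for (d in c(0, 0.5, 1)) {
    acc <- p[p$score >= s & p$delta_rank_score >= d, ]
    nd <- sum(acc$is_decoy); nt <- sum(!acc$is_decoy)
    if (nt > 0)
      expect_equal(estimate_fdr(acc), nd / nt)
  }
})

test_that("a decoy-free input is fully accepted at minimal thresholds", {
  p <- discrete_mixture(150, seed = 3)
  p$is_decoy <- FALSE
  av <- autovalidate(p, autovalidation_targets("proteome")[1, ])
  acc2 <- sum(p$charge == 2)
  expect_identical(nrow(av$accepted), acc2)
  expect_true(all(av$thresholds$fdr_estimate == 0))
  expect_equal(av$thresholds$min_score, min(p$score))
})

test_that("autovalidation reproduces exhaustive enumeration", {
  tg <- data.frame(bucket = "2", charge_min = 2L, charge_max = 2L,
                   scope = "run", fdr_target = 0.05,
                   stringsAsFactors = FALSE)
  for (seed in 1:10) {
    p <- discrete_mixture(600, seed = seed)
    # candidate levels are few and discrete, so a wide-open quantile grid
    # equals the full unique-value grid and a double loop is the oracle
    av <- autovalidate(p, tg, max_candidates = c(1000L, 1000L))
    o <- brute_force_pair_opt(p$score, p$delta_rank_score, p$is_decoy,
                              0.05, sort(unique(p$score)),
                              sort(unique(p$delta_rank_score)))
    expect_equal(av$thresholds$min_score, o$min_score)
    expect_equal(av$thresholds$min_delta_rank, o$min_delta)
    expect_identical(av$thresholds$n_accepted_targets, o$nt)
    expect_identical(nrow(av$accepted), o$nt + o$nd)
  }
})

test_that("per-run scopes optimize independently and union their optima", {
  p <- discrete_mixture(800, seed = 9, n_runs = 2L)
  tg <- data.frame(bucket = "2", charge_min = 2L, charge_max = 2L,
                   scope = "run", fdr_target = 0.05,
                   stringsAsFactors = FALSE)
  av <- autovalidate(p, tg)
  per_run <- lapply(split(p, p$run_id), function(sub)
    autovalidate(sub, tg)$accepted)
  expect_setequal(av$accepted$spectrum_id,
                  unlist(lapply(per_run, `[[`, "spectrum_id")))
  expect_identical(nrow(av$thresholds), 2L)
})

test_that("raising a threshold never increases accepted counts", {
  p <- discrete_mixture(500, seed = 13)
  ss <- sort(unique(p$score)); dd <- sort(unique(p$delta_rank_score))
  for (k in seq(1, length(ss) - 1, by = 5)) {
    a1 <- p$score >= ss[k]; a2 <- p$score >= ss[k + 1]
    expect_lte(sum(a2 & p$is_decoy), sum(a1 & p$is_decoy))
    expect_lte(sum(a2 & !p$is_decoy), sum(a1 & !p$is_decoy))
  }
  for (k in seq_len(length(dd) - 1)) {
    a1 <- p$delta_rank_score >= dd[k]; a2 <- p$delta_rank_score >= dd[k + 1]
    expect_lte(sum(a2), sum(a1))
  }
})

test_that("autovalidation is invariant to record order", {
  p <- discrete_mixture(400, seed = 31, n_runs = 2L)
  tg <- autovalidation_targets("proteome")
  av1 <- autovalidate(p, tg)
  set.seed(1); av2 <- autovalidate(p[sample(nrow(p)), ], tg)
  expect_setequal(av1$accepted$spectrum_id, av2$accepted$spectrum_id)
  t2 <- av2$thresholds[order(av2$thresholds$scope_id,
                             av2$thresholds$bucket), ]
  t1 <- av1$thresholds[order(av1$thresholds$scope_id,
                             av1$thresholds$bucket), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("fixed subset thresholds use inclusive bounds except mass error", {
  prof <- filter_profile("HLA-I")
  keep <- psm_row("k", score = 7.0, spi_pct = 50.0, mass_error_ppm = -4.9,
                  bcs = 5, sequence = "ACDEFGHIK")         # 9-mer
  drop_ppm <- psm_row("p", mass_error_ppm = 5.0)           # strict < 5
  drop_len <- psm_row("l", sequence = "ACDEFGHIKLMNP")     # 13-mer
  out <- apply_fixed_subset_thresholds(
    psm_table(keep, drop_ppm, drop_len), prof)
  expect_identical(out$spectrum_id, "k")
})

test_that("grid search matches exhaustive enumeration and handles edges", {
  # no decoys: grid minima, everything retained
  clean <- psm_table(psm_row("a", bcs = 4, score = 7),
                     psm_row("b", bcs = 9, score = 12))
  g <- subset_grid_search(clean, 4:10, seq(7, 12, 0.5))
  expect_true(g$feasible)
  expect_equal(c(g$min_bcs, g$min_score), c(4, 7))
  expect_identical(nrow(g$accepted), 2L)
  # all decoys: infeasible, nothing retained
  alld <- psm_table(psm_row("a", is_decoy = TRUE),
                    psm_row("b", is_decoy = TRUE))
  g2 <- subset_grid_search(alld, 4:10, seq(7, 12, 0.5))
  expect_false(g2$feasible)
  expect_identical(nrow(g2$accepted), 0L)
  # random instances against the double-loop oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300
    correct <- runif(n) < 0.6
    p <- do.call(rbind, lapply(seq_len(n), function(i)
      psm_row(spectrum_id = paste0("s", i),
              bcs = sample(0:14, 1, prob = if (correct[i]) 1:15 else 15:1),
              score = sample(seq(5, 20, 0.5), 1),
              is_decoy = !correct[i] & runif(1) < 0.5)))
    bg <- 4:12; sg <- seq(7, 15, 0.5)
    got <- subset_grid_search(p, bg, sg)
    want <- brute_force_grid_search(p, bg, sg)
    if (is.null(want)) {
      expect_false(got$feasible)
    } else {
      expect_equal(c(got$min_bcs, got$min_score),
                   c(want$min_bcs, want$min_score))
      expect_identical(got$n_retained, want$nt)
    }
  }
})

test_that("subset FDR control composes per class and spares canonical", {
  prof <- filter_profile("PTM-ome")
  canon <- do.call(rbind, lapply(1:50, function(i)
    psm_row(paste0("c", i), score = 3, bcs = 1)))   # would fail any subset cut
  out <- run_subset_fdr(canon, prof)
  expect_identical(out$accepted$spectrum_id, canon$spectrum_id)
  expect_null(out$class_thresholds)

  # clean class keeps the grid minima; noisy class is tightened
  set.seed(77)
  mk_class <- function(label, n, noisy) do.call(rbind, lapply(seq_len(n),
    function(i) {
      bad <- noisy && runif(1) < 0.4
      psm_row(paste0(label, i), class_label = label,
              score = if (bad) runif(1, 7, 10) else runif(1, 12, 20),
              bcs = if (bad) sample(4:6, 1) else sample(8:14, 1),
              spi_pct = 80, mass_error_ppm = 0,
              is_decoy = bad && runif(1) < 0.5)
    }))
  p <- rbind(mk_class("nuORF:uORF", 200, noisy = TRUE),
             mk_class("nuORF:lncRNA", 200, noisy = FALSE))
  res <- run_subset_fdr(p, prof)
  ct <- res$class_thresholds
  clean_row <- ct[ct$class_label == "nuORF:lncRNA", ]
  noisy_row <- ct[ct$class_label == "nuORF:uORF", ]
  expect_equal(c(clean_row$min_bcs, clean_row$min_score),
               c(prof$min_bcs, prof$min_score))
  expect_true(noisy_row$min_bcs > prof$min_bcs ||
                noisy_row$min_score > prof$min_score)
  expect_true(all(is.na(ct$fdr_estimate) | ct$fdr_estimate < 0.01 |
                    !ct$feasible))
  # permutation invariance of the accepted set
  res2 <- run_subset_fdr(p[sample(nrow(p)), ], prof)
  expect_setequal(res$accepted$spectrum_id, res2$accepted$spectrum_id)
  # unknown labels are an error
  bad <- psm_row("x", class_label = "mystery")
  expect_error(run_subset_fdr(bad, prof), "unknown class")
})
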