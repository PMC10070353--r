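test_that("spectral quality bounds are inclusive on MH and strict on tag", {
  p <- psm_table(
    psm_row("keep", precursor_mh = 600, tag_length = 2),
    psm_row("tag1", precursor_mh = 1000, tag_length = 1),
    psm_row("hiMH", precursor_mh = 4001, tag_length = 5))
  expect_identical(spectral_quality_filter(p, "hla")$spectrum_id, "keep")
  g <- psm_table(psm_row("a", precursor_mh = 700, tag_length = 1),
                 psm_row("b", precursor_mh = 800, tag_length = 1))
  expect_identical(spectral_quality_filter(g, "global")$spectrum_id, "b")
  expect_error(spectral_quality_filter(psm_row("x"), "hla"), "tag_length")
})

test_that("class-specific charge, length and BCS pre-filters apply", {
  p <- psm_table(
    psm_row("c5", charge = 5L, bcs = 8, sequence = "ACDEFGHIK"),
    psm_row("ok2", charge = 2L, bcs = 5, sequence = "ACDEFGH"),
    psm_row("short", charge = 2L, bcs = 8, sequence = "ACDEFG"))
  r1 <- hla_psm_filter(p, "I")
  expect_false("c5" %in% r1$accepted$spectrum_id)     # HLA-I: charges 1-4
  expect_false("short" %in% r1$accepted$spectrum_id)  # min length 7
  expect_true("ok2" %in% r1$accepted$spectrum_id)     # 7-mer, bcs 5, charge 2
  r2 <- hla_psm_filter(psm_table(psm_row("c1", charge = 1L)), "II")
  expect_identical(nrow(r2$accepted), 0L)             # HLA-II: charges 2-6
})

test_that("contaminant removal audits each list separately", {
  p <- psm_table(psm_row("a", sequence = "AAAAAAAAA"),
                 psm_row("b", sequence = "CCCCCCCCC"),
                 psm_row("c", sequence = "DDDDDDDDD"))
  out <- contaminant_filter(p, blank_bead_list = "AAAAAAAAA",
                            tryptic_list = "CCCCCCCCC")
  expect_identical(out$spectrum_id, "c")
  aud <- attr(out, "audit")
  expect_identical(sum(aud$removed), 2L)
  expect_identical(nrow(contaminant_filter(p)), 3L)   # empty lists: identity
})

test_that("modified peptides need score > 6 and SPI > 60, strictly", {
  p <- psm_table(
    psm_row("mod60", modifications = "2:phospho", score = 6.5,
            spi_pct = 60.0, sequence = "ASDEFGHIK"),
    psm_row("mod6", modifications = "2:phospho", score = 6.0, spi_pct = 80,
            sequence = "ASDEFGHIK"),
    psm_row("ok", modifications = "2:phospho", score = 6.1, spi_pct = 61,
            sequence = "ASDEFGHIK"),
    psm_row("unmod", score = 3, spi_pct = 10))
  expect_setequal(modified_hla_filter(p)$spectrum_id, c("ok", "unmod"))
})

test_that("HLA-I reporting keeps only 8-11mers", {
  p <- psm_table(psm_row("a", sequence = "ACDEFGH"),
                 psm_row("b", sequence = "ACDEFGHI"),
                 psm_row("c", sequence = "ACDEFGHIKLM"),
                 psm_row("d", sequence = "ACDEFGHIKLMN"))
  expect_setequal(hla_class1_final_filter(p)$spectrum_id, c("b", "c"))
})

test_that("the filter chain yields the expected survivors with a complete audit", {
  fx <- hla_fixture()
  res <- hla_filter_chain(fx$psms, "I", blank_bead_list = fx$blank_bead,
                          tryptic_list = fx$tryptic)
  expect_setequal(res$accepted$spectrum_id, fx$survivors)
  expect_identical(sum(res$audit$n_removed),
                   nrow(fx$psms) - nrow(res$accepted))
  # per-stage attribution
  aud <- res$audit
  get <- function(stage) aud$n_removed[aud$stage == stage]
  expect_identical(get("spectral_quality"), 2L)   # p02, p03
  expect_identical(get("min_length_7"), 1L)       # p04
  expect_identical(get("min_bcs_5"), 1L)          # p05
  expect_identical(get("charge_range"), 1L)       # p06
  expect_identical(get("fdr_autovalidation"), 0L) # no decoys present
  expect_identical(get("contaminants"), 3L)       # p07, p08, p09
  expect_identical(get("modified_quality"), 2L)   # p10, p11
  expect_identical(get("length_restriction"), 2L) # p13, p14
  # idempotence: filtering the survivors again changes nothing
  res2 <- hla_filter_chain(res$accepted, "I",
                           blank_bead_list = fx$blank_bead,
                           tryptic_list = fx$tryptic)
  expect_setequal(res2$accepted$spectrum_id, fx$survivors)
})

test_that("length histograms count and conserve totals", {
  expect_identical(length_distribution(character(0)), integer(0))
  h <- length_distribution(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                             "EEEEEEEEEE"))
  expect_identical(h, c("9" = 3L, "10" = 1L))
  set.seed(2)
  peps <- replicate(300, paste(sample(LETTERS[1:20], sample(8:14, 1), TRUE),
                               collapse = ""))
  parts <- split(peps, rep(1:3, 100))
  merged <- Reduce(function(a, b) {
    all <- union(names(a), names(b))
    out <- setNames(integer(length(all)), all)
    out[names(a)] <- a
    out[names(b)] <- out[names(b)] + b
    out
  }, lapply(parts, length_distribution))
  expect_identical(sum(merged), 300L)
  expect_equal(merged[order(as.integer(names(merged)))],
               length_distribution(peps))
})

test_that("position frequency matrices are column-normalized", {
  m <- position_frequency_matrix("ACDEFGHIK")
  expect_equal(colSums(m), setNames(rep(1, 9), paste0("P", 1:9)))
  expect_equal(m["A", "P1"], 1)
  m2 <- position_frequency_matrix(c("ACDEFGHIK", "AWDEFGHIK"))
  expect_equal(m2["C", "P2"], 0.5)
  expect_equal(m2["W", "P2"], 0.5)
  expect_error(position_frequency_matrix(c("ACD", "ACDE")), "mixed")
})

test_that("anchor frequencies are recovered from sampled peptides", {
  cfg <- synthetic_hla_config(n_class1 = 5000L)
  hla <- generate_hla_peptides(cfg, seed = 42)
  nine <- hla$class1[nchar(hla$class1) == 9]
  pfm <- position_frequency_matrix(nine)
  expect_lt(abs(pfm["L", "P2"] - cfg$anchor2_prob), 0.03)
})

test_that("nested sets group by containment and shared 9-mer cores", {
  peps <- c("GIRAEVSEAN", "AGIRAEVSEANK",     # containment
            "QQQQQWWWWW", "WWWWWEEEEE",       # share only a 5-mer
            "KKKKABCDEFGHI", "ABCDEFGHIPPPP") # share a 9-mer core
  g <- nested_set_grouping(peps)
  expect_identical(g[1], g[2])
  expect_false(g[3] == g[4])
  expect_identical(g[5], g[6])
  # chain closure: A within B, B shares a core with C
  chain <- c("RRRDDDDDDDDD", "DDDDDDDDD", "DDDDDDDDDTTTT")
  expect_identical(length(unique(nested_set_grouping(chain))), 1L)
  # groups partition the input
  expect_identical(length(g), length(peps))
  expect_true(all(g >= 1))
})

test_that("every synthetic class-II nested set is recovered as one group", {
  hla <- generate_hla_peptides(synthetic_hla_config(n_sets = 25L), seed = 9)
  g <- nested_set_grouping(hla$class2$peptide)
  split_groups <- tapply(g, hla$class2$set_id,
                         function(x) length(unique(x)))
  expect_true(all(split_groups == 1))
})

test_that("PTM positions summarize to fractions", {
  p <- psm_table(
    psm_row("a", modifications = "4:phospho", sequence = "AAASAAAAK"),
    psm_row("b", modifications = "4:phospho", sequence = "CCCSCCCCK"),
    psm_row("c", modifications = "2:phospho", sequence = "ASAAAAAAK"))
  s <- ptm_position_summary(p)
  expect_equal(s[["4"]], 2 / 3)
  expect_equal(sum(s), 1)
  expect_identical(ptm_position_summary(p[0, ]), numeric(0))
})
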