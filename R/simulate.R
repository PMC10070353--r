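# Seeded synthetic-data generators with known ground truth.
#
# The PSM generator emulates the statistical structure the downstream
# filters assume: target PSMs are a mixture of correct matches (shifted,
# roughly normal score distribution) and incorrect matches (right-skewed
# Gumbel scores); decoys are label-flipped draws from the incorrect
# distribution, and by default the decoy fraction is matched to the
# incorrect-target fraction so the decoy/target ratio estimates the
# false-discovery proportion. Backbone cleavage score, scored peak
# intensity, tag length, mass error and the delta forward-reverse score
# are all correlated with correctness; noncanonical classes (nuORFs,
# variants) carry lower correct-match priors, which is what motivates
# subset-specific FDR control.

.rgumbel <- function(n, loc, scale) loc - scale * log(-log(stats::runif(n)))

.rand_seq <- function(n, len_min, len_max, tryptic = FALSE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(len_min:len_max, n, replace = TRUE)
  vapply(lens, function(L) {
    s <- sample(aa, L, replace = TRUE)
    if (tryptic) s[L] <- sample(c("K", "R"), 1)
    paste(s, collapse = "")
  }, "")
}

#' Configuration for the synthetic PSM generator
#'
#' Defaults describe a two-plex, four-run tryptic experiment: 20,000
#' PSMs, charges 2-6 dominated by 2+/3+, a 90% canonical / 10%
#' noncanonical class mixture with markedly lower correct-match priors
#' for the nuORF classes, and a decoy fraction automatically matched to
#' the incorrect-target fraction (`decoy_fraction = NULL`).
#'
#' @param n_psms,n_runs,n_plexes dataset size and layout (runs are split
#'   evenly across plexes).
#' @param charge_probs named numeric vector of charge probabilities.
#' @param class_probs named numeric vector over class labels.
#' @param correct_prior named numeric vector, correct-match probability
#'   per class.
#' @param decoy_fraction probability that a record is a decoy; NULL
#'   matches it to the expected incorrect-target fraction.
#' @param score_correct,score_incorrect location/scale of the correct
#'   (normal) and incorrect (Gumbel) score families.
#' @param mod_rate fraction of target PSMs carrying a phospho site.
#' @param ambiguity_rate fraction of modified PSMs whose localization
#'   score gap falls below the confident-call threshold.
#' @return a `synthetic_psm_config` list.
#' @export
synthetic_psm_config <- function(
    n_psms = 20000L, n_runs = 4L, n_plexes = 2L,
    charge_probs = c("2" = 0.45, "3" = 0.30, "4" = 0.15,
                     "5" = 0.07, "6" = 0.03),
    class_probs = c("canonical" = 0.90, "nuORF:lncRNA" = 0.05,
                    "nuORF:uORF" = 0.03, "variant" = 0.02),
    correct_prior = c("canonical" = 0.85, "nuORF:lncRNA" = 0.45,
                      "nuORF:uORF" = 0.35, "variant" = 0.60),
    decoy_fraction = NULL,
    score_correct = c(mean = 11, sd = 2.5),
    score_incorrect = c(loc = 4, scale = 1.2),
    mod_rate = 0.3, ambiguity_rate = 0.3) {
  stopifnot(n_psms > 0, n_runs >= 1, n_plexes >= 1,
            abs(sum(charge_probs) - 1) < 1e-9,
            abs(sum(class_probs) - 1) < 1e-9,
            all(correct_prior >= 0 & correct_prior <= 1),
            setequal(names(class_probs), names(correct_prior)),
            is.null(decoy_fraction) ||
              (decoy_fraction >= 0 && decoy_fraction < 1),
            mod_rate >= 0, mod_rate <= 1)
  structure(as.list(environment()), class = "synthetic_psm_config")
}

#' Generate a synthetic PSM dataset with ground truth
#'
#' @param config [synthetic_psm_config()].
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   dataset exactly.
#' @return list with `psms` (a valid PSM table) and `truth` (data.frame
#'   spectrum_id, correct).
#' @export
generate_psm_dataset <- function(config = synthetic_psm_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_psm_config"))
  set.seed(seed)
  n <- config$n_psms
  q_incorrect <- sum(config$class_probs *
                       (1 - config$correct_prior[names(config$class_probs)]))
  dfrac <- config$decoy_fraction %||% (q_incorrect / (1 + q_incorrect))
  is_decoy <- stats::runif(n) < dfrac
  class_label <- sample(names(config$class_probs), n, replace = TRUE,
                        prob = config$class_probs)
  correct <- !is_decoy &
    stats::runif(n) < config$correct_prior[class_label]
  nc <- sum(correct); ni <- n - nc
  score <- numeric(n)
  score[correct] <- stats::rnorm(nc, config$score_correct[["mean"]],
                                 config$score_correct[["sd"]])
  score[!correct] <- .rgumbel(ni, config$score_incorrect[["loc"]],
                              config$score_incorrect[["scale"]])
  score <- pmax(score, 0.1)
  delta_rank <- numeric(n)
  delta_rank[correct] <- stats::rgamma(nc, shape = 2, scale = 0.8)
  delta_rank[!correct] <- stats::rexp(ni, rate = 5)
  bcs <- numeric(n)
  bcs[correct] <- pmax(0, round(stats::rnorm(nc, 8, 2)))
  bcs[!correct] <- pmax(0, round(stats::rnorm(ni, 3.5, 1.5)))
  spi <- numeric(n)
  spi[correct] <- 100 * stats::rbeta(nc, 8, 2)
  spi[!correct] <- 100 * stats::rbeta(ni, 3, 2)
  ppm <- numeric(n)
  ppm[correct] <- stats::rnorm(nc, 0, 1.5)
  ppm[!correct] <- stats::runif(ni, -10, 10)
  delta_fr <- numeric(n)
  delta_fr[correct] <- abs(stats::rnorm(nc, 0, 3)) + 0.5
  delta_fr[!correct] <- stats::rnorm(ni, 0, 2)   # about half negative
  tag <- integer(n)
  tag[correct] <- 2L + stats::rpois(nc, 4)
  tag[!correct] <- stats::rpois(ni, 2)
  charge <- as.integer(sample(names(config$charge_probs), n, replace = TRUE,
                              prob = config$charge_probs))
  run_id <- sample(sprintf("run%02d", seq_len(config$n_runs)), n,
                   replace = TRUE)
  plex_of_run <- rep(sprintf("plex%d", seq_len(config$n_plexes)),
                     length.out = config$n_runs)
  names(plex_of_run) <- sprintf("run%02d", seq_len(config$n_runs))
  sequence <- .rand_seq(n, 7L, 25L, tryptic = TRUE)
  purity <- 100 * stats::rbeta(n, 8, 2)
  # phospho sites on a fraction of targets: overwrite one residue with S
  mods <- character(n)
  loc_top <- rep(NA_real_, n); loc_second <- rep(NA_real_, n)
  modded <- which(!is_decoy & stats::runif(n) < config$mod_rate)
  if (length(modded)) {
    pos <- vapply(nchar(sequence[modded]) - 1L, function(L)
      sample.int(L, 1L), 1L)
    s2 <- sequence[modded]
    substr(s2, pos, pos) <- "S"
    sequence[modded] <- s2
    mods[modded] <- paste0(pos, ":phospho")
    gap <- ifelse(stats::runif(length(modded)) < config$ambiguity_rate,
                  stats::rexp(length(modded), rate = 1 / 0.6),
                  1.2 + stats::rexp(length(modded), rate = 1 / 2))
    loc_top[modded] <- score[modded]
    loc_second[modded] <- pmax(0, score[modded] - gap)
  }
  psms <- data.frame(
    spectrum_id = sprintf("sp%06d", seq_len(n)),
    run_id = run_id,
    plex_id = unname(plex_of_run[run_id]),
    fraction_id = "f1",
    charge = charge,
    precursor_mh = pmin(5999, pmax(801, nchar(sequence) * 111 +
                                     stats::rnorm(n, 0, 120))),
    mass_error_ppm = ppm,
    score = score,
    delta_rank_score = delta_rank,
    delta_fr_score = delta_fr,
    bcs = bcs,
    spi_pct = pmin(100, spi),
    sequence = sequence,
    modifications = mods,
    loc_top_score = loc_top,
    loc_second_score = loc_second,
    is_decoy = is_decoy,
    class_label = class_label,
    purity_pct = purity,
    tmt_labeled = TRUE,
    proteins = sprintf("PROT%04d", sample.int(2000, n, replace = TRUE)),
    tag_length = tag,
    stringsAsFactors = FALSE)
  validate_psm_table(psms)
  list(psms = psms,
       truth = data.frame(spectrum_id = psms$spectrum_id, correct = correct,
                          stringsAsFactors = FALSE))
}

#' Typical TMT certificate-of-analysis impurity factors
#'
#' A fixed, representative correction-factor table (percent of each
#' reagent's signal appearing -2/-1/+1/+2 positions along the series),
#' with per-channel variation of the magnitude seen on real lot CoAs.
#'
#' @param channels channel labels in series order.
#' @return data.frame suitable for [build_impurity_matrix()].
#' @export
default_coa <- function(channels) {
  n <- length(channels)
  idx <- seq_len(n)
  data.frame(channel = channels,
             minus2 = round(0.1 + 0.1 * (idx %% 3), 2),
             minus1 = round(0.6 + 0.25 * (idx %% 4), 2),
             plus1 = round(5.5 - 0.35 * (idx %% 5), 2),
             plus2 = round(0.2 + 0.05 * (idx %% 2), 2),
             stringsAsFactors = FALSE)
}

.tmt10_channels <- c("126", "127N", "127C", "128N", "128C",
                     "129N", "129C", "130N", "130C", "131")

#' Configuration for the synthetic quantitation generator
#'
#' Defaults: a TMT-10 plex with 200 features, 50 usable PSMs per feature,
#' a true log2 fold change of 1.0 between the first and second halves of
#' the channels, multiplicative log-normal noise with sigma 0.3 (log2
#' units), precursor purity drawn high (clean isolation), and no
#' co-isolation background by default — raising `contamination_intensity`
#' mixes (1 - purity) of a flat background into every channel, which is
#' the ratio-compression mechanism.
#'
#' @param n_features,psms_per_feature dataset size.
#' @param channels channel labels in series order.
#' @param log2_fc true fold change of the second channel group over the
#'   first.
#' @param sigma log2-scale standard deviation of multiplicative noise.
#' @param base_intensity mean reporter intensity of an unregulated
#'   channel.
#' @param purity_shape1,purity_shape2 Beta parameters for precursor
#'   purity (on 0-1, scaled to percent).
#' @param contamination_intensity intensity of the co-isolation
#'   background mixed in proportionally to (1 - purity).
#' @param coa impurity correction factors (default [default_coa()]).
#' @return a `synthetic_quant_config` list.
#' @export
synthetic_quant_config <- function(
    n_features = 200L, psms_per_feature = 50L,
    channels = .tmt10_channels, log2_fc = 1.0, sigma = 0.3,
    base_intensity = 1e5, purity_shape1 = 16, purity_shape2 = 1.6,
    contamination_intensity = 0, coa = default_coa(channels)) {
  stopifnot(n_features > 0, psms_per_feature > 0, sigma >= 0,
            length(channels) >= 4, contamination_intensity >= 0)
  structure(as.list(environment()), class = "synthetic_quant_config")
}

#' Generate a synthetic reporter-ion quantitation dataset
#'
#' True per-channel intensities (a known log2 profile around a base
#' intensity) are passed through the impurity matrix built from the
#' config's CoA table, multiplied by log-normal noise, and mixed with a
#' flat co-isolation background in proportion to (1 - purity).
#'
#' @param config [synthetic_quant_config()].
#' @param seed integer seed.
#' @return list with `psms` (PSM table rows carrying reporter_<channel>
#'   columns and a `feature_id` column), `design`, `impurity_matrix`, and
#'   `truth` (per-feature true log2 profiles, centered).
#' @export
generate_quant_dataset <- function(config = synthetic_quant_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "synthetic_quant_config"))
  set.seed(seed)
  ch <- config$channels
  nch <- length(ch)
  design <- plex_design("plex1", ch)
  M <- build_impurity_matrix(config$coa, design)
  half <- nch %/% 2
  n_feat <- config$n_features
  k <- config$psms_per_feature
  n <- n_feat * k
  # balanced per-feature profiles: alternate features are regulated up or
  # down in the second channel group, so channel medians stay near zero —
  # the structure median/MAD normalization assumes (mostly-null cohorts)
  sign_f <- ifelse(seq_len(n_feat) %% 2 == 0, 1, -1)
  base_prof <- c(rep(0, half), rep(config$log2_fc, nch - half))
  base_prof <- base_prof - mean(base_prof)
  profiles <- outer(sign_f, base_prof)          # n_feat x nch, centered
  feature_id <- rep(sprintf("feat%04d", seq_len(n_feat)), each = k)
  true_int <- config$base_intensity * 2 ^ profiles
  purity <- if (config$purity_shape2 == 0) rep(1, n) else
    stats::rbeta(n, config$purity_shape1, config$purity_shape2)
  noise <- matrix(2 ^ stats::rnorm(n * nch, 0, config$sigma), n, nch)
  mixed <- t(unclass(M) %*% t(true_int))        # per-feature mixed truth
  mixed_psm <- mixed[rep(seq_len(n_feat), each = k), , drop = FALSE]
  bg <- config$contamination_intensity
  observed <- (mixed_psm * purity + (1 - purity) * bg) * noise
  colnames(observed) <- paste0("reporter_", ch)
  seqs <- .rand_seq(n, 8L, 20L, tryptic = TRUE)
  psms <- data.frame(
    spectrum_id = sprintf("qsp%06d", seq_len(n)),
    run_id = "run01", plex_id = "plex1", fraction_id = "f1",
    charge = 2L,
    precursor_mh = nchar(seqs) * 111,
    mass_error_ppm = 0, score = 12, delta_rank_score = 2,
    delta_fr_score = abs(stats::rnorm(n, 2, 1)),
    bcs = 8, spi_pct = 80,
    sequence = seqs, modifications = "",
    loc_top_score = NA_real_, loc_second_score = NA_real_,
    is_decoy = FALSE, class_label = "canonical",
    purity_pct = 100 * purity, tmt_labeled = TRUE,
    proteins = feature_id,
    feature_id = feature_id,
    stringsAsFactors = FALSE)
  psms <- cbind(psms, as.data.frame(observed))
  truth <- data.frame(feature_id = sprintf("feat%04d", seq_len(n_feat)),
                      stringsAsFactors = FALSE)
  colnames(profiles) <- ch
  truth <- cbind(truth, as.data.frame(profiles))
  list(psms = psms, design = design, impurity_matrix = M, truth = truth)
}

#' Configuration for the synthetic HLA peptide generator
#'
#' Class I peptides have the canonical length mode at 9 (8-12mers
#' emitted) and an anchor residue at P2 (leucine with probability 0.9 by
#' default) plus a C-terminal anchor; class II peptides come in nested
#' sets built by extending a shared 9-residue binding core with ragged
#' N-/C-terminal flanks.
#'
#' @param n_class1 number of class I peptides.
#' @param length_probs named probabilities over class I lengths.
#' @param anchor2,anchor2_prob P2 anchor residue and its frequency.
#' @param anchorC,anchorC_prob C-terminal anchor residue and frequency.
#' @param n_sets,set_size_range class II nested-set count and per-set
#'   peptide counts.
#' @param core_length class II binding-core length.
#' @return a `synthetic_hla_config` list.
#' @export
synthetic_hla_config <- function(
    n_class1 = 5000L,
    length_probs = c("8" = 0.12, "9" = 0.55, "10" = 0.18, "11" = 0.10,
                     "12" = 0.05),
    anchor2 = "L", anchor2_prob = 0.9,
    anchorC = "V", anchorC_prob = 0.7,
    n_sets = 40L, set_size_range = c(3L, 8L), core_length = 9L) {
  stopifnot(abs(sum(length_probs) - 1) < 1e-9,
            anchor2_prob >= 0, anchor2_prob <= 1)
  structure(as.list(environment()), class = "synthetic_hla_config")
}

#' Generate synthetic HLA class I and class II peptide sets
#'
#' @param config [synthetic_hla_config()].
#' @param seed integer seed.
#' @return list with `class1` (character vector), `class2` (data.frame
#'   peptide, set_id, core).
#' @export
generate_hla_peptides <- function(config = synthetic_hla_config(),
                                  seed = 1L) {
  stopifnot(inherits(config, "synthetic_hla_config"))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- as.integer(sample(names(config$length_probs), config$n_class1,
                            replace = TRUE, prob = config$length_probs))
  class1 <- vapply(lens, function(L) {
    s <- sample(aa, L, replace = TRUE)
    if (stats::runif(1) < config$anchor2_prob) s[2] <- config$anchor2
    if (stats::runif(1) < config$anchorC_prob) s[L] <- config$anchorC
    paste(s, collapse = "")
  }, "")
  rows <- list()
  for (g in seq_len(config$n_sets)) {
    core <- paste(sample(aa, config$core_length, replace = TRUE),
                  collapse = "")
    sz <- sample(config$set_size_range[1]:config$set_size_range[2], 1L)
    peps <- unique(vapply(seq_len(sz), function(i) {
      nfl <- sample(0:6, 1L); cfl <- sample(0:6, 1L)
      paste0(paste(sample(aa, nfl, replace = TRUE), collapse = ""), core,
             paste(sample(aa, cfl, replace = TRUE), collapse = ""))
    }, ""))
    rows[[g]] <- data.frame(peptide = peps, set_id = g, core = core,
                            stringsAsFactors = FALSE)
  }
  list(class1 = class1, class2 = do.call(rbind, rows))
}
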