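# TMT reporter-ion quantitation.
#
# Reporter intensities are corrected for reagent isotope impurities by
# solving M x = observed with Cramer's rule, where column j of M gives
# the fraction of reagent j's signal landing in each channel (diagonal =
# retained fraction; -2/-1/+1/+2 neighbors per the reagent series order;
# spill outside the plex is lost, so such columns sum to < 1). PSM-level
# log2 ratios are medianed into feature-level ratios, then median/MAD
# normalized per channel.

#' Build a channel-by-channel impurity matrix from CoA correction factors
#'
#' @param coa data.frame with columns `channel` and impurity percentages
#'   `minus2`, `minus1`, `plus1`, `plus2` (percent of the reagent's signal
#'   appearing 2/1 channels earlier / later in the series), one row per
#'   channel of the design, in any order.
#' @param design [plex_design()]; the channel order defines the isotope
#'   series neighbor structure.
#' @return matrix of class `impurity_matrix`, rows/cols named by channel;
#'   entry (i, j) is the fraction of reagent j observed in channel i.
#' @export
build_impurity_matrix <- function(coa, design) {
  ch <- design$channels
  stopifnot(all(c("channel", "minus2", "minus1", "plus1", "plus2")
                %in% names(coa)))
  if (!setequal(coa$channel, ch))
    stop("CoA table channels do not match the design")
  n <- length(ch)
  M <- matrix(0, n, n, dimnames = list(ch, ch))
  for (j in seq_len(n)) {
    row <- coa[coa$channel == ch[j], ]
    imp <- c(row$minus2, row$minus1, row$plus1, row$plus2) / 100
    if (any(imp < 0) || any(imp > 1))
      stop("impurity percentages must lie in [0,100]")
    if (sum(imp) >= 1)
      stop("impurity sum >= 100% for reagent '", ch[j], "'")
    M[j, j] <- 1 - sum(imp)
    off <- c(-2L, -1L, 1L, 2L)
    for (k in seq_along(off)) {
      i <- j + off[k]
      if (i >= 1 && i <= n) M[i, j] <- imp[k]   # out-of-plex spill is lost
    }
  }
  for (j in seq_len(n))
    if (any(M[-j, j] > M[j, j]))
      stop("off-diagonal impurity exceeds diagonal for reagent '",
           ch[j], "'")
  if (abs(det(M)) < .Machine$double.eps)
    stop("impurity matrix is singular")
  class(M) <- c("impurity_matrix", class(M))
  M
}

#' Correct observed reporter intensities for isotope impurities
#'
#' Solves M x = observed with Cramer's rule (the solution components are
#' ratios of determinants). Negative components — possible when noise
#' pushes a low channel below its neighbors' spill — are clamped to zero
#' and flagged, since intensities are physical quantities.
#'
#' @param observed non-negative intensity vector (one entry per channel).
#' @param M impurity matrix from [build_impurity_matrix()].
#' @param max_condition reject matrices with a 2-norm condition number
#'   above this cap (default 1e8).
#' @return corrected vector with a logical `clamped` attribute.
#' @export
correct_reporters <- function(observed, M, max_condition = 1e8) {
  M <- unclass(M)
  stopifnot(length(observed) == nrow(M))
  detM <- det(M)
  if (!is.finite(detM) || abs(detM) < .Machine$double.eps ||
      kappa(M, exact = TRUE) > max_condition)
    stop("impurity matrix is singular or ill-conditioned")
  x <- vapply(seq_len(ncol(M)), function(j) {
    Mj <- M
    Mj[, j] <- observed
    det(Mj) / detM
  }, 0)
  clamped <- x < 0
  x[clamped] <- 0
  names(x) <- colnames(M)
  attr(x, "clamped") <- any(clamped)
  x
}

#' Is a PSM usable for quantitation?
#'
#' Excluded are PSMs lacking a TMT label, with precursor isolation purity
#' below 50% (co-isolation contamination compresses ratios), or with a
#' negative delta forward-reverse score (about half of such PSMs are
#' false identifications).
#'
#' @param psms PSM data.frame.
#' @return logical vector.
#' @export
psm_quant_filter <- function(psms) {
  psms$tmt_labeled & psms$purity_pct >= 50 & psms$delta_fr_score >= 0
}

#' PSM-level log2 reporter ratios
#'
#' @param corrected corrected intensity vector (named by channel).
#' @param policy "per-psm-median" (denominator = median of the PSM's
#'   positive channel intensities; the default, for designs without a
#'   common reference) or "reference-channel".
#' @param reference_channel required under the reference-channel policy.
#' @return log2 ratio vector; channels with zero intensity are NA. An
#'   all-zero input yields all-NA with a `flagged` attribute.
#' @export
psm_log_ratios <- function(corrected,
                           policy = c("per-psm-median", "reference-channel"),
                           reference_channel = NULL) {
  policy <- match.arg(policy)
  pos <- corrected[corrected > 0]
  if (!length(pos)) {
    out <- rep(NA_real_, length(corrected))
    names(out) <- names(corrected)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  denom <- if (policy == "per-psm-median") stats::median(pos) else {
    if (is.null(reference_channel) ||
        !reference_channel %in% names(corrected))
      stop("reference-channel policy requires a valid reference_channel")
    ref <- corrected[[reference_channel]]
    if (ref <= 0) NA_real_ else ref
  }
  out <- ifelse(corrected > 0 & !is.na(denom) & denom > 0,
                log2(corrected / denom), NA_real_)
  names(out) <- names(corrected)
  out
}

#' Aggregate PSM ratios to feature-level medians
#'
#' Each feature-level (protein subgroup or VM site) channel ratio is the
#' median of all contributing PSM-level ratios; the contributing PSM
#' count per channel is recorded as the ratio count.
#'
#' @param ratios numeric matrix of PSM-level log2 ratios (rows = PSMs,
#'   columns = channels; NA = not quantified).
#' @param feature_ids character vector assigning each PSM row to a feature.
#' @return list with `matrix` (features x channels, median ratios) and
#'   `ratio_counts` (same shape, contributing PSMs per cell).
#' @export
aggregate_feature_ratios <- function(ratios, feature_ids) {
  stopifnot(NROW(ratios) == length(feature_ids))
  feats <- sort(unique(feature_ids))
  out <- matrix(NA_real_, length(feats), ncol(ratios),
                dimnames = list(feats, colnames(ratios)))
  cnt <- matrix(0L, length(feats), ncol(ratios),
                dimnames = list(feats, colnames(ratios)))
  for (f in feats) {
    block <- ratios[feature_ids == f, , drop = FALSE]
    out[f, ] <- apply(block, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    cnt[f, ] <- as.integer(colSums(!is.na(block)))
  }
  list(matrix = out, ratio_counts = cnt)
}

#' Reporting filter for quantified proteins
#'
#' Requires at least `min_unique_peptides` fully quantified unique
#' peptides per protein and a ratio count of at least `min_ratio_count`
#' in every quantified channel.
#'
#' @param quant list from [aggregate_feature_ratios()].
#' @param unique_quant_peptides named integer vector: per feature, the
#'   number of unique peptide sequences with complete (no-NA) PSM-level
#'   ratio vectors.
#' @param min_unique_peptides,min_ratio_count thresholds (default 2 each).
#' @return the filtered `quant` list.
#' @export
quant_reporting_filter <- function(quant, unique_quant_peptides,
                                   min_unique_peptides = 2L,
                                   min_ratio_count = 2L) {
  m <- quant$matrix
  if (NROW(m) == 0) return(quant)
  upep <- unique_quant_peptides[rownames(m)]
  upep[is.na(upep)] <- 0L
  rc_ok <- apply(quant$ratio_counts >= min_ratio_count |
                   is.na(m), 1, all)
  has_q <- apply(!is.na(m), 1, any)
  keep <- upep >= min_unique_peptides & rc_ok & has_q
  list(matrix = m[keep, , drop = FALSE],
       ratio_counts = quant$ratio_counts[keep, , drop = FALSE])
}

#' Median/MAD normalization of a quant matrix
#'
#' Centers every channel (column) at zero median and rescales it so that
#' all channel MADs equal the pre-normalization median of per-channel
#' MADs, equalizing spread without changing the overall scale. The MAD is
#' the raw median absolute deviation (no Gaussian consistency factor:
#' only relative channel scaling matters). Missing entries are left
#' untouched; channels with fewer than 3 non-missing values (or zero MAD)
#' are centered only and flagged.
#'
#' @param m numeric matrix (features x channels), NA = missing.
#' @return normalized matrix with a `flagged_channels` attribute.
#' @export
median_mad_normalize <- function(m) {
  if (NROW(m) == 0 || NCOL(m) == 0) return(m)
  raw_mad <- function(v) stats::median(abs(v - stats::median(v,
    na.rm = TRUE)), na.rm = TRUE)
  n_obs <- apply(m, 2, function(v) sum(!is.na(v)))
  mads <- apply(m, 2, raw_mad)
  scalable <- n_obs >= 3 & !is.na(mads) & mads > 0
  target <- if (any(scalable)) stats::median(mads[scalable]) else NA_real_
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j] - stats::median(m[, j], na.rm = TRUE)
    if (scalable[j] && !is.na(target)) v <- v * (target / mads[j])
    out[, j] <- v
  }
  attr(out, "flagged_channels") <-
    colnames(m)[!scalable] %||% which(!scalable)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full PSM-to-feature quantitation stack
#'
#' Applies the PSM quantitation filter, corrects each usable PSM's
#' reporter intensities for isotope impurities, forms log2 ratios,
#' aggregates them to feature-level medians, and (optionally) median/MAD
#' normalizes the result.
#'
#' @param psms PSM data.frame carrying reporter_<channel> columns.
#' @param design [plex_design()].
#' @param M impurity matrix from [build_impurity_matrix()].
#' @param feature_col column assigning PSMs to features (default
#'   "feature_id", falling back to "proteins").
#' @param policy,reference_channel see [psm_log_ratios()].
#' @param normalize apply [median_mad_normalize()] (default TRUE).
#' @return list from [aggregate_feature_ratios()], with the normalized
#'   matrix when requested.
#' @export
quantify_psms <- function(psms, design, M, feature_col = "feature_id",
                          policy = "per-psm-median",
                          reference_channel = NULL, normalize = TRUE) {
  if (!feature_col %in% names(psms)) feature_col <- "proteins"
  rep_cols <- paste0("reporter_", design$channels)
  stopifnot(all(rep_cols %in% names(psms)))
  usable <- psm_quant_filter(psms)
  sub <- psms[usable, , drop = FALSE]
  obs <- as.matrix(sub[, rep_cols])
  ratios <- t(apply(obs, 1, function(v) {
    corr <- correct_reporters(unname(v), M)
    as.numeric(psm_log_ratios(stats::setNames(corr, design$channels),
                              policy, reference_channel))
  }))
  colnames(ratios) <- design$channels
  agg <- aggregate_feature_ratios(ratios, sub[[feature_col]])
  if (normalize) agg$matrix <- median_mad_normalize(agg$matrix)
  agg
}

#' Patient-consistency filter for variant peptides
#'
#' A single-amino-acid-variant (SAAV) feature is kept only when its TMT
#' ratios are extremely high exactly in the carrier channels: the robust
#' z-score (against the row's own median/MAD) must reach `z_hi` in every
#' carrier channel and stay below it in every non-carrier channel.
#'
#' @param row numeric vector of normalized log2 ratios (one feature).
#' @param carrier_mask logical vector, TRUE for channels whose patient
#'   carries the variant.
#' @param z_hi robust z threshold (default 2).
#' @return logical: keep the feature?
#' @export
saav_patient_consistency <- function(row, carrier_mask, z_hi = 2.0) {
  stopifnot(length(row) == length(carrier_mask))
  if (!any(carrier_mask)) stop("no carrier channels in design")
  med <- stats::median(row, na.rm = TRUE)
  mad <- stats::median(abs(row - med), na.rm = TRUE)
  if (is.na(mad) || mad == 0) return(FALSE)
  z <- (row - med) / mad
  carriers_ok <- all(!is.na(z[carrier_mask]) & z[carrier_mask] >= z_hi)
  others <- z[!carrier_mask]
  others_ok <- all(is.na(others) | others < z_hi)
  carriers_ok && others_ok
}
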