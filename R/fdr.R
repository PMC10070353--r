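# Target-decoy FDR estimation and threshold optimization.
#
# The estimator is the simple concatenated target-decoy ratio D/T, kept in
# one function so corrected variants ((1+D)/T, 2D/(T+D)) are a one-line
# swap. "Optimizing" thresholds means: over the grid of observed score and
# delta-rank values, accept as many targets as possible subject to the
# estimated FDR staying at or below the scope's target.

#' Estimate the false discovery rate of an accepted PSM set
#'
#' @param psms PSM data.frame (or any data.frame with an `is_decoy`
#'   logical column) representing an accepted set.
#' @return n_decoy / n_target. Returns 0 when no decoys are present.
#'   Errors on an empty set and when decoys are present without any target.
#' @export
estimate_fdr <- function(psms) {
  if (NROW(psms) == 0) stop("no accepted PSMs")
  d <- sum(psms$is_decoy)
  t <- sum(!psms$is_decoy)
  if (d == 0) return(0)
  if (t == 0) stop("accepted set contains decoys but no targets; FDR undefined")
  d / t
}

# Suffix-sum count matrix over the empirical candidate grids. Returns, for
# every (score candidate i, delta candidate j), the number of records with
# score >= s_i and delta >= d_j. Used by both threshold optimizers.
.suffix_counts <- function(score, delta, s_cand, d_cand) {
  i <- findInterval(score, s_cand)
  j <- findInterval(delta, d_cand)
  m <- matrix(0, nrow = length(s_cand), ncol = length(d_cand))
  if (length(i)) {
    tab <- table(factor(i, levels = seq_along(s_cand)),
                 factor(j, levels = seq_along(d_cand)))
    m <- matrix(as.numeric(tab), nrow = length(s_cand))
  }
  # reverse 2-D cumulative sum -> counts at or above each candidate pair
  m <- apply(m, 2, function(col) rev(cumsum(rev(col))))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(s_cand))
  t(apply(m, 1, function(row) rev(cumsum(rev(row)))))
}

# Optimize (min_score, min_delta_rank) for one scope. Candidate thresholds
# are quantiles of the observed values (so the lowest candidates accept
# everything); capping the grid resolution, and selecting with one extra
# pseudo-decoy ((D+1)/T <= target), guards against overfitting the decoy
# sample when maximizing acceptance over many cells — the reported
# estimate remains the plain D/T ratio. Among feasible cells the one with
# the most targets wins, ties broken by fewer decoys, then higher score
# threshold, then higher delta threshold (all deterministic).
.candidate_grid <- function(x, max_levels) {
  sort(unique(stats::quantile(x, probs = seq(0, 1, length.out = max_levels),
                              type = 1, names = FALSE)))
}

.optimize_pair_thresholds <- function(score, delta, is_decoy, target,
                                      s_cand = NULL, d_cand = NULL,
                                      max_candidates = c(25L, 15L),
                                      n_decoy_extra = 1) {
  n <- length(score)
  out <- list(min_score = NA_real_, min_delta_rank = NA_real_,
              fdr_estimate = NA_real_, n_accepted_targets = 0L,
              n_accepted_decoys = 0L, feasible = FALSE)
  if (n == 0 || !any(!is_decoy)) return(out)
  if (is.null(s_cand)) s_cand <- .candidate_grid(score, max_candidates[1])
  if (is.null(d_cand)) d_cand <- .candidate_grid(delta, max_candidates[2])
  if (!any(is_decoy))   # no decoy sample to overfit: accept everything
    return(list(min_score = s_cand[1], min_delta_rank = d_cand[1],
                fdr_estimate = 0, n_accepted_targets = n,
                n_accepted_decoys = 0L, feasible = TRUE))
  Tm <- .suffix_counts(score[!is_decoy], delta[!is_decoy], s_cand, d_cand)
  Dm <- .suffix_counts(score[is_decoy], delta[is_decoy], s_cand, d_cand)
  fdr <- ifelse(Tm > 0, (Dm + n_decoy_extra) / Tm, Inf)
  ok <- which(fdr <= target & Tm > 0)
  if (!length(ok)) return(out)
  tt <- Tm[ok]; dd <- Dm[ok]
  ridx <- (ok - 1L) %% nrow(Tm) + 1L
  cidx <- (ok - 1L) %/% nrow(Tm) + 1L
  ord <- order(-tt, dd, -s_cand[ridx], -d_cand[cidx])
  best <- ord[1L]
  list(min_score = s_cand[ridx[best]],
       min_delta_rank = d_cand[cidx[best]],
       fdr_estimate = dd[best] / tt[best],
       n_accepted_targets = as.integer(tt[best]),
       n_accepted_decoys = as.integer(dd[best]),
       feasible = TRUE)
}

#' Default autovalidation targets
#'
#' The proteome/PTM-ome scheme optimizes thresholds per LC-MS/MS run for
#' precursor charges 2, 3 and 4 at an FDR target of 0.8% each, and pools
#' charges 5-6 per TMT plex at 0.4% (too few high-charge spectra per run
#' for stable statistics). The HLA scheme pools all runs (fractions) of a
#' plex at 1.0% with the class-specific charge range.
#'
#' @param mode "proteome" (also used for PTM-omes), "hla1" or "hla2".
#' @return data.frame with columns bucket, charge_min, charge_max, scope
#'   ("run", "plex" or "pooled") and fdr_target.
#' @export
autovalidation_targets <- function(mode = c("proteome", "hla1", "hla2")) {
  mode <- match.arg(mode)
  if (mode == "proteome") {
    data.frame(bucket = c("2", "3", "4", "5-6"),
               charge_min = c(2L, 3L, 4L, 5L),
               charge_max = c(2L, 3L, 4L, 6L),
               scope = c("run", "run", "run", "plex"),
               fdr_target = c(0.008, 0.008, 0.008, 0.004),
               stringsAsFactors = FALSE)
  } else {
    cr <- if (mode == "hla1") c(1L, 4L) else c(2L, 6L)
    data.frame(bucket = paste0(cr[1], "-", cr[2]),
               charge_min = cr[1], charge_max = cr[2],
               scope = "pooled", fdr_target = 0.01,
               stringsAsFactors = FALSE)
  }
}

#' Per-run / per-charge PSM autovalidation
#'
#' For each scope (a charge bucket crossed with a run, plex, or the pooled
#' dataset) the score and delta-rank thresholds are chosen on an empirical
#' candidate grid — quantiles of the observed values, up to
#' `max_candidates` levels per dimension — to accept the maximum number of
#' targets subject to the estimated FDR staying at or below the scope's
#' target. Selection counts `n_decoy_extra` pseudo-decoys so that
#' maximizing acceptance over the grid does not overfit the finite decoy
#' sample; the reported `fdr_estimate` is the plain decoy/target ratio and
#' always satisfies the target. Scopes where no threshold pair meets the
#' target accept nothing and are flagged; they are never silently relaxed.
#' Charges outside every bucket are not accepted.
#'
#' @param psms PSM data.frame.
#' @param targets data.frame as from [autovalidation_targets()].
#' @param max_candidates integer pair: maximum score and delta-rank
#'   candidate levels per scope.
#' @param n_decoy_extra pseudo-decoy count added during selection (default
#'   1; 0 reproduces the uncorrected maximizer).
#' @return list with `thresholds` (one row per scope) and `accepted`
#'   (the union of accepted PSMs across scopes, original row order).
#' @export
autovalidate <- function(psms, targets = autovalidation_targets("proteome"),
                         max_candidates = c(25L, 15L), n_decoy_extra = 1) {
  stopifnot(is.data.frame(targets),
            all(c("bucket", "charge_min", "charge_max", "scope",
                  "fdr_target") %in% names(targets)))
  accepted_idx <- logical(NROW(psms))
  rows <- list()
  for (b in seq_len(nrow(targets))) {
    tg <- targets[b, ]
    in_bucket <- psms$charge >= tg$charge_min & psms$charge <= tg$charge_max
    scope_ids <- switch(tg$scope,
      run = psms$run_id, plex = psms$plex_id,
      pooled = rep("all", NROW(psms)),
      stop("unknown scope '", tg$scope, "'"))
    for (sid in sort(unique(scope_ids[in_bucket]))) {
      sel <- which(in_bucket & scope_ids == sid)
      sub <- psms[sel, ]
      opt <- .optimize_pair_thresholds(sub$score, sub$delta_rank_score,
                                       sub$is_decoy, tg$fdr_target,
                                       max_candidates = max_candidates,
                                       n_decoy_extra = n_decoy_extra)
      if (opt$feasible) {
        acc <- sub$score >= opt$min_score &
               sub$delta_rank_score >= opt$min_delta_rank
        accepted_idx[sel[acc]] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scope = tg$scope, scope_id = sid, bucket = tg$bucket,
        fdr_target = tg$fdr_target,
        min_score = opt$min_score, min_delta_rank = opt$min_delta_rank,
        fdr_estimate = opt$fdr_estimate,
        n_accepted_targets = opt$n_accepted_targets,
        n_accepted_decoys = opt$n_accepted_decoys,
        feasible = opt$feasible, stringsAsFactors = FALSE)
    }
  }
  thresholds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scope = character(0), scope_id = character(0),
               bucket = character(0), fdr_target = numeric(0),
               min_score = numeric(0), min_delta_rank = numeric(0),
               fdr_estimate = numeric(0), n_accepted_targets = integer(0),
               n_accepted_decoys = integer(0), feasible = logical(0))
  list(thresholds = thresholds, accepted = psms[accepted_idx, , drop = FALSE])
}

#' Apply a profile's fixed subset thresholds
#'
#' Retains records with score, scored peak intensity, backbone cleavage
#' score and peptide length at or above/within the profile's limits. All
#' comparisons are inclusive except the precursor mass error, which is a
#' strict |ppm| < max bound.
#'
#' @param psms PSM data.frame.
#' @param profile a [filter_profile()].
#' @return the retained subset (possibly empty).
#' @export
apply_fixed_subset_thresholds <- function(psms, profile) {
  len <- nchar(psms$sequence)
  keep <- psms$score >= profile$min_score &
    psms$spi_pct >= profile$min_spi_pct &
    abs(psms$mass_error_ppm) < profile$max_abs_ppm &
    psms$bcs >= profile$min_bcs &
    len >= profile$length_range[1] & len <= profile$length_range[2]
  psms[keep, , drop = FALSE]
}

#' BCS-by-score grid search for one peptide class
#'
#' Finds, over the finite (bcs, score) grid, the threshold pair that
#' retains the most targets while the estimated FDR of the surviving
#' subset is strictly below `fdr_target`; ties are broken toward the
#' smaller BCS, then the smaller score (the least aggressive tightening).
#' A class already below target therefore keeps the grid minima. When no
#' pair is feasible the class is flagged infeasible and retains nothing.
#'
#' @param psms PSMs of one class (already past the fixed thresholds).
#' @param bcs_grid,score_grid finite ascending candidate vectors starting
#'   at the profile's fixed minima.
#' @param fdr_target subset FDR target (default 0.01).
#' @return list with min_bcs, min_score, fdr_estimate, n_retained,
#'   feasible, and `accepted` (the retained subset).
#' @export
subset_grid_search <- function(psms, bcs_grid, score_grid, fdr_target = 0.01) {
  stopifnot(!is.unsorted(bcs_grid), !is.unsorted(score_grid))
  infeasible <- list(min_bcs = NA_real_, min_score = NA_real_,
                     fdr_estimate = NA_real_, n_retained = 0L,
                     feasible = FALSE,
                     accepted = psms[0, , drop = FALSE])
  if (NROW(psms) == 0 || !any(!psms$is_decoy)) return(infeasible)
  best <- NULL
  for (b in bcs_grid) for (s in score_grid) {
    keep <- psms$bcs >= b & psms$score >= s
    nt <- sum(keep & !psms$is_decoy)
    nd <- sum(keep & psms$is_decoy)
    if (nt == 0) next
    if (nd / nt < fdr_target) {
      cand <- list(b = b, s = s, nt = nt, nd = nd)
      if (is.null(best) || cand$nt > best$nt) best <- cand
      # ascending grids + first-hit keeps smaller (bcs, score) on ties
    }
  }
  if (is.null(best)) return(infeasible)
  keep <- psms$bcs >= best$b & psms$score >= best$s
  list(min_bcs = best$b, min_score = best$s,
       fdr_estimate = best$nd / best$nt,
       n_retained = as.integer(best$nt), feasible = TRUE,
       accepted = psms[keep, , drop = FALSE])
}

#' Subset-specific FDR control across peptide classes
#'
#' Canonical PSMs bypass the subset machinery (they are controlled by
#' [autovalidate()] alone). Every other class is put through the two-step
#' procedure: the profile's fixed thresholds first, then — only if the
#' class FDR estimate is still at or above target — the BCS-by-score grid
#' search.
#'
#' @param psms PSM data.frame (typically the autovalidated set).
#' @param profile [filter_profile()] used for the fixed step and as the
#'   grid origin.
#' @param fdr_target subset FDR target (default 0.01).
#' @param bcs_grid,score_grid candidate grids; defaults start at the
#'   profile minima with unit / half-unit steps.
#' @return list with `accepted` (disjoint union across classes) and
#'   `class_thresholds` (one row per non-canonical class).
#' @export
run_subset_fdr <- function(psms, profile, fdr_target = 0.01,
                           bcs_grid = NULL, score_grid = NULL) {
  known <- grepl("^(canonical|variant|contaminant|nuORF:.+)$",
                 psms$class_label)
  if (any(!known))
    stop("unknown class label(s): ",
         paste(unique(psms$class_label[!known]), collapse = ", "))
  if (is.null(bcs_grid))
    bcs_grid <- seq(profile$min_bcs, profile$min_bcs + 10, by = 1)
  if (is.null(score_grid))
    score_grid <- seq(profile$min_score, profile$min_score + 10, by = 0.5)
  canon <- psms$class_label == "canonical"
  out <- list(psms[canon, , drop = FALSE])
  rows <- list()
  for (cl in sort(unique(psms$class_label[!canon]))) {
    sub <- psms[psms$class_label == cl, , drop = FALSE]
    fixed <- apply_fixed_subset_thresholds(sub, profile)
    fdr_fixed <- if (NROW(fixed) == 0 || !any(!fixed$is_decoy)) Inf else
      estimate_fdr(fixed)
    if (fdr_fixed < fdr_target) {
      res <- list(min_bcs = bcs_grid[1], min_score = score_grid[1],
                  fdr_estimate = fdr_fixed,
                  n_retained = sum(!fixed$is_decoy), feasible = TRUE,
                  accepted = fixed)
      grid_used <- FALSE
    } else {
      res <- subset_grid_search(fixed, bcs_grid, score_grid, fdr_target)
      grid_used <- TRUE
    }
    out[[length(out) + 1L]] <- res$accepted
    rows[[length(rows) + 1L]] <- data.frame(
      class_label = cl, grid_search = grid_used,
      min_bcs = res$min_bcs, min_score = res$min_score,
      fdr_estimate = res$fdr_estimate, n_retained = res$n_retained,
      feasible = res$feasible, stringsAsFactors = FALSE)
  }
  accepted <- do.call(rbind, out)
  accepted <- accepted[order(match(accepted$spectrum_id, psms$spectrum_id)), ,
                       drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted,
       class_thresholds = if (length(rows)) do.call(rbind, rows) else NULL)
}
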