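# Shared fixtures: tiny hand-built PSM tables and brute-force oracles used
# across test files. Everything is built in code; no binary fixtures.

# A minimal valid PSM row; override any field through ...
psm_row <- function(spectrum_id = "sp1", run_id = "run01", plex_id = "plex1",
                    fraction_id = "f1", charge = 2L, precursor_mh = 1200,
                    mass_error_ppm = 0.5, score = 12, delta_rank_score = 2,
                    delta_fr_score = 3, bcs = 8, spi_pct = 75,
                    sequence = "ACDEFGHIK", modifications = "",
                    loc_top_score = NA_real_, loc_second_score = NA_real_,
                    is_decoy = FALSE, class_label = "canonical",
                    purity_pct = 90, tmt_labeled = TRUE,
                    proteins = "PROT0001", ...) {
  data.frame(spectrum_id = spectrum_id, run_id = run_id, plex_id = plex_id,
             fraction_id = fraction_id, charge = charge,
             precursor_mh = precursor_mh, mass_error_ppm = mass_error_ppm,
             score = score, delta_rank_score = delta_rank_score,
             delta_fr_score = delta_fr_score, bcs = bcs, spi_pct = spi_pct,
             sequence = sequence, modifications = modifications,
             loc_top_score = loc_top_score,
             loc_second_score = loc_second_score, is_decoy = is_decoy,
             class_label = class_label, purity_pct = purity_pct,
             tmt_labeled = tmt_labeled, proteins = proteins, ...,
             stringsAsFactors = FALSE)
}

psm_table <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Brute-force threshold optimizer over explicit candidate grids: enumerate
# every pair, apply the same conservative selection rule, return the best.
brute_force_pair_opt <- function(score, delta, is_decoy, target,
                                 s_cand, d_cand, n_decoy_extra = 1) {
  best <- NULL
  for (s in s_cand) for (d in d_cand) {
    acc <- score >= s & delta >= d
    nt <- sum(acc & !is_decoy); nd <- sum(acc & is_decoy)
    if (nt == 0) next
    if ((nd + n_decoy_extra) / nt <= target) {
      cand <- list(min_score = s, min_delta = d, nt = nt, nd = nd)
      if (is.null(best) || cand$nt > best$nt ||
          (cand$nt == best$nt && cand$nd < best$nd) ||
          (cand$nt == best$nt && cand$nd == best$nd &&
             (cand$min_score > best$min_score ||
                (cand$min_score == best$min_score &&
                   cand$min_delta > best$min_delta))))
        best <- cand
    }
  }
  best
}

# Brute-force subset grid search (strict FDR <, max targets, ties to the
# smaller bcs then smaller score).
brute_force_grid_search <- function(psms, bcs_grid, score_grid,
                                    fdr_target = 0.01) {
  best <- NULL
  for (b in bcs_grid) for (s in score_grid) {
    acc <- psms$bcs >= b & psms$score >= s
    nt <- sum(acc & !psms$is_decoy); nd <- sum(acc & psms$is_decoy)
    if (nt == 0) next
    if (nd / nt < fdr_target && (is.null(best) || nt > best$nt))
      best <- list(min_bcs = b, min_score = s, nt = nt, nd = nd)
  }
  best
}

# Direct restatement of the within-plex polishing rule, evaluated from the
# subgroup table of one plex.
brute_force_within_plex_removed <- function(psms) {
  eg <- expand_subgroups(psms, "expand")
  sg <- eg$subgroups
  thr <- if (any(sg$all_false)) max(sg$protein_score[sg$all_false]) else 0
  pp <- eg$peptides
  key <- paste(pp$group_id, pp$subgroup_id)
  skey <- paste(sg$group_id, sg$subgroup_id)
  bad <- skey[sg$protein_score < thr]
  pp$sequence[key %in% bad]
}

# 25-peptide HLA class I fixture with a known per-stage fate for every
# record. No decoys, so the pooled FDR stage accepts everything that
# reaches it and each removal is attributable to one deterministic stage.
hla_fixture <- function() {
  good <- function(id, seq, ...) {
    args <- list(...)
    defaults <- list(tag_length = 5, bcs = 8, charge = 2L,
                     precursor_mh = 1100, score = 10, spi_pct = 80,
                     is_human = TRUE)
    for (nm in setdiff(names(defaults), names(args)))
      args[[nm]] <- defaults[[nm]]
    do.call(psm_row, c(list(spectrum_id = id, sequence = seq), args))
  }
  psms <- psm_table(
    good("p01", "ALDFEQSIK"),                               # survivor
    good("p02", "SLYNTVATL", tag_length = 1),               # spectral: tag
    good("p03", "GILGFVFTL", precursor_mh = 5000),          # spectral: MH
    good("p04", "KVAELV"),                                  # min length 7
    good("p05", "NLVPMVATV", bcs = 4),                      # bcs < 5
    good("p06", "GLCTLVAML", charge = 5L),                  # charge range
    good("p07", "YLLEMLWRL"),                               # blank-bead list
    good("p08", "VLFGLGFAI"),                               # tryptic list
    good("p09", "TLWVDPYEV", is_human = FALSE),             # non-human
    good("p10", "RMSPNAPYL", modifications = "3:phospho",
         loc_top_score = 6, loc_second_score = 2, score = 6.0),
    good("p11", "SLLMWITQC", modifications = "1:phospho",
         loc_top_score = 6.5, loc_second_score = 1, score = 6.5,
         spi_pct = 60.0),
    good("p12", "SLSKILDTV", modifications = "1:phospho",
         loc_top_score = 6.5, loc_second_score = 1, score = 6.5,
         spi_pct = 61),                                     # survivor
    good("p13", "FLNAIHASQHEV"),                            # 12-mer
    good("p14", "LLFGYPV"),                                 # 7-mer: 8-11 only
    good("p15", "YMDGTMSQV"),
    good("p16", "KTWGQYWQV"),
    good("p17", "ITDQVPFSV"),
    good("p18", "YLEPGPVTA"),
    good("p19", "LLDGTATLRL"),
    good("p20", "VLYRYGSFSV"),
    good("p21", "IMDQVPFSV"),
    good("p22", "KLTPLCVTL"),
    good("p23", "FLPSDFFPSV"),
    good("p24", "AAGIGILTV"),
    good("p25", "ELAGIGILTV"))
  list(psms = psms,
       blank_bead = "YLLEMLWRL",
       tryptic = "VLFGLGFAI",
       survivors = c("p01", "p12", paste0("p", 15:25)))
}

# Per-feature fold-change estimates (second channel group minus first)
# aligned with the generator's truth table.
quant_fc_estimates <- function(q, truth) {
  nch <- ncol(q$matrix)
  half <- nch %/% 2
  est <- rowMeans(q$matrix[, (half + 1):nch]) - rowMeans(q$matrix[, 1:half])
  tm <- as.matrix(truth[, -1])
  names(est) <- rownames(q$matrix)
  tru <- rowMeans(tm[, (half + 1):nch]) - rowMeans(tm[, 1:half])
  names(tru) <- truth$feature_id
  list(est = est, tru = tru[names(est)])
}

# Straight-line restatement of grouping + allocation, written as naive
# loops (fixed-point merging instead of union-find, explicit per-peptide
# scans) for cross-checking expand_subgroups.
naive_subgroups <- function(psms) {
  seqs <- toupper(psms$sequence)
  pep <- lapply(unique(seqs), function(s) {
    idx <- which(seqs == s)
    best <- idx[order(-psms$score[idx], psms$spectrum_id[idx])][1]
    list(sequence = s, score = psms$score[best],
         proteins = sort(unique(unlist(strsplit(psms$proteins[idx], ";")))))
  })
  # fixed-point group merging over shared peptides of length >= 9
  groups <- as.list(sort(unique(unlist(lapply(pep, `[[`, "proteins")))))
  repeat {
    changed <- FALSE
    for (p in pep) {
      if (nchar(p$sequence) < 9 || length(p$proteins) < 2) next
      hit <- which(vapply(groups, function(g)
        any(p$proteins %in% g), TRUE))
      if (length(hit) > 1) {
        groups[[hit[1]]] <- sort(unique(unlist(groups[hit])))
        groups <- groups[-hit[-1]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # per-group classes by identical peptide support, seeded subgroups
  subs <- list()
  for (g in groups) {
    gp <- Filter(function(p) any(p$proteins %in% g), pep)
    support <- lapply(g, function(a)
      sort(vapply(Filter(function(p) a %in% p$proteins, gp),
                  `[[`, "", "sequence")))
    sig <- vapply(support, paste, "", collapse = "|")
    classes <- lapply(unique(sig), function(s) sort(g[sig == s]))
    classes <- classes[order(vapply(classes, min, ""))]
    uniq_score <- vapply(classes, function(cl)
      sum(vapply(gp, function(p)
        if (all(p$proteins %in% cl)) p$score else 0, 0)), 0)
    seeded <- which(vapply(classes, function(cl)
      any(vapply(gp, function(p) all(p$proteins %in% cl), TRUE)), TRUE))
    if (!length(seeded)) seeded <- 1L
    rank_order <- seeded[order(-uniq_score[seeded],
                               vapply(classes[seeded], min, ""))]
    assign_cl <- integer(length(classes))
    assign_cl[seeded] <- seeded
    for (ci in setdiff(seq_along(classes), seeded)) {
      shares <- vapply(rank_order, function(sc)
        any(vapply(gp, function(p)
          any(p$proteins %in% classes[[ci]]) &&
            any(p$proteins %in% classes[[sc]]), TRUE)), TRUE)
      assign_cl[ci] <- if (any(shares)) rank_order[which(shares)[1]] else
        rank_order[1]
    }
    for (si in seq_along(rank_order))
      subs[[length(subs) + 1]] <- list(
        members = sort(unlist(classes[assign_cl == rank_order[si]])),
        unique_score = uniq_score[rank_order[si]])
  }
  rank <- order(-vapply(subs, `[[`, 0, "unique_score"),
                vapply(subs, function(s) min(s$members), ""))
  alloc <- vapply(pep, function(p) {
    for (si in rank) if (any(p$proteins %in% subs[[si]]$members)) return(si)
    NA_integer_
  }, 1L)
  data.frame(
    members = vapply(subs, function(s) paste(s$members, collapse = ";"), ""),
    protein_score = vapply(seq_along(subs), function(si)
      sum(vapply(pep[alloc == si], `[[`, 0, "score")), 0),
    n_distinct_peptides = vapply(seq_along(subs), function(si)
      sum(alloc == si), 0L),
    stringsAsFactors = FALSE)
}

# Random small grouping instance: n_prot proteins, peptides with random
# protein support and scores.
random_grouping_instance <- function(n_prot, n_pep, seed) {
  set.seed(seed)
  accs <- sprintf("P%02d", seq_len(n_prot))
  rows <- lapply(seq_len(n_pep), function(i) {
    np <- sample(1:min(3, n_prot), 1)
    len <- sample(7:12, 1)
    psm_row(spectrum_id = sprintf("sp%03d", i),
            sequence = paste(sample(LETTERS[1:20], len, TRUE), collapse = ""),
            score = round(runif(1, 1, 20), 2),
            delta_fr_score = round(runif(1, -3, 6), 2),
            plex_id = sample(c("plex1", "plex2"), 1),
            proteins = paste(sample(accs, np), collapse = ";"))
  })
  do.call(rbind, rows)
}

discrete_mixture <- function(n, seed, n_runs = 1L, p_correct = 0.7,
                             score_levels = seq(1, 15, by = 0.5),
                             delta_levels = seq(0, 2, by = 0.25)) {
  # discrete score levels so the empirical candidate grid is the full
  # unique-value grid and a plain double loop can serve as the oracle
  set.seed(seed)
  correct <- runif(n) < p_correct
  is_decoy <- !correct & runif(n) < 0.5
  sc_hi <- sample(score_levels, n, TRUE,
                  prob = seq_along(score_levels))          # right-heavy
  sc_lo <- sample(score_levels, n, TRUE,
                  prob = rev(seq_along(score_levels)))     # left-heavy
  dl_hi <- sample(delta_levels, n, TRUE, prob = seq_along(delta_levels))
  dl_lo <- sample(delta_levels, n, TRUE, prob = rev(seq_along(delta_levels)))
  do.call(rbind, lapply(seq_len(n), function(i)
    psm_row(spectrum_id = sprintf("sp%05d", i),
            run_id = sprintf("run%02d", 1 + (i %% n_runs)),
            score = if (correct[i]) sc_hi[i] else sc_lo[i],
            delta_rank_score = if (correct[i]) dl_hi[i] else dl_lo[i],
            is_decoy = is_decoy[i])))
}

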