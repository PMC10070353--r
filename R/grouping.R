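# Parsimony protein grouping.
#
# Proteins sharing a peptide of sequence length > 8 fall into the same
# protein group (connected components; shorter shared peptides never
# create edges but still count as evidence for their proteins). Within a
# group, subgroups are seeded by unique-peptide support, and under the
# "top uses shared" mode each shared peptide is allocated to the highest
# scoring subgroup containing it, with the ranking computed once from the
# unique-peptide scores. The protein score is the sum of the scores of
# distinct peptides, a distinct peptide being the single highest-scoring
# instance of a sequence.

# minimal union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
.uf_union <- function(p, i, j) {
  ri <- .uf_find(p, i); rj <- .uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}
.uf_roots <- function(p) vapply(seq_along(p), function(i) .uf_find(p, i), 1L)

# distinct-peptide evidence table from accepted PSMs: one row per peptide
# sequence with its best PSM, candidate protein set, and whether every
# supporting PSM looks false (negative delta forward-reverse score)
.distinct_peptides <- function(psms) {
  seqs <- toupper(psms$sequence)
  prots <- split_tokens(psms$proteins)
  split_idx <- split(seq_len(NROW(psms)), seqs)
  rows <- lapply(names(split_idx), function(s) {
    idx <- split_idx[[s]]
    best <- idx[order(-psms$score[idx], psms$spectrum_id[idx])][1L]
    data.frame(sequence = s,
               best_score = psms$score[best],
               best_psm = psms$spectrum_id[best],
               proteins = paste(sort(unique(unlist(prots[idx]))),
                                collapse = ";"),
               all_negative = all(psms$delta_fr_score[idx] < 0),
               plexes = paste(sort(unique(psms$plex_id[idx])),
                              collapse = ";"),
               psm_ids = paste(psms$spectrum_id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$sequence), , drop = FALSE]
}

#' Build protein groups from peptide evidence
#'
#' @param psms accepted PSM data.frame (each row lists candidate proteins).
#' @param min_shared_length peptides must be strictly longer than 8
#'   residues (i.e. length >= 9) to link proteins into one group.
#' @return data.frame with columns accession, group_id; group ids are
#'   dense integers ordered by the lexicographically smallest member.
#' @export
build_groups <- function(psms, min_shared_length = 9L) {
  pep <- .distinct_peptides(psms)
  accs <- sort(unique(unlist(split_tokens(pep$proteins))))
  if (!length(accs))
    return(data.frame(accession = character(0), group_id = integer(0)))
  p <- .uf_new(length(accs))
  for (i in seq_len(nrow(pep))) {
    if (nchar(pep$sequence[i]) < min_shared_length) next
    members <- match(strsplit(pep$proteins[i], ";", fixed = TRUE)[[1]], accs)
    if (length(members) > 1)
      for (j in members[-1]) p <- .uf_union(p, members[1], j)
  }
  roots <- .uf_roots(p)
  gid <- match(roots, sort(unique(roots)))
  data.frame(accession = accs, group_id = gid, stringsAsFactors = FALSE)
}

# allocation of one group's peptides to subgroups; see expand_subgroups
.allocate_group <- function(pep, group_accs) {
  # full candidate protein sets: a peptide spanning groups (length <= 8)
  # supports member proteins but is never unique to any class
  pep_prots <- split_tokens(pep$proteins)
  # proteins with identical peptide-sequence support are indistinguishable
  prot_peps <- lapply(group_accs, function(a)
    sort(pep$sequence[vapply(pep_prots, function(pp) a %in% pp, TRUE)]))
  names(prot_peps) <- group_accs
  sig <- vapply(prot_peps, paste, "", collapse = "\r")
  classes <- split(group_accs, sig)
  classes <- classes[order(vapply(classes, min, ""))]
  # unique peptides: protein set contained in a single class
  class_of <- function(pp) {
    hits <- which(vapply(classes, function(cl) all(pp %in% cl), TRUE))
    if (length(hits) == 1L) hits else NA_integer_
  }
  uniq_class <- vapply(pep_prots, class_of, 1L)
  uniq_score <- vapply(seq_along(classes), function(ci)
    sum(pep$best_score[!is.na(uniq_class) & uniq_class == ci]), 0)
  seeded <- which(vapply(seq_along(classes), function(ci)
    any(!is.na(uniq_class) & uniq_class == ci), TRUE))
  if (!length(seeded)) seeded <- 1L   # no unique support anywhere: one subgroup
  # unseeded classes attach to the best-ranked seeded class sharing a peptide,
  # falling back to the top-ranked seeded class
  rank_order <- seeded[order(-uniq_score[seeded],
                             vapply(classes[seeded], min, ""))]
  assign_class <- integer(length(classes))
  assign_class[seeded] <- seeded
  for (ci in setdiff(seq_along(classes), seeded)) {
    shares <- vapply(rank_order, function(sc)
      any(vapply(pep_prots, function(pp)
        any(pp %in% classes[[ci]]) && any(pp %in% classes[[sc]]), TRUE)),
      TRUE)
    assign_class[ci] <- if (any(shares)) rank_order[which(shares)[1L]] else
      rank_order[1L]
  }
  subgroup_of_class <- match(assign_class, rank_order)  # NA never occurs
  members <- lapply(seq_along(rank_order), function(si)
    sort(unlist(classes[assign_class == rank_order[si]])))
  # allocate every peptide to the highest-ranked subgroup containing it
  alloc <- vapply(pep_prots, function(pp) {
    holds <- which(vapply(members, function(m) any(pp %in% m), TRUE))
    holds[1L]
  }, 1L)
  list(members = members, alloc = alloc,
       unique_score = uniq_score[rank_order],
       unique_pep = !is.na(uniq_class))
}

# Global subgroup structure: per-group seeding/ranking as in
# .allocate_group, then one allocation pass over all distinct peptides so
# that a peptide spanning several groups (possible only below the
# group-linking length) is still allocated exactly once, to the
# highest-ranked subgroup containing any of its proteins.
.subgroup_structure <- function(pep_all, groups) {
  subs <- list()
  for (g in sort(unique(groups$group_id))) {
    gaccs <- groups$accession[groups$group_id == g]
    in_group <- vapply(split_tokens(pep_all$proteins),
                       function(pp) any(pp %in% gaccs), TRUE)
    al <- .allocate_group(pep_all[in_group, , drop = FALSE], gaccs)
    for (si in seq_along(al$members))
      subs[[length(subs) + 1L]] <- list(group_id = g, subgroup_id = si,
                                        members = al$members[[si]],
                                        unique_score = al$unique_score[si])
  }
  rank <- order(-vapply(subs, `[[`, 0, "unique_score"),
                vapply(subs, function(s) min(s$members), ""))
  pep_prots <- split_tokens(pep_all$proteins)
  alloc <- vapply(pep_prots, function(pp) {
    holds <- rank[vapply(rank, function(si)
      any(pp %in% subs[[si]]$members), TRUE)]
    holds[1L]
  }, 1L)
  unique_pep <- vapply(seq_along(pep_prots), function(i)
    all(pep_prots[[i]] %in% subs[[alloc[i]]]$members), TRUE)
  list(subs = subs, alloc = alloc, unique_pep = unique_pep)
}

#' Expand a protein group into scored subgroups
#'
#' Subgroups are seeded by proteins with unique distinct-peptide support
#' (proteins with identical peptide sets are indistinguishable and share
#' a subgroup). Subgroup ranking uses the unique-peptide scores, computed
#' once; each shared peptide is then allocated to the highest-ranked
#' subgroup containing it ("top uses shared"). In "unexpand" mode the
#' whole group is reported as one row whose peptides are the union, with
#' each shared peptide still attributed once, to the top-ranked subgroup,
#' which is what PTM-site reports use. Ties rank by accession order.
#'
#' @param psms accepted PSM data.frame.
#' @param mode "expand" (one row per subgroup) or "unexpand" (one row per
#'   group).
#' @param min_shared_length see [build_groups()].
#' @return list with `subgroups` (data.frame: group_id, subgroup_id,
#'   members, protein_score, n_distinct_peptides, plexes, all_false) and
#'   `peptides` (data.frame mapping each distinct peptide to its group,
#'   subgroup and best PSM).
#' @export
expand_subgroups <- function(psms, mode = c("expand", "unexpand"),
                             min_shared_length = 9L) {
  mode <- match.arg(mode)
  pep_all <- .distinct_peptides(psms)
  groups <- build_groups(psms, min_shared_length)
  st <- .subgroup_structure(pep_all, groups)
  grows <- list(); prows <- list()
  peptides <- data.frame(
    sequence = pep_all$sequence,
    group_id = vapply(st$alloc, function(si) st$subs[[si]]$group_id, 1L),
    subgroup_id = vapply(st$alloc, function(si) st$subs[[si]]$subgroup_id,
                         1L),
    best_score = pep_all$best_score, best_psm = pep_all$best_psm,
    unique_peptide = st$unique_pep, stringsAsFactors = FALSE)
  for (si in seq_along(st$subs)) {
    s <- st$subs[[si]]
    sel <- st$alloc == si
    grows[[length(grows) + 1L]] <- data.frame(
      group_id = s$group_id, subgroup_id = s$subgroup_id,
      members = paste(s$members, collapse = ";"),
      protein_score = sum(pep_all$best_score[sel]),
      n_distinct_peptides = sum(sel),
      plexes = paste(sort(unique(unlist(
        split_tokens(pep_all$plexes[sel])))), collapse = ";"),
      all_false = any(sel) && all(pep_all$all_negative[sel]),
      stringsAsFactors = FALSE)
  }
  subgroups_expand <- do.call(rbind, grows)
  if (mode == "unexpand") {
    # one row per group; peptide attribution (top-ranked subgroup) retained
    grows <- lapply(sort(unique(groups$group_id)), function(g) {
      sel <- peptides$group_id == g
      data.frame(
        group_id = g, subgroup_id = 1L,
        members = paste(sort(groups$accession[groups$group_id == g]),
                        collapse = ";"),
        protein_score = sum(peptides$best_score[sel]),
        n_distinct_peptides = sum(sel),
        plexes = paste(sort(unique(unlist(
          split_tokens(pep_all$plexes[sel])))), collapse = ";"),
        all_false = any(sel) && all(pep_all$all_negative[sel]),
        stringsAsFactors = FALSE)
    })
  } else {
    grows <- list(subgroups_expand)
  }
  prows <- list(peptides)
  subgroups <- if (length(grows)) do.call(rbind, grows) else
    data.frame(group_id = integer(0), subgroup_id = integer(0),
               members = character(0), protein_score = numeric(0),
               n_distinct_peptides = integer(0), plexes = character(0),
               all_false = logical(0))
  peptides <- if (length(prows)) do.call(rbind, prows) else
    data.frame(sequence = character(0), group_id = integer(0),
               subgroup_id = integer(0), best_score = numeric(0),
               best_psm = character(0), unique_peptide = logical(0))
  rownames(subgroups) <- rownames(peptides) <- NULL
  list(subgroups = subgroups, peptides = peptides)
}

#' Within-plex protein polishing
#'
#' Per TMT plex: assemble subgroups, find the maximum protein score among
#' subgroups consisting entirely of likely-false distinct peptides (every
#' supporting PSM has a negative delta forward-reverse score; 0 when no
#' such subgroup exists), and remove all PSMs contributing to subgroups
#' scoring strictly below that maximum. Targets single-peptide
#' "one-hit wonders" at a protein-level FDR of zero.
#'
#' @param psms accepted PSM data.frame.
#' @param min_shared_length see [build_groups()].
#' @return the retained PSMs; removed rows are available in the
#'   `removed` attribute.
#' @export
polish_within_plex <- function(psms, min_shared_length = 9L) {
  keep <- logical(NROW(psms))
  for (px in unique(psms$plex_id)) {
    sel <- which(psms$plex_id == px)
    sub <- psms[sel, , drop = FALSE]
    eg <- expand_subgroups(sub, "expand", min_shared_length)
    sg <- eg$subgroups
    thr <- if (any(sg$all_false)) max(sg$protein_score[sg$all_false]) else 0
    bad_sub <- sg[sg$protein_score < thr, c("group_id", "subgroup_id")]
    pp <- eg$peptides
    bad_pep <- pp$sequence[paste(pp$group_id, pp$subgroup_id) %in%
                             paste(bad_sub$group_id, bad_sub$subgroup_id)]
    keep[sel] <- !(toupper(sub$sequence) %in% bad_pep)
  }
  out <- psms[keep, , drop = FALSE]
  attr(out, "removed") <- psms[!keep, , drop = FALSE]
  out
}

#' Cross-plex protein polishing
#'
#' Retains protein subgroups scoring at least `min_score` or observed in
#' at least `min_plexes` TMT plexes.
#'
#' @param subgroups subgroup table from [expand_subgroups()].
#' @param min_score minimum protein score (default 25, inclusive).
#' @param min_plexes minimum distinct plexes (default 2).
#' @return the retained subgroup rows.
#' @export
polish_cross_plex <- function(subgroups, min_score = 25, min_plexes = 2L) {
  if (NROW(subgroups) == 0) return(subgroups)
  n_plex <- lengths(split_tokens(subgroups$plexes))
  keep <- subgroups$protein_score >= min_score | n_plex >= min_plexes
  subgroups[keep, , drop = FALSE]
}
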