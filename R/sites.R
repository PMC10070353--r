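# Variable-modification (VM) site assembly.
#
# An observation's localization confidence comes from the difference
# between the identification scores of the top two candidate
# localizations; the confident-call threshold is a difference strictly
# greater than 1.1. Observations of the same site (same protein, same
# modification type, same number of sites) are combined across charge
# states, missed-cleavage forms and confident/ambiguous localizations,
# but never across different confident localizations or differing site
# counts.

# acceptor residues per modification type; ambiguity windows are the
# acceptor positions within the peptide
.mod_acceptors <- c(phospho = "STY", acetyl = "K", diGly = "K")

#' Classify localization confidence
#'
#' A site localization is confident when the top candidate's score exceeds
#' the runner-up's by strictly more than `threshold` (default 1.1). A
#' single-candidate localization (no runner-up) is confident by
#' convention: no competing placement exists.
#'
#' @param top_score,second_score numeric vectors; `second_score` may be NA.
#' @param threshold confident-call score difference (strict).
#' @return logical vector.
#' @export
classify_localization <- function(top_score, second_score, threshold = 1.1) {
  if (any(!is.na(second_score) & top_score < second_score))
    stop("localization pair reversed: top_score < second_score")
  ifelse(is.na(second_score), TRUE, (top_score - second_score) > threshold)
}

# candidate protein positions for an ambiguous observation: every acceptor
# residue of the mod type within the peptide, in protein coordinates
.ambiguity_window <- function(sequence, mod_type, offset) {
  acc <- .mod_acceptors[[mod_type]]
  if (is.null(acc)) return(integer(0))
  pos <- which(strsplit(toupper(sequence), "")[[1]] %in%
                 strsplit(acc, "")[[1]])
  as.integer(offset + pos - 1L)
}

# One observation record per (PSM, mod_type): mapped positions, confidence,
# ambiguity window. proteins = named character vector of sequences.
.site_observations <- function(psms, proteins) {
  mods <- parse_modifications(psms$modifications)
  cand <- split_tokens(psms$proteins)
  out <- list()
  for (i in seq_len(NROW(psms))) {
    m <- mods[[i]]
    if (nrow(m) == 0) next
    accs <- intersect(cand[[i]], names(proteins))
    if (!length(accs)) next
    acc <- accs[1L]                        # first mappable accession
    pep <- toupper(psms$sequence[i])
    hit <- regexpr(pep, proteins[[acc]], fixed = TRUE)
    if (hit == -1L) next
    conf <- classify_localization(psms$loc_top_score[i],
                                  psms$loc_second_score[i])
    for (mt in unique(m$mod_type)) {
      pp <- sort(as.integer(hit + m$position[m$mod_type == mt] - 1L))
      window <- if (conf) pp else
        sort(unique(c(pp, .ambiguity_window(psms$sequence[i], mt, hit))))
      out[[length(out) + 1L]] <- list(
        spectrum_id = psms$spectrum_id[i], protein = acc, mod_type = mt,
        n_mods = length(pp), positions = pp, window = window,
        confident = isTRUE(conf), score = psms$score[i],
        pep_length = nchar(psms$sequence[i]), plex_id = psms$plex_id[i])
    }
  }
  out
}

#' Select the representative observation of a VM-site row
#'
#' Preference order: confident localization first, then higher
#' identification score, then longer peptide, then the smaller spectrum id
#' as a deterministic tie-break. Invariant to member order.
#'
#' @param members data.frame with columns spectrum_id, confident, score,
#'   pep_length.
#' @return the representative spectrum_id.
#' @export
select_representative <- function(members) {
  stopifnot(NROW(members) > 0)
  ord <- order(-as.integer(members$confident), -members$score,
               -members$pep_length, members$spectrum_id)
  members$spectrum_id[ord[1L]]
}

#' Assemble the VM-site table
#'
#' Combines non-conflicting observations of a modification site into one
#' row: rows are keyed by (protein, modification type, number of sites,
#' position set). Confident observations with identical position sets
#' share a row; an ambiguous observation joins a confident row when its
#' ambiguity window contains that row's positions (the row with the
#' highest confident score wins when several qualify); ambiguous
#' observations matching no confident row form rows keyed by their full
#' candidate window, merged only with identical windows. Observations
#' differing in site count, or with different confident localizations,
#' are never combined.
#'
#' @param psms PSM data.frame (modified PSMs; unmodified rows are ignored).
#' @param proteins named character vector of protein sequences.
#' @return data.frame, one row per VM site, with columns protein,
#'   mod_type, n_mods, positions (";"-joined), confident, best_score,
#'   representative, n_obs, plexes (";"-joined), member_ids (";"-joined).
#' @export
build_site_table <- function(psms, proteins) {
  obs <- .site_observations(psms, proteins)
  empty <- data.frame(protein = character(0), mod_type = character(0),
                      n_mods = integer(0), positions = character(0),
                      confident = logical(0), best_score = numeric(0),
                      representative = character(0), n_obs = integer(0),
                      plexes = character(0), member_ids = character(0),
                      stringsAsFactors = FALSE)
  if (!length(obs)) return(empty)
  grp_key <- vapply(obs, function(o)
    paste(o$protein, o$mod_type, o$n_mods, sep = "\r"), "")
  rows <- list()
  for (g in sort(unique(grp_key))) {
    members <- obs[grp_key == g]
    conf <- Filter(function(o) o$confident, members)
    ambi <- Filter(function(o) !o$confident, members)
    # one bucket per distinct confident position set
    buckets <- list()
    for (o in conf) {
      k <- paste(o$positions, collapse = ";")
      buckets[[k]] <- c(buckets[[k]], list(o))
    }
    conf_keys <- names(buckets)
    conf_sets <- lapply(conf_keys, function(k)
      as.integer(strsplit(k, ";", fixed = TRUE)[[1]]))
    conf_best <- vapply(conf_keys, function(k)
      max(vapply(buckets[[k]], `[[`, 0, "score")), 0)
    # route each ambiguous observation
    for (o in ambi) {
      containing <- which(vapply(conf_sets, function(s)
        all(s %in% o$window), TRUE))
      if (length(containing)) {
        pick <- containing[order(-conf_best[containing],
                                 conf_keys[containing])][1L]
        k <- conf_keys[pick]
      } else {
        k <- paste("?", paste(o$window, collapse = ";"))
      }
      buckets[[k]] <- c(buckets[[k]], list(o))
    }
    for (k in sort(names(buckets))) {
      mem <- buckets[[k]]
      df <- data.frame(
        spectrum_id = vapply(mem, `[[`, "", "spectrum_id"),
        confident = vapply(mem, `[[`, TRUE, "confident"),
        score = vapply(mem, `[[`, 0, "score"),
        pep_length = vapply(mem, `[[`, 0L, "pep_length"),
        plex_id = vapply(mem, `[[`, "", "plex_id"),
        stringsAsFactors = FALSE)
      any_conf <- any(df$confident)
      pos_str <- if (any_conf) k else sub("^\\? ", "", k)
      first <- mem[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein = first$protein, mod_type = first$mod_type,
        n_mods = first$n_mods, positions = pos_str,
        confident = any_conf, best_score = max(df$score),
        representative = select_representative(df),
        n_obs = nrow(df),
        plexes = paste(sort(unique(df$plex_id)), collapse = ";"),
        member_ids = paste(sort(df$spectrum_id), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$mod_type, out$positions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-plex VM-site polishing
#'
#' Retains site rows scoring at least `min_score` or observed in at least
#' `min_plexes` TMT plexes; removes the low-scoring, infrequently observed
#' remainder.
#'
#' @param site_table output of [build_site_table()].
#' @param min_score minimum best identification score (default 8.0,
#'   inclusive).
#' @param min_plexes minimum number of distinct plexes (default 2).
#' @return the retained rows.
#' @export
polish_sites <- function(site_table, min_score = 8.0, min_plexes = 2L) {
  if (NROW(site_table) == 0) return(site_table)
  n_plex <- lengths(split_tokens(site_table$plexes))
  keep <- site_table$best_score >= min_score | n_plex >= min_plexes
  site_table[keep, , drop = FALSE]
}

#' C-terminal modified-lysine filter
#'
#' Trypsin and Lys-C cannot cleave at a ubiquitylated or acetylated
#' lysine, so peptides whose last three residues match `[^K][^K]k`
#' (modified lysine rendered lowercase) are removed. An unmodified K in
#' either of the two preceding positions rescues the peptide (a missed
#' cleavage with ambiguous site localization). Peptides shorter than
#' three residues are retained.
#'
#' @param peptides character vector of sequences with modified lysine as
#'   lowercase "k".
#' @return the retained peptides.
#' @export
cterm_mod_lysine_filter <- function(peptides) {
  drop <- nchar(peptides) >= 3 & grepl("[^K][^K]k$", peptides)
  peptides[!drop]
}
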