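# HLA class I / class II immunopeptidome filtering and summaries.
#
# The filter chain runs in the fixed order: spectral quality -> class
# PSM filters (length/BCS/charge) -> pooled FDR autovalidation ->
# contaminant removal -> modified-peptide quality -> HLA-I length
# restriction. Every removal is attributed to exactly one named stage in
# the audit table.

#' Spectral-quality record filter
#'
#' HLA mode keeps spectra with a sequence tag length > 1 (at least three
#' peaks separated by consecutive in-chain residue masses) and precursor
#' MH+ inside 600-4000 Da (inclusive); global mode uses tag length > 0
#' and MH+ 800-6000 Da.
#'
#' @param psms PSM data.frame with a `tag_length` column.
#' @param mode "hla" or "global".
#' @return the retained rows.
#' @export
spectral_quality_filter <- function(psms, mode = c("hla", "global")) {
  mode <- match.arg(mode)
  if (is.null(psms$tag_length))
    stop("spectral_quality_filter requires a 'tag_length' column")
  min_tag <- if (mode == "hla") 2L else 1L
  mh <- if (mode == "hla") c(600, 4000) else c(800, 6000)
  keep <- psms$tag_length >= min_tag &
    psms$precursor_mh >= mh[1] & psms$precursor_mh <= mh[2]
  psms[keep, , drop = FALSE]
}

#' Class-specific HLA PSM filter plus pooled FDR
#'
#' PSM-level thresholding with a minimum peptide length of 7, a minimum
#' backbone cleavage score of 5, the class-allowed precursor charges
#' (HLA-I: 1-4, HLA-II: 2-6), then target-decoy autovalidation pooled
#' across all fractions at 1.0% FDR.
#'
#' @param psms PSM data.frame.
#' @param hla_class "I" or "II".
#' @return list with `accepted` and the autovalidation `thresholds`.
#' @export
hla_psm_filter <- function(psms, hla_class = c("I", "II")) {
  hla_class <- match.arg(hla_class)
  cr <- if (hla_class == "I") c(1L, 4L) else c(2L, 6L)
  keep <- nchar(psms$sequence) >= 7 & psms$bcs >= 5 &
    psms$charge >= cr[1] & psms$charge <= cr[2]
  pre <- psms[keep, , drop = FALSE]
  av <- autovalidate(pre, autovalidation_targets(
    if (hla_class == "I") "hla1" else "hla2"))
  av
}

#' Contaminant removal
#'
#' Removes peptides exactly matching the blank-bead negative-control IP
#' list or the tryptic contaminant list, and peptides whose candidate
#' proteins are all annotated non-human (species annotation is a
#' `species` column or a "<acc>|<species>" accession suffix convention;
#' here a logical `is_human` column is used when present, else all rows
#' count as human).
#'
#' @param psms PSM data.frame.
#' @param blank_bead_list,tryptic_list character vectors of peptide
#'   sequences (see [read_peptide_list()]).
#' @return the retained rows; removals audited in the `audit` attribute.
#' @export
contaminant_filter <- function(psms, blank_bead_list = character(0),
                               tryptic_list = character(0)) {
  seqs <- toupper(psms$sequence)
  in_bb <- seqs %in% toupper(blank_bead_list)
  in_tr <- seqs %in% toupper(tryptic_list)
  non_human <- if (!is.null(psms$is_human)) !psms$is_human else
    rep(FALSE, NROW(psms))
  drop <- in_bb | in_tr | non_human
  out <- psms[!drop, , drop = FALSE]
  attr(out, "audit") <- data.frame(
    reason = c("blank_bead", "tryptic", "non_human"),
    removed = c(sum(in_bb), sum(in_tr & !in_bb),
                sum(non_human & !in_bb & !in_tr)))
  out
}

#' Modified-peptide quality filter
#'
#' Phospho and acetyl HLA peptides must have an identification score
#' strictly above 6 and scored peak intensity strictly above 60%;
#' unmodified peptides pass through.
#'
#' @param psms PSM data.frame.
#' @return the retained rows.
#' @export
modified_hla_filter <- function(psms) {
  mods <- parse_modifications(psms$modifications)
  modified <- vapply(mods, function(m)
    any(m$mod_type %in% c("phospho", "acetyl")), TRUE)
  keep <- !modified | (psms$score > 6 & psms$spi_pct > 60)
  psms[keep, , drop = FALSE]
}

#' HLA-I final length restriction
#'
#' The reported HLA class I set includes only 8-11mers.
#'
#' @param psms PSM data.frame.
#' @return the retained rows.
#' @export
hla_class1_final_filter <- function(psms) {
  len <- nchar(psms$sequence)
  psms[len >= 8 & len <= 11, , drop = FALSE]
}

#' Run the full HLA filter chain with a stage-attributed audit
#'
#' @param psms PSM data.frame (with `tag_length`).
#' @param hla_class "I" or "II".
#' @param blank_bead_list,tryptic_list contaminant peptide vectors.
#' @return list with `accepted`, `audit` (stage, n_in, n_removed, n_out;
#'   removals sum to input minus output) and the FDR `thresholds`.
#' @export
hla_filter_chain <- function(psms, hla_class = c("I", "II"),
                             blank_bead_list = character(0),
                             tryptic_list = character(0)) {
  hla_class <- match.arg(hla_class)
  audit <- list()
  note <- function(stage, n_in, n_out)
    data.frame(stage = stage, n_in = n_in, n_removed = n_in - n_out,
               n_out = n_out, stringsAsFactors = FALSE)
  cr <- if (hla_class == "I") c(1L, 4L) else c(2L, 6L)
  s1 <- spectral_quality_filter(psms, "hla")
  audit[[1]] <- note("spectral_quality", NROW(psms), NROW(s1))
  s1a <- s1[nchar(s1$sequence) >= 7, , drop = FALSE]
  audit[[2]] <- note("min_length_7", NROW(s1), NROW(s1a))
  s1b <- s1a[s1a$bcs >= 5, , drop = FALSE]
  audit[[3]] <- note("min_bcs_5", NROW(s1a), NROW(s1b))
  s1c <- s1b[s1b$charge >= cr[1] & s1b$charge <= cr[2], , drop = FALSE]
  audit[[4]] <- note("charge_range", NROW(s1b), NROW(s1c))
  fd <- autovalidate(s1c, autovalidation_targets(
    if (hla_class == "I") "hla1" else "hla2"))
  s2 <- fd$accepted[!fd$accepted$is_decoy, , drop = FALSE]  # no decoys reported
  audit[[5]] <- note("fdr_autovalidation", NROW(s1c), NROW(s2))
  s3 <- contaminant_filter(s2, blank_bead_list, tryptic_list)
  audit[[6]] <- note("contaminants", NROW(s2), NROW(s3))
  s4 <- modified_hla_filter(s3)
  audit[[7]] <- note("modified_quality", NROW(s3), NROW(s4))
  s5 <- if (hla_class == "I") hla_class1_final_filter(s4) else s4
  audit[[8]] <- note("length_restriction", NROW(s4), NROW(s5))
  list(accepted = s5, audit = do.call(rbind, audit),
       thresholds = fd$thresholds)
}

# ---- summaries -------------------------------------------------------------

#' Peptide length distribution
#'
#' @param peptides character vector.
#' @return named integer vector, length -> count (empty input -> empty).
#' @export
length_distribution <- function(peptides) {
  if (!length(peptides)) return(integer(0))
  tab <- table(nchar(peptides))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Position-frequency matrix of equal-length peptides
#'
#' @param peptides character vector, all of one length.
#' @return 20 x L matrix; entry (aa, pos) is the fraction of peptides
#'   carrying that residue at that position, so every column sums to 1.
#' @export
position_frequency_matrix <- function(peptides) {
  if (!length(peptides)) stop("no peptides")
  lens <- unique(nchar(peptides))
  if (length(lens) != 1) stop("mixed peptide lengths: ",
                              paste(lens, collapse = ", "))
  L <- lens
  m <- matrix(0, length(.aa20), L,
              dimnames = list(.aa20, paste0("P", seq_len(L))))
  chars <- do.call(rbind, strsplit(toupper(peptides), ""))
  for (p in seq_len(L)) {
    tab <- table(factor(chars[, p], levels = .aa20))
    m[, p] <- as.numeric(tab) / length(peptides)
  }
  m
}

#' Group HLA class II peptides into nested sets
#'
#' Two peptides join one set when one contains the other as a substring
#' or they share a common substring of at least `core_length` residues
#' (the class II binding core); groups are the transitive closure.
#'
#' @param peptides character vector (unique sequences).
#' @param core_length shared-core length (default 9).
#' @return integer vector of group ids, parallel to `peptides`; groups
#'   partition the input.
#' @export
nested_set_grouping <- function(peptides, core_length = 9L) {
  n <- length(peptides)
  if (!n) return(integer(0))
  peptides <- toupper(peptides)
  p <- .uf_new(n)
  # bucket by k-mer: any two peptides sharing a core_length-mer unite;
  # containment of peptides shorter than the core is handled pairwise
  kmers <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- peptides[i]
    L <- nchar(s)
    if (L < core_length) next
    for (st in seq_len(L - core_length + 1L)) {
      k <- substr(s, st, st + core_length - 1L)
      prev <- kmers[[k]]
      if (is.null(prev)) kmers[[k]] <- i else p <- .uf_union(p, prev, i)
    }
  }
  short <- which(nchar(peptides) < core_length)
  for (i in short) for (j in seq_len(n)) {
    if (i != j && grepl(peptides[i], peptides[j], fixed = TRUE))
      p <- .uf_union(p, i, j)
  }
  roots <- .uf_roots(p)
  match(roots, unique(roots))
}

#' PTM position distribution of modified peptides
#'
#' @param psms PSM data.frame of modified peptides.
#' @param mod_type optional modification type to restrict to.
#' @return named numeric vector, peptide position -> fraction of
#'   modification sites at that position (sums to 1; empty -> empty).
#' @export
ptm_position_summary <- function(psms, mod_type = NULL) {
  mods <- parse_modifications(psms$modifications)
  pos <- unlist(lapply(mods, function(m) {
    if (!is.null(mod_type)) m <- m[m$mod_type == mod_type, , drop = FALSE]
    m$position
  }))
  if (!length(pos)) return(numeric(0))
  tab <- table(pos)
  out <- as.numeric(tab) / length(pos)
  names(out) <- names(tab)
  out
}
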