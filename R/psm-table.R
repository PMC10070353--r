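#' @keywords internal
"_PACKAGE"

# Mandatory columns of the on-disk PSM table (tab-delimited, header row).
# Reporter intensities follow as reporter_<channel> columns; extra columns
# are carried through untouched so real search-engine exports stay loadable.
.psm_mandatory_cols <- c(
  "spectrum_id", "run_id", "plex_id", "fraction_id", "charge",
  "precursor_mh", "mass_error_ppm", "score", "delta_rank_score",
  "delta_fr_score", "bcs", "spi_pct", "sequence", "modifications",
  "loc_top_score", "loc_second_score", "is_decoy", "class_label",
  "purity_pct", "tmt_labeled", "proteins"
)

#' Describe a TMT plex design
#'
#' A plex design names the ordered reporter channels of one isobaric
#' labeling experiment and (optionally) maps each channel to a sample and
#' designates a common reference channel.
#'
#' @param plex_id plex identifier token.
#' @param channels ordered character vector of unique channel labels; the
#'   order defines the reagent isotope series used for impurity spill.
#' @param sample_map optional named character vector, channel -> sample.
#' @param reference_channel optional channel label used as ratio denominator.
#' @return an object of class `plex_design`.
#' @export
plex_design <- function(plex_id, channels, sample_map = NULL,
                        reference_channel = NULL) {
  stopifnot(is.character(channels), length(channels) >= 1)
  if (anyDuplicated(channels))
    stop("plex_design: duplicated channel labels")
  if (!is.null(reference_channel) && !reference_channel %in% channels)
    stop("plex_design: reference_channel '", reference_channel,
         "' is not a member of channels")
  if (!is.null(sample_map)) {
    if (is.null(names(sample_map)) || !all(names(sample_map) %in% channels))
      stop("plex_design: sample_map names must be channel labels")
  }
  structure(list(plex_id = as.character(plex_id),
                 channels = as.character(channels),
                 sample_map = sample_map,
                 reference_channel = reference_channel),
            class = "plex_design")
}

#' @export
print.plex_design <- function(x, ...) {
  cat("TMT plex design '", x$plex_id, "': ", length(x$channels),
      " channels (", paste(x$channels, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$reference_channel))
    cat("  reference channel:", x$reference_channel, "\n")
  invisible(x)
}

#' Named filter profiles
#'
#' Fixed record-level threshold sets for the four dataset types. The
#' common subset thresholds (minimum identification score 7, minimum
#' scored peak intensity 50%, precursor mass error strictly inside
#' +/- 5 ppm) are shared by all profiles; the HLA profiles add a minimum
#' backbone cleavage score of 5 with class-specific length and charge
#' ranges, and the PTM profile uses a minimum BCS of 4 with lengths 7-50.
#' Spectral-quality constants (minimum sequence tag length; precursor MH+
#' inclusion window, 600-4000 Da for HLA data and 800-6000 Da otherwise)
#' ride along on the same object.
#'
#' @param name one of "HLA-I", "HLA-II", "PTM-ome", "proteome".
#' @return an immutable `filter_profile` list of named constants.
#' @export
filter_profile <- function(name = c("HLA-I", "HLA-II", "PTM-ome", "proteome")) {
  name <- match.arg(name)
  base <- list(name = name, min_score = 7, min_spi_pct = 50, max_abs_ppm = 5)
  extra <- switch(name,
    "HLA-I"  = list(min_bcs = 5, length_range = c(8L, 12L),
                    charge_range = c(1L, 4L), mh_range = c(600, 4000),
                    min_tag_length = 2L),
    "HLA-II" = list(min_bcs = 5, length_range = c(9L, 50L),
                    charge_range = c(2L, 6L), mh_range = c(600, 4000),
                    min_tag_length = 2L),
    "PTM-ome" = list(min_bcs = 4, length_range = c(7L, 50L),
                     charge_range = c(2L, 6L), mh_range = c(800, 6000),
                     min_tag_length = 1L),
    "proteome" = list(min_bcs = 0, length_range = c(7L, 50L),
                      charge_range = c(2L, 6L), mh_range = c(800, 6000),
                      min_tag_length = 1L))
  prof <- c(base, extra)
  stopifnot(prof$length_range[1] <= prof$length_range[2],
            prof$charge_range[1] <= prof$charge_range[2],
            prof$mh_range[1] <= prof$mh_range[2])
  class(prof) <- "filter_profile"
  prof
}

# ---- modification / protein list encodings --------------------------------

#' Parse a modification annotation string
#'
#' Modifications are serialized as "pos:type" pairs joined by ";", e.g.
#' "4:phospho;9:acetyl". Positions are 1-based peptide coordinates. A
#' modified lysine is additionally rendered as lowercase "k" in the
#' sequence string itself, so the C-terminal cleavage rule can be applied
#' directly to sequences.
#'
#' @param x character vector of annotation strings ("" = unmodified).
#' @return list of data.frames with columns `position`, `mod_type`.
#' @export
parse_modifications <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(position = integer(0), mod_type = character(0),
                        stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("unparseable modification annotation: '", s, "'")
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               mod_type = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
}

#' @rdname parse_modifications
#' @param mods list of modification data.frames.
#' @export
format_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0) return("")
    paste(paste0(m$position, ":", m$mod_type), collapse = ";")
  }, "")
}

split_tokens <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

# ---- validation ------------------------------------------------------------

#' Validate a PSM table against its invariants
#'
#' Checks the record-level invariants: charge in 1..6, percentages within
#' 0-100, non-negative delta rank score, ordered localization pair,
#' modification positions inside the peptide, and (when a design is given)
#' one reporter column per channel.
#'
#' @param psms data.frame as returned by [read_psm_table()].
#' @param design optional [plex_design()] to check reporter columns against.
#' @return invisibly `TRUE`; stops with offending row numbers otherwise.
#' @export
validate_psm_table <- function(psms, design = NULL) {
  missing <- setdiff(.psm_mandatory_cols, names(psms))
  if (length(missing))
    stop("PSM table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  fail <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop("PSM table invariant violated (", what, ") at row(s): ",
           paste(utils::head(which(cond), 10), collapse = ", "))
  }
  fail(psms$charge < 1 | psms$charge > 6, "charge in [1,6]")
  fail(psms$spi_pct < 0 | psms$spi_pct > 100, "spi_pct in [0,100]")
  fail(psms$purity_pct < 0 | psms$purity_pct > 100, "purity_pct in [0,100]")
  fail(psms$delta_rank_score < 0, "delta_rank_score >= 0")
  both <- !is.na(psms$loc_top_score) & !is.na(psms$loc_second_score)
  fail(both & psms$loc_top_score < psms$loc_second_score,
       "localization pair ordered")
  mods <- parse_modifications(psms$modifications)
  bad_pos <- mapply(function(m, s) nrow(m) > 0 && any(m$position > nchar(s) |
                                                      m$position < 1),
                    mods, psms$sequence)
  fail(bad_pos, "modification positions within sequence")
  if (!is.null(design)) {
    rep_cols <- grep("^reporter_", names(psms), value = TRUE)
    want <- paste0("reporter_", design$channels)
    if (!setequal(rep_cols, want))
      stop("reporter columns (", length(rep_cols),
           ") do not match design channel count (", length(design$channels),
           "): expected ", paste(want, collapse = ", "))
    for (rc in rep_cols)
      fail(psms[[rc]] < 0, paste0(rc, " non-negative"))
  }
  invisible(TRUE)
}

# ---- readers / writers -----------------------------------------------------

#' Read a PSM table
#'
#' Reads the tab-delimited PSM export format (one row per peptide-spectrum
#' match). Mandatory columns are checked by name; unknown columns are kept
#' untouched. Every row is validated against the record invariants and
#' failures are reported with row numbers.
#'
#' @param path file path.
#' @param design optional [plex_design()]; when given, reporter columns are
#'   checked against the channel list.
#' @return data.frame, row order preserved.
#' @export
read_psm_table <- function(path, design = NULL) {
  psms <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = c("NA", ""))
  missing <- setdiff(.psm_mandatory_cols, names(psms))
  if (length(missing))
    stop("PSM file '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  num_cols <- c("charge", "precursor_mh", "mass_error_ppm", "score",
                "delta_rank_score", "delta_fr_score", "bcs", "spi_pct",
                "loc_top_score", "loc_second_score", "purity_pct",
                grep("^reporter_", names(psms), value = TRUE),
                intersect("tag_length", names(psms)))
  for (cc in num_cols) {
    v <- psms[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop("unparseable numeric in column '", cc, "' at row(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
      psms[[cc]] <- vn
    }
  }
  psms$charge <- as.integer(psms$charge)
  for (lc in c("is_decoy", "tmt_labeled")) {
    v <- psms[[lc]]
    if (!is.logical(v)) psms[[lc]] <- as.logical(toupper(as.character(v)))
    if (anyNA(psms[[lc]]))
      stop("unparseable logical in column '", lc, "' at row(s): ",
           paste(utils::head(which(is.na(psms[[lc]])), 10), collapse = ", "))
  }
  psms$modifications[is.na(psms$modifications)] <- ""
  psms$proteins[is.na(psms$proteins)] <- ""
  validate_psm_table(psms, design)
  psms
}

#' @rdname read_psm_table
#' @param psms PSM data.frame to serialize.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- sequence / list inputs ------------------------------------------------

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case amino-acid sequences; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1L)
  seqs
}

#' Read a one-peptide-per-line contaminant list
#'
#' Blank lines and lines starting with '#' are ignored.
#' @param path plain-text file.
#' @return character vector of upper-case peptide sequences.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) stop("peptide list file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' Map peptide modification positions onto protein coordinates
#'
#' Protein coordinates are 1-based. The leftmost occurrence of the peptide
#' in the protein is used; additional occurrences are flagged but not
#' enumerated.
#'
#' @param sequence peptide string (modified lysine may be lowercase "k").
#' @param modifications data.frame with `position` (1-based peptide
#'   coordinate) and `mod_type`.
#' @param protein_seq protein sequence string.
#' @param accession protein accession token used in the output.
#' @return data.frame with columns accession, protein_position, residue,
#'   mod_type, and a `multiple_hits` attribute-style logical column.
#' @export
map_peptide_to_sites <- function(sequence, modifications, protein_seq,
                                 accession = "protein") {
  pep <- toupper(sequence)
  hits <- gregexpr(pep, toupper(protein_seq), fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("peptide '", pep, "' does not occur in protein '", accession, "'")
  offset <- hits[1]
  pos <- offset + modifications$position - 1L
  res <- substring(toupper(protein_seq), pos, pos)
  pep_res <- substring(pep, modifications$position, modifications$position)
  stopifnot(identical(res, pep_res))
  data.frame(accession = accession,
             protein_position = as.integer(pos),
             residue = res,
             mod_type = modifications$mod_type,
             multiple_hits = length(hits) > 1L,
             stringsAsFactors = FALSE)
}
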