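# Minimal GCT 1.3 reader/writer for quant matrices with ratio-count
# metadata columns. Layout: "#1.3"; then "nrow ncol nrowmeta ncolmeta";
# then the header row (id, row-metadata names, column ids); then one line
# per column-metadata field; then the data rows.

#' Write a quant matrix as GCT 1.3
#'
#' @param m numeric matrix (features x channels); NA written as blank.
#' @param path output path.
#' @param row_meta optional data.frame of per-feature metadata (e.g.
#'   ratio counts), same row order as `m`.
#' @param col_meta optional data.frame of per-channel metadata with one
#'   row per channel.
#' @return the path, invisibly.
#' @export
write_gct <- function(m, path, row_meta = NULL, col_meta = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  nrm <- if (is.null(row_meta)) 0L else ncol(row_meta)
  ncm <- if (is.null(col_meta)) 0L else ncol(col_meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.3", paste(nr, nc, nrm, ncm, sep = "\t")), con)
  header <- c("id", if (nrm) colnames(row_meta), colnames(m))
  writeLines(paste(header, collapse = "\t"), con)
  if (ncm) for (k in seq_len(ncm)) {
    line <- c(colnames(col_meta)[k], rep("na", nrm),
              as.character(col_meta[[k]]))
    writeLines(paste(line, collapse = "\t"), con)
  }
  for (i in seq_len(nr)) {
    vals <- ifelse(is.na(m[i, ]), "", format(m[i, ], digits = 15,
                                             trim = TRUE, scientific = FALSE))
    line <- c(rownames(m)[i],
              if (nrm) as.character(unlist(row_meta[i, , drop = TRUE])),
              vals)
    writeLines(paste(line, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GCT 1.3 file written by [write_gct()]
#'
#' @param path input path.
#' @return list with `matrix`, `row_meta`, `col_meta`.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "#1.3") stop("not a GCT 1.3 file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  header <- strsplit(lines[3], "\t")[[1]]
  cm <- NULL
  if (ncm) {
    cm_lines <- lapply(lines[3 + seq_len(ncm)],
                       function(l) strsplit(l, "\t")[[1]])
    cm <- as.data.frame(lapply(seq_len(nc), function(j)
      vapply(cm_lines, `[`, "", 1 + nrm + j)),
      col.names = header[(2 + nrm):(1 + nrm + nc)])
    rownames(cm) <- vapply(cm_lines, `[`, "", 1)
    cm <- as.data.frame(t(cm))
  }
  body <- lines[(3 + ncm) + seq_len(nr)]
  parts <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  parts <- lapply(parts, function(p) c(p, rep("", 1 + nrm + nc - length(p))))
  ids <- vapply(parts, `[`, "", 1)
  rm_df <- NULL
  if (nrm) {
    rm_df <- as.data.frame(lapply(seq_len(nrm), function(k)
      utils::type.convert(vapply(parts, `[`, "", 1 + k), as.is = TRUE)),
      col.names = header[1 + seq_len(nrm)])
    rownames(rm_df) <- ids
  }
  m <- do.call(rbind, lapply(parts, function(p) {
    v <- p[(2 + nrm):(1 + nrm + nc)]
    suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }))
  dimnames(m) <- list(ids, header[(2 + nrm):(1 + nrm + nc)])
  list(matrix = m, row_meta = rm_df, col_meta = cm)
}
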