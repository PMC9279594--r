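# Readers and writers for the plain-text formats the pipeline consumes:
# wide expression TSV, passage-record TSV, newline gene lists, GMT
# annotation collections, ROI JSON, and 16-bit grayscale TIFF.

#' Read a wide FPKM expression matrix from TSV
#'
#' Expects columns `feature_id`, `feature_kind`, `culture_id`, `status` and
#' time-point columns `t0`, `t1`, ... Malformed values are reported with
#' their (1-based, header included) line number.
#'
#' @param path TSV file path.
#' @return A validated wide expression data frame.
#' @export
read_expression_tsv <- function(path) {
  mat <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vc <- value_cols(mat)
  if (length(vc)) {
    vals <- as.matrix(mat[vc])
    bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      abort_input("negative or non-numeric FPKM at line ",
                  bad[1, 1] + 1L, " (column ", vc[bad[1, 2]], ") of ", path)
    }
  }
  validate_fpkm_matrix(mat)
  mat
}

#' Write a wide FPKM expression matrix to TSV
#' @param mat A wide expression data frame.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_fpkm_matrix(mat)
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read serial-passage colony records from TSV
#'
#' Expects columns `culture_id`, `passage`, `inoculum`, `cfe`, `cell_yield`,
#' `aborted_fraction`; validated per culture.
#'
#' @param path TSV file path.
#' @return A passage-record data frame.
#' @export
read_passage_tsv <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cid in unique(rec$culture_id)) {
    validate_passage_records(rec[rec$culture_id == cid, , drop = FALSE])
  }
  rec
}

#' Write serial-passage colony records to TSV
#' @param records Passage-record data frame.
#' @param path Output path.
#' @export
write_passage_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a newline-delimited gene list
#' @param path File path.
#' @return Character vector of gene ids (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read an annotation collection in GMT format
#'
#' Parses a GMT file (term, description, members...) into a named list of
#' member vectors. Duplicate members within a term are removed with a
#' warning.
#'
#' @param path GMT file path.
#' @return Named list term id -> character vector of members.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("duplicate members removed from term(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  sets
}

#' Write an annotation collection in GMT format
#' @param annotations Named list of member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (second GMT column).
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  lines <- vapply(names(annotations), function(tid) {
    paste(c(tid, descriptions[[tid]] %||% tid,
            unique(annotations[[tid]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ROI definitions as JSON
#'
#' ROIs are stored as a JSON array of objects with `cell_id` and either
#' `rect` (`[row0, col0, row1, col1]`, half-open, 0-based, row-major) or
#' `pixels` (array of `[row, col]` pairs, 0-based).
#'
#' @param path JSON file path.
#' @return A list of ROI lists.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    if (!is.null(r$rect)) r$rect <- as.integer(unlist(r$rect))
    if (!is.null(r$pixels)) {
      px <- r$pixels
      if (is.list(px)) px <- do.call(rbind, lapply(px, unlist))
      r$pixels <- matrix(as.integer(px), ncol = 2L)
    }
    r
  })
}

#' @rdname read_roi_json
#' @param rois List of ROI lists to write.
#' @export
write_roi_json <- function(rois, path) {
  out <- lapply(rois, function(r) {
    if (!is.null(r$pixels)) {
      r$pixels <- lapply(seq_len(nrow(r$pixels)),
                         function(i) unname(r$pixels[i, ]))
    }
    r
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write 16-bit grayscale TIFF images
#'
#' Images are integer matrices in \[0, 65535\]; the TIFF layer's \[0, 1\]
#' scaling is handled internally and round-trips exactly.
#'
#' @param path TIFF file path.
#' @return Integer matrix of pixel values.
#' @export
read_tiff16 <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(img), nrow(img), ncol(img))
}

#' @rdname read_tiff16
#' @param image Integer matrix in \[0, 65535\].
#' @export
write_tiff16 <- function(image, path) {
  if (any(image < 0) || any(image > 65535)) {
    abort_input("image values must lie in the 16-bit range [0, 65535]")
  }
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
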