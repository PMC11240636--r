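#' Read a detector frame from disk
#'
#' Two dialects round-trip integer photon counts bit-exactly: a
#' whitespace-delimited integer text matrix, and single-page TIFF (written by
#' \code{\link{write_image}} as 32-bit samples). The dialect is chosen by
#' file extension (\code{.tif}/\code{.tiff} vs anything else).
#'
#' @param path File to read.
#' @param expect_shape Required matrix dimension, or \code{NULL} to skip the
#'   check.
#' @param sample_id,patient_id,batch_id,label Identity attached to the frame.
#' @return A \code{raw_image}.
#' @export
read_image <- function(path, expect_shape = c(256L, 256L),
                       sample_id = NA_character_, patient_id = NA_character_,
                       batch_id = NA_character_, label = "unknown") {
  if (!file.exists(path)) stop("no such image file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    counts <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(counts) <- "double"
  } else {
    counts <- as.matrix(utils::read.table(path, header = FALSE,
                                          colClasses = "numeric"))
    dimnames(counts) <- NULL
  }
  if (!is.null(expect_shape) && !all(dim(counts) == expect_shape))
    stop(sprintf("%s: expected a %d x %d matrix, got %d x %d", path,
                 expect_shape[1], expect_shape[2], nrow(counts), ncol(counts)))
  if (any(counts < 0))
    stop(path, ": negative photon counts are not a valid detector frame")
  if (any(counts != round(counts)))
    stop(path, ": non-integer values; raw frames are photon counts")
  new_raw_image(counts, sample_id, patient_id, batch_id, label)
}

#' Write a detector frame to disk
#'
#' @param img A \code{raw_image} (or bare count matrix).
#' @param path Destination file.
#' @param format \code{"text"} (whitespace-delimited integers) or
#'   \code{"tiff"} (32-bit single page; exact for counts below 2^24).
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path, format = c("text", "tiff")) {
  format <- match.arg(format)
  counts <- if (inherits(img, "raw_image")) img$counts else img
  stopifnot(is.matrix(counts), all(counts >= 0), all(counts == round(counts)))
  if (format == "tiff") {
    tiff::writeTIFF(counts / (2^32 - 1), path, bits.per.sample = 32)
  } else {
    utils::write.table(counts, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' CSV with header \code{sample_id,patient_id,label,batch_id,path}; extra
#' columns are preserved.
#' @param path CSV file.
#' @return \code{read_manifest}: a data.frame, one row per sample.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "label", "batch_id")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest ", path, " lacks columns: ", paste(miss, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
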