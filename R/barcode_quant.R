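# Barcode quantification: FASTQ -> barcode x sample count matrix.

#' Extract barcodes from reads
#'
#' Locates the first exact occurrence of a 6-base anchor in each read and
#' emits the following \code{barcode_length} bases. Reads without the anchor,
#' or where the barcode would run off the read end, are discarded and
#' counted. Matching is exact: no mismatch tolerance in either the anchor or
#' the barcode, mirroring an error-free amplicon design.
#'
#' @param reads A FASTQ file path, or a character vector of read sequences.
#' @param anchor 6-base anchor (A/C/G/T only).
#' @param barcode_length Barcode length following the anchor.
#' @return A list: \code{barcodes} (named integer vector, barcode -> count)
#'   and \code{discarded} (number of reads dropped).
#' @export
#' @examples
#' extract_barcodes(c("NNNGTCGACACGTACGTACGTACGTACGT"), anchor = "GTCGAC")
extract_barcodes <- function(reads, anchor, barcode_length = 20L) {
  if (nchar(anchor) != 6L || grepl("[^ACGT]", anchor)) {
    stop("anchor must be a 6-mer over A/C/G/T", call. = FALSE)
  }
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  pos <- regexpr(anchor, reads, fixed = TRUE)
  start <- as.integer(pos) + 6L
  ok <- pos > 0L & (start + barcode_length - 1L) <= nchar(reads)
  bc <- substr(reads[ok], start[ok], start[ok] + barcode_length - 1L)
  tab <- table(bc)
  list(
    barcodes = setNames(as.integer(tab), names(tab)),
    discarded = sum(!ok)
  )
}

#' Count extracted barcodes against a mapping table
#'
#' Exact-match counting: barcodes absent from the map are tallied as
#' unmapped, never counted. The matrix has one row per mapped barcode (in map
#' order) and one column per sample; samples with no mapped barcodes yield
#' zero columns and a warning.
#'
#' @param samples Named list of per-sample barcode multisets, each either a
#'   named integer vector (barcode -> count, as returned by
#'   \code{\link{extract_barcodes}$barcodes}) or a character vector of
#'   barcode observations.
#' @param map Mapping table with a \code{barcode} column (see
#'   \code{\link{simulate_library}} or \code{\link{read_barcode_map}}).
#' @return Integer matrix barcodes x samples with attribute
#'   \code{"unmapped"}: per-sample counts of reads whose barcode is not in
#'   the map.
#' @export
count_barcodes <- function(samples, map) {
  if (nrow(map) == 0L) stop("mapping table is empty", call. = FALSE)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("'samples' must be a named list", call. = FALSE)
  }
  counts <- matrix(0L, nrow = nrow(map), ncol = length(samples),
                   dimnames = list(map$barcode, names(samples)))
  unmapped <- setNames(integer(length(samples)), names(samples))
  for (j in seq_along(samples)) {
    x <- samples[[j]]
    if (is.character(x)) {
      tab <- table(x)
      x <- setNames(as.integer(tab), names(tab))
    }
    idx <- match(names(x), map$barcode)
    hit <- !is.na(idx)
    counts[idx[hit], j] <- as.integer(x[hit])
    unmapped[j] <- sum(x[!hit])
  }
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    warning("sample(s) with zero mapped reads: ",
            paste(names(samples)[empty], collapse = ", "), call. = FALSE)
  }
  attr(counts, "unmapped") <- unmapped
  counts
}

#' Usability filter for barcodes
#'
#' Retains barcodes that (i) fall inside a gene (have a locus tag), (ii) sit
#' in the central 10-90\% of the gene body when \code{central_only}, and
#' (iii) have a mean count of at least \code{min_reference_reads} across the
#' reference (soil) samples. Raising the threshold can only remove barcodes.
#'
#' @param counts Integer matrix barcodes x samples.
#' @param map Mapping table aligned with \code{rownames(counts)}.
#' @param design Design table; rows with habitat \code{"soil"} define the
#'   reference samples.
#' @param min_reference_reads Minimum mean soil count.
#' @param central_only Drop insertions outside the central gene body.
#' @return The filtered count matrix (same column set).
#' @export
filter_barcodes <- function(counts, map, design, min_reference_reads = 3,
                            central_only = TRUE) {
  .check_design(design)
  soil <- design$sample_id[design$habitat == "soil"]
  soil <- intersect(soil, colnames(counts))
  if (length(soil) == 0L) {
    stop("no reference (soil) samples found among count columns", call. = FALSE)
  }
  m <- map[match(rownames(counts), map$barcode), ]
  keep <- !is.na(m$locus_tag) & m$locus_tag != ""
  if (central_only) keep <- keep & m$central
  soil_mean <- rowMeans(counts[, soil, drop = FALSE])
  keep <- keep & soil_mean >= min_reference_reads
  counts[keep, , drop = FALSE]
}

#' Read and write TnBarSeq tables
#'
#' Plain-text interchange: tab-separated mapping tables
#' (barcode, scaffold, position, strand, locus_tag, central) and count
#' matrices (barcode column followed by one column per sample).
#'
#' @param map,counts Objects to write.
#' @param path File path.
#' @return The object read, or (for writers) the path invisibly.
#' @name barseq_io
NULL

#' @rdname barseq_io
#' @export
write_barcode_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname barseq_io
#' @export
read_barcode_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  map$locus_tag[map$locus_tag == ""] <- NA_character_
  map
}

#' @rdname barseq_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname barseq_io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  m
}
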