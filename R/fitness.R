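# Fitness scores: strain-level log2 ratios against the soil reference, then
# inverse-variance weighted gene-level aggregation with median centering.

#' Reference abundance profile from soil samples
#'
#' The soil (substrate) samples play the role of the T0 control: the library
#' colonizes plants from the surrounding soil, so soil abundances define the
#' starting proportions. The reference is the per-barcode mean of
#' depth-normalized soil counts.
#'
#' @param counts Integer matrix barcodes x samples.
#' @param design Design table with a \code{habitat} column.
#' @return Named numeric vector of reference proportions (one per barcode).
#' @export
reference_profile <- function(counts, design) {
  .check_design(design)
  soil <- intersect(design$sample_id[design$habitat == "soil"],
                    colnames(counts))
  if (length(soil) == 0L) stop("no soil samples in counts", call. = FALSE)
  sc <- counts[, soil, drop = FALSE]
  depth <- colSums(sc)
  if (all(depth == 0)) stop("all reference samples are empty", call. = FALSE)
  props <- sweep(sc, 2, pmax(depth, 1), "/")
  rowMeans(props)
}

#' Per-strain fitness scores
#'
#' \deqn{f(b, s) = \log_2 \frac{n(b,s) + \epsilon}{d(s)\,r(b) + \epsilon}}
#' where \eqn{n(b,s)} is the count of barcode b in sample s, \eqn{d(s)} the
#' sample depth (column sum), \eqn{r(b)} the reference proportion, and
#' \eqn{\epsilon} a pseudocount keeping zero counts finite.
#'
#' @param counts Integer matrix barcodes x samples (typically after
#'   \code{\link{filter_barcodes}}).
#' @param reference Reference proportions from \code{\link{reference_profile}}
#'   (matched to rownames of \code{counts}).
#' @param pseudocount Positive pseudocount (default 1).
#' @return Numeric matrix barcodes x samples of log2 fitness values, with
#'   attribute \code{"pseudocount"}.
#' @export
strain_fitness <- function(counts, reference, pseudocount = 1) {
  .check_positive(pseudocount, "pseudocount")
  reference <- reference[rownames(counts)]
  if (anyNA(reference)) {
    stop("reference is missing entries for some barcodes", call. = FALSE)
  }
  depth <- colSums(counts)
  expected <- outer(reference, depth)
  f <- log2((counts + pseudocount) / (expected + pseudocount))
  attr(f, "pseudocount") <- pseudocount
  f
}

#' Per-gene fitness scores
#'
#' The gene fitness in a sample is the inverse-variance weighted mean of its
#' member strains' fitness, with Poisson-motivated weights
#' \deqn{w(b, s) = \left( \frac{1}{1 + n(b,s)} + \frac{1}{1 + d(s) r(b)} \right)^{-1}}
#' so strains observed at higher counts (in the sample and in the reference)
#' carry more weight. Columns are then centered so that the per-sample median
#' gene fitness is exactly 0, removing sample-wide abundance shifts under the
#' assumption that the typical gene is neutral.
#'
#' @param strain Strain fitness matrix from \code{\link{strain_fitness}}.
#' @param map Mapping table (barcode -> locus_tag).
#' @param counts The count matrix the strain fitness was computed from.
#' @param design Design table (soil samples define the reference).
#' @param center Median-center each sample column (default TRUE).
#' @return Numeric matrix genes x samples with attributes
#'   \code{"n_barcodes"} (named integer vector) and \code{"centering"}.
#' @export
gene_fitness <- function(strain, map, counts, design, center = TRUE) {
  genes <- map$locus_tag[match(rownames(strain), map$barcode)]
  if (anyNA(genes)) {
    stop("every retained barcode must carry a locus_tag", call. = FALSE)
  }
  reference <- reference_profile(counts, design)[rownames(strain)]
  depth <- colSums(counts)
  n <- counts[rownames(strain), colnames(strain), drop = FALSE]
  expected <- outer(reference, depth[colnames(strain)])
  w <- 1 / (1 / (1 + n) + 1 / (1 + expected))
  num <- rowsum(w * strain, group = genes)
  den <- rowsum(w, group = genes)
  g <- num / den
  if (center) {
    g <- sweep(g, 2, apply(g, 2, median))
  }
  nb <- table(genes)
  attr(g, "n_barcodes") <- setNames(as.integer(nb), names(nb))
  attr(g, "centering") <- if (center) "median" else "none"
  g
}

#' @rdname barseq_io
#' @param fitness Gene fitness matrix.
#' @export
write_gene_fitness <- function(fitness, path) {
  hdr <- sprintf("# centering=%s", attr(fitness, "centering"))
  writeLines(hdr, path)
  df <- data.frame(gene = rownames(fitness), fitness, check.names = FALSE)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE)
  )
  invisible(path)
}
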