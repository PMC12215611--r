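# One-call analysis pipeline from a count matrix to classified results.

#' Analyze a TnBarSeq screen from counts to classified effects
#'
#' Chains the standard pipeline: barcode usability filter
#' (\code{\link{filter_barcodes}}), soil reference profile, strain and gene
#' fitness (\code{\link{strain_fitness}}, \code{\link{gene_fitness}}), and
#' mixed-model differential-fitness testing with normality gate and
#' classification (\code{\link{test_differential_fitness}}), finishing with
#' per-gene specificity profiles (\code{\link{build_profiles}}).
#'
#' @param counts Integer matrix barcodes x samples.
#' @param map Barcode mapping table.
#' @param design Design table.
#' @param min_reference_reads,central_only Passed to
#'   \code{\link{filter_barcodes}}.
#' @param pseudocount Passed to \code{\link{strain_fitness}}.
#' @param contrasts,normality_alpha,q_threshold,lfc_threshold Passed to
#'   \code{\link{test_differential_fitness}}.
#' @return A list: \code{fitness} (gene x sample matrix), \code{results}
#'   (long classified table), \code{profiles} (per-gene specificity).
#' @export
#' @examples
#' \donttest{
#' p <- sim_params(n_genes = 40, read_depth = 20000, seed = 7)
#' lib <- simulate_library(p)
#' design <- make_design(n_per_habitat = 3, n_soil = 3)
#' counts <- simulate_counts(lib, design, params = p)
#' out <- analyze_screen(counts, lib$map, design)
#' head(out$results)
#' }
analyze_screen <- function(counts, map, design,
                           min_reference_reads = 3, central_only = TRUE,
                           pseudocount = 1,
                           contrasts = NULL, normality_alpha = 0.05,
                           q_threshold = 0.05, lfc_threshold = 1) {
  kept <- filter_barcodes(counts, map, design,
                          min_reference_reads = min_reference_reads,
                          central_only = central_only)
  reference <- reference_profile(kept, design)
  strain <- strain_fitness(kept, reference, pseudocount = pseudocount)
  fitness <- gene_fitness(strain, map, kept, design)
  results <- test_differential_fitness(fitness, design,
                                       contrasts = contrasts,
                                       normality_alpha = normality_alpha,
                                       q_threshold = q_threshold,
                                       lfc_threshold = lfc_threshold)
  list(fitness = fitness, results = results,
       profiles = build_profiles(results))
}
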