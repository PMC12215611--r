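# Operating-characteristic benchmarks: recovery of planted effects and
# false-call control under the global null, run on the package's own
# generative model. Used to calibrate and regression-test the pipeline.

#' Effect-recovery benchmark for the screen pipeline
#'
#' Simulates replicate screens in which a subset of genes carries a known
#' log2 fitness effect in one habitat, runs the full analysis
#' (\code{\link{analyze_screen}}), and aggregates sensitivity (fraction of
#' true-effect genes called, counting gate-omitted genes as misses),
#' empirical false discovery rate among called genes, and the fraction of
#' true positives whose specificity profile is the planted single-habitat
#' class. Plant samples are drawn without a founder bottleneck so that
#' recovery reflects the test, not incomplete sampling.
#'
#' Replicate seeds are \code{seed + 0:(n_reps - 1)}.
#'
#' @param seed Base seed.
#' @param n_reps Number of replicate screens to aggregate.
#' @param n_genes Genes in each simulated genome.
#' @param barcodes_per_gene Insertions per gene (fixed count).
#' @param n_true Number of genes carrying the planted effect.
#' @param effect Planted log2 effect.
#' @param habitat Habitat carrying the effect.
#' @param read_depth Reads per sample.
#' @param design Design table (default \code{\link{make_design}()}).
#' @return A list: \code{sensitivity}, \code{fdr},
#'   \code{single_habitat_fraction}, \code{n_true_total}, \code{n_called},
#'   and \code{per_rep} (data.frame of per-replicate values).
#' @export
screen_power_benchmark <- function(seed = 1L, n_reps = 4L, n_genes = 500L,
                                   barcodes_per_gene = 5,
                                   n_true = 30L, effect = -2,
                                   habitat = "At_shoot",
                                   read_depth = 250000L,
                                   design = make_design()) {
  per_rep <- vector("list", n_reps)
  tp_total <- 0L; called_total <- 0L; fp_total <- 0L; single_total <- 0L
  for (k in seq_len(n_reps)) {
    s <- as.integer(seed) + k - 1L
    p <- sim_params(n_genes = n_genes,
                    insertions_per_gene_mean = barcodes_per_gene,
                    insertion_model = "fixed",
                    read_depth = read_depth, seed = s)
    lib <- simulate_library(p)
    genes <- unique(lib$map$locus_tag)
    effects <- make_effects(genes)
    true_genes <- genes[seq_len(n_true)]
    effects[true_genes, habitat] <- effect
    counts <- simulate_counts(lib, design, effects, p)
    out <- analyze_screen(counts, lib$map, design)
    r <- out$results[out$results$contrast == habitat, ]
    wanted <- if (effect < 0) "association" else "negative_association"
    called <- r$gene[r$category == wanted]
    tp <- intersect(called, true_genes)
    single <- out$profiles$gene[
      out$profiles$class == paste0("single_habitat:", habitat)
    ]
    per_rep[[k]] <- data.frame(
      seed = s,
      sensitivity = length(tp) / n_true,
      fdr = if (length(called)) 1 - length(tp) / length(called) else 0,
      single_habitat_fraction = if (length(tp)) {
        mean(tp %in% single)
      } else NA_real_
    )
    tp_total <- tp_total + length(tp)
    called_total <- called_total + length(called)
    fp_total <- fp_total + length(setdiff(called, true_genes))
    single_total <- single_total + sum(tp %in% single)
  }
  list(
    sensitivity = tp_total / (n_true * n_reps),
    fdr = if (called_total) fp_total / called_total else 0,
    single_habitat_fraction = if (tp_total) single_total / tp_total else NA_real_,
    n_true_total = n_true * n_reps,
    n_called = called_total,
    per_rep = do.call(rbind, per_rep)
  )
}

#' Null-calibration benchmark for the screen pipeline
#'
#' Simulates a screen in which every gene is neutral in every habitat and
#' reports, per contrast, the fraction of gate-retained genes called
#' non-indifferent. Under the null this should not exceed the nominal FDR
#' level plus sampling error.
#'
#' @inheritParams screen_power_benchmark
#' @return data.frame per contrast: \code{contrast}, \code{n_retained},
#'   \code{n_called}, \code{call_rate}.
#' @export
screen_null_benchmark <- function(seed = 1L, n_genes = 500L,
                                  barcodes_per_gene = 5,
                                  read_depth = 250000L,
                                  design = make_design()) {
  p <- sim_params(n_genes = n_genes,
                  insertions_per_gene_mean = barcodes_per_gene,
                  insertion_model = "fixed",
                  read_depth = read_depth, seed = as.integer(seed))
  lib <- simulate_library(p)
  counts <- simulate_counts(lib, design, effects = NULL, p)
  out <- analyze_screen(counts, lib$map, design)
  r <- out$results
  do.call(rbind, lapply(split(r, r$contrast), function(d) {
    ret <- d[d$retained, ]
    data.frame(
      contrast = d$contrast[1],
      n_retained = nrow(ret),
      n_called = sum(ret$category != "indifferent"),
      call_rate = mean(ret$category != "indifferent"),
      stringsAsFactors = FALSE
    )
  }))
}
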