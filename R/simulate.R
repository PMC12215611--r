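# Synthetic-data generators. These emulate the statistical structure of a
# TnBarSeq colonization screen: a lognormal inoculum, per-habitat
# multiplicative fitness effects, a per-plant founder bottleneck, and
# multinomial sequencing depth.

#' Simulation parameters for a synthetic TnBarSeq library
#'
#' Bundles the knobs of the generative model. Defaults reflect a desk-scale
#' screen: ~8.5 insertions per gene (the density observed in saturated
#' mariner libraries of plant-associated bacteria), a lognormal inoculum with
#' log2 standard deviation 1, and no founder bottleneck unless one is
#' requested (set \code{bottleneck_founders} to model the limited number of
#' plant colonization events that makes each plant sample an incomplete draw
#' from the library).
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param insertions_per_gene_mean Mean number of barcoded insertions per
#'   gene (Poisson mean, or the exact count when
#'   \code{insertion_model = "fixed"}).
#' @param read_depth Sequencing reads per sample.
#' @param inoculum_logsd Standard deviation, in log2 units, of barcode
#'   abundances in the inoculum.
#' @param bottleneck_founders Number of barcodes founding each plant sample,
#'   or \code{NA} for no bottleneck.
#' @param insertion_model \code{"poisson"} (default) or \code{"fixed"}.
#' @param seed Integer seed; every generator draws from a generator seeded
#'   with this value, so a fixed seed reproduces outputs bit for bit.
#' @return A list of class \code{"sim_params"}.
#' @export
#' @examples
#' p <- sim_params(n_genes = 50, seed = 1)
sim_params <- function(n_genes = 500L,
                       insertions_per_gene_mean = 8.5,
                       read_depth = 250000L,
                       inoculum_logsd = 1,
                       bottleneck_founders = NA,
                       insertion_model = c("poisson", "fixed"),
                       seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  read_depth <- .check_count(read_depth, "read_depth")
  .check_positive(insertions_per_gene_mean, "insertions_per_gene_mean")
  .check_positive(inoculum_logsd, "inoculum_logsd")
  if (!is.na(bottleneck_founders)) {
    bottleneck_founders <- .check_count(bottleneck_founders, "bottleneck_founders")
  }
  structure(
    list(
      n_genes = n_genes,
      insertions_per_gene_mean = insertions_per_gene_mean,
      read_depth = read_depth,
      inoculum_logsd = inoculum_logsd,
      bottleneck_founders = bottleneck_founders,
      insertion_model = match.arg(insertion_model),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Experiment design table for a synthetic screen
#'
#' Builds a balanced design over the five habitats with the covariates the
#' differential-fitness model uses: an auxiliary-community indicator, a
#' harvest day (1 or 2), and a flat grouping id (the random-effect level).
#' Auxiliary community and harvest day alternate within habitat; flats are
#' assigned round-robin.
#'
#' @param n_per_habitat Samples per plant habitat.
#' @param n_soil Soil (reference) samples; must be at least 2.
#' @param n_flats Number of flats.
#' @return A data.frame with columns \code{sample_id}, \code{habitat},
#'   \code{auxiliary_community}, \code{harvest_day}, \code{flat}.
#' @export
#' @examples
#' head(make_design(n_per_habitat = 3, n_soil = 2))
make_design <- function(n_per_habitat = 6L, n_soil = 6L, n_flats = 4L) {
  n_per_habitat <- .check_count(n_per_habitat, "n_per_habitat")
  n_soil <- .check_count(n_soil, "n_soil", min = 2L)
  n_flats <- .check_count(n_flats, "n_flats")
  habs <- c(rep("soil", n_soil),
            rep(plant_habitats(), each = n_per_habitat))
  n <- length(habs)
  design <- data.frame(
    sample_id = sprintf("S%03d_%s", seq_len(n), habs),
    habitat = habs,
    auxiliary_community = rep_len(c(FALSE, TRUE), n),
    harvest_day = unlist(lapply(rle(habs)$lengths, function(k) {
      c(rep(1L, ceiling(k / 2)), rep(2L, floor(k / 2)))
    })),
    flat = rep_len(seq_len(n_flats), n),
    stringsAsFactors = FALSE
  )
  .check_design(design)
}

#' Zero-initialized true-effect matrix
#'
#' Ground truth for recovery tests: one log2 fitness effect per gene per
#' habitat, 0 meaning neutral.
#'
#' @param gene_ids Character vector of gene ids.
#' @return A numeric matrix genes x habitats filled with 0.
#' @export
make_effects <- function(gene_ids) {
  matrix(0, nrow = length(gene_ids), ncol = length(habitat_levels()),
         dimnames = list(gene_ids, habitat_levels()))
}

.random_barcodes <- function(n, width = 20L) {
  bc <- character(0)
  while (length(bc) < n) {
    need <- n - length(bc)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1))
    bc <- unique(c(bc, new))
  }
  bc[seq_len(n)]
}

#' Simulate a barcoded insertion library
#'
#' Generates a barcode-to-genome mapping table and a lognormal inoculum
#' abundance vector. Each gene receives a Poisson number of unique 20-mer
#' barcodes (or a fixed count, see \code{\link{sim_params}}); insertion
#' positions are uniform within the central 10-90\% of the gene body, so
#' every simulated insertion is "central" in the sense used by
#' \code{\link{filter_barcodes}}.
#'
#' Genes are laid out in tandem on one scaffold, 1000 bp long with 200 bp
#' intergenic gaps; coordinates are 1-based.
#'
#' @param params A \code{\link{sim_params}} object.
#' @return A list of class \code{"barseq_library"} with elements \code{map}
#'   (data.frame: barcode, scaffold, position, strand, locus_tag, central)
#'   and \code{inoculum} (named abundance vector, one entry per barcode).
#' @export
#' @examples
#' lib <- simulate_library(sim_params(n_genes = 20, seed = 1))
#' head(lib$map)
simulate_library <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gene_len <- 1000L
  gap <- 200L
  gene_ids <- sprintf("gene_%04d", seq_len(params$n_genes))
  n_ins <- switch(params$insertion_model,
    poisson = rpois(params$n_genes, params$insertions_per_gene_mean),
    fixed = rep(as.integer(round(params$insertions_per_gene_mean)), params$n_genes)
  )
  total <- sum(n_ins)
  if (total == 0L) {
    stop("simulated library contains zero barcodes; increase ",
         "insertions_per_gene_mean or n_genes", call. = FALSE)
  }
  gene_idx <- rep(seq_len(params$n_genes), n_ins)
  start <- (gene_idx - 1L) * (gene_len + gap) + 1L
  lo <- start + ceiling(0.1 * gene_len)
  hi <- start + floor(0.9 * gene_len) - 1L
  pos <- lo + floor(runif(total) * (hi - lo + 1L))
  map <- data.frame(
    barcode = .random_barcodes(total),
    scaffold = "scaffold_1",
    position = as.integer(pos),
    strand = sample(c("+", "-"), total, replace = TRUE),
    locus_tag = gene_ids[gene_idx],
    central = TRUE,
    stringsAsFactors = FALSE
  )
  inoculum <- 2^rnorm(total, mean = 0, sd = params$inoculum_logsd)
  names(inoculum) <- map$barcode
  structure(list(map = map, inoculum = inoculum), class = "barseq_library")
}

#' Simulate a barcode count matrix under the screen's generative model
#'
#' Soil samples draw \code{read_depth} reads from a multinomial over all
#' barcodes with probabilities proportional to inoculum abundance times
#' \code{2^soil_effect}. Plant samples first subsample
#' \code{bottleneck_founders} barcodes without replacement, weighted by
#' inoculum (the founder bottleneck: each plant is colonized by a limited
#' number of cells, so each plant sample starts from an incomplete draw of
#' the library), then apply the habitat effect multiplicatively
#' (deterministic exponential growth) and draw reads multinomially.
#'
#' @param lib A \code{\link{simulate_library}} result.
#' @param design A design table (see \code{\link{make_design}}).
#' @param effects Optional genes x habitats matrix of log2 effects (see
#'   \code{\link{make_effects}}); missing genes/habitats are neutral.
#' @param params A \code{\link{sim_params}} object; \code{read_depth} and
#'   \code{bottleneck_founders} are taken from it. The count draw is seeded
#'   with \code{params$seed + 1} so it is reproducible yet independent of the
#'   library draw.
#' @return Integer matrix barcodes x samples, rows ordered as \code{lib$map}.
#' @export
simulate_counts <- function(lib, design, effects = NULL, params) {
  stopifnot(inherits(lib, "barseq_library"), inherits(params, "sim_params"))
  .check_design(design)
  map <- lib$map
  n_bc <- nrow(map)
  founders <- params$bottleneck_founders
  if (!is.na(founders) && founders > n_bc) {
    stop("bottleneck_founders (", founders, ") exceeds the number of ",
         "barcodes in the library (", n_bc, ")", call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- make_effects(unique(map$locus_tag))
  }
  if (!all(rownames(effects) %in% map$locus_tag)) {
    stop("effects contains genes absent from the library map", call. = FALSE)
  }
  # per-barcode log2 effect in each habitat (0 where unspecified)
  eff_bc <- matrix(0, nrow = n_bc, ncol = length(habitat_levels()),
                   dimnames = list(map$barcode, habitat_levels()))
  hit <- map$locus_tag %in% rownames(effects)
  eff_bc[hit, ] <- effects[map$locus_tag[hit], , drop = FALSE]

  set.seed(params$seed + 1L)
  counts <- matrix(0L, nrow = n_bc, ncol = nrow(design),
                   dimnames = list(map$barcode, design$sample_id))
  for (i in seq_len(nrow(design))) {
    hab <- design$habitat[i]
    w <- lib$inoculum
    if (hab != "soil" && !is.na(founders)) {
      keep <- sample.int(n_bc, founders, replace = FALSE, prob = lib$inoculum)
      mask <- rep(0, n_bc)
      mask[keep] <- 1
      w <- w * mask
    }
    w <- w * 2^eff_bc[, hab]
    counts[, i] <- rmultinom(1, params$read_depth, prob = w)[, 1]
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write synthetic barcode reads as FASTQ
#'
#' Emits one FASTQ file per sample. Each counted barcode produces that many
#' reads of the form random-prefix + anchor + barcode + random-suffix,
#' padded to \code{read_length}. Prefix lengths are drawn uniformly from
#' \code{0:max_offset} so barcode extraction must locate the anchor rather
#' than assume a fixed position.
#'
#' @param counts Integer matrix barcodes x samples.
#' @param anchor 6-base anchor sequence preceding the barcode.
#' @param dir Output directory (created if needed).
#' @param read_length Total read length.
#' @param max_offset Maximum random prefix length.
#' @param seed Integer seed for prefix/suffix bases.
#' @return Invisibly, the vector of files written (named by sample).
#' @export
write_barcode_fastq <- function(counts, anchor, dir, read_length = 50L,
                                max_offset = 5L, seed = 1L) {
  stopifnot(is.matrix(counts), nchar(anchor) == 6L)
  bclen <- nchar(rownames(counts)[1])
  if (read_length < max_offset + 6L + bclen) {
    stop("read_length too short for anchor + barcode at max_offset", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(ncol(counts))
  names(files) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    n <- counts[, j]
    reads <- rep(rownames(counts), n)
    m <- length(reads)
    path <- file.path(dir, paste0(colnames(counts)[j], ".fastq"))
    if (m == 0L) {
      file.create(path)
      files[j] <- path
      next
    }
    off <- sample.int(max_offset + 1L, m, replace = TRUE) - 1L
    seqs <- vapply(seq_len(m), function(k) {
      pre <- paste(sample(c("A", "C", "G", "T"), off[k], replace = TRUE),
                   collapse = "")
      core <- paste0(pre, anchor, reads[k])
      pad <- read_length - nchar(core)
      suf <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                   collapse = "")
      paste0(core, suf)
    }, character(1))
    qual <- strrep("I", read_length)
    out <- character(4L * m)
    out[seq(1, by = 4, length.out = m)] <- sprintf("@read_%d", seq_len(m))
    out[seq(2, by = 4, length.out = m)] <- seqs
    out[seq(3, by = 4, length.out = m)] <- "+"
    out[seq(4, by = 4, length.out = m)] <- qual
    writeLines(out, path)
    files[j] <- path
  }
  invisible(files)
}

#' Simulate a recombinant inbred line (RIL) population
#'
#' Biallelic (Col/Ler) genotypes over five chromosomes. Each line starts each
#' chromosome from a random parental allele and accumulates a Poisson number
#' of crossovers at uniform positions; residual heterozygosity is ignored.
#' The phenotype of each line is computed from its alleles at the three
#' causal loci (ESP-, MAM- and AOP-like) through the glucosinolate rule
#' engine (\code{\link{gsl_product}}): Col at the ESP locus means no
#' functional epithiospecifier (isothiocyanates form), Col at the MAM locus
#' means MAM1 (4-carbon chain), and Col at the AOP locus means inactive AOP3
#' (methylsulfinyl side chain retained).
#'
#' @param n_lines Number of lines.
#' @param markers_per_chrom Markers per chromosome (ids
#'   \code{chr<k>_m<i>}).
#' @param recomb_per_chrom Expected crossovers per chromosome per line.
#' @param causal_loci Named character vector with entries \code{esp},
#'   \code{mam}, \code{aop}: marker ids on three distinct chromosomes.
#' @param seed Integer seed.
#' @return A list of class \code{"ril_population"}: \code{genotypes} (lines x
#'   markers character matrix, values "Col"/"Ler"), \code{marker_map}
#'   (marker, chrom, index), \code{phenotype} (named vector: "non_toxic",
#'   "d90_toxic" or "WT_toxic"), \code{causal_loci}.
#' @export
#' @examples
#' pop <- simulate_ril_population(n_lines = 20, seed = 1)
#' table(pop$phenotype)
simulate_ril_population <- function(n_lines = 98L,
                                    markers_per_chrom = 20L,
                                    recomb_per_chrom = 1.5,
                                    causal_loci = c(esp = "chr1_m10",
                                                    mam = "chr5_m10",
                                                    aop = "chr4_m10"),
                                    seed = 1L) {
  n_lines <- .check_count(n_lines, "n_lines")
  markers_per_chrom <- .check_count(markers_per_chrom, "markers_per_chrom")
  if (recomb_per_chrom < 0) stop("recomb_per_chrom must be >= 0", call. = FALSE)
  if (!all(c("esp", "mam", "aop") %in% names(causal_loci))) {
    stop("causal_loci must name 'esp', 'mam' and 'aop' markers", call. = FALSE)
  }
  marker_map <- data.frame(
    marker = as.vector(t(outer(1:5, seq_len(markers_per_chrom),
                               function(c, i) sprintf("chr%d_m%02d", c, i)))),
    chrom = rep(1:5, each = markers_per_chrom),
    index = rep(seq_len(markers_per_chrom), 5),
    stringsAsFactors = FALSE
  )
  if (!all(causal_loci %in% marker_map$marker)) {
    stop("causal locus not in marker map: ",
         paste(setdiff(causal_loci, marker_map$marker), collapse = ", "),
         call. = FALSE)
  }
  causal_chrom <- marker_map$chrom[match(causal_loci, marker_map$marker)]
  if (anyDuplicated(causal_chrom)) {
    stop("the three causal loci must lie on distinct chromosomes", call. = FALSE)
  }
  set.seed(seed)
  geno <- matrix(NA_character_, n_lines, nrow(marker_map),
                 dimnames = list(sprintf("RIL_%03d", seq_len(n_lines)),
                                 marker_map$marker))
  for (l in seq_len(n_lines)) {
    for (ch in 1:5) {
      cols <- which(marker_map$chrom == ch)
      m <- length(cols)
      allele <- sample(c(0L, 1L), 1L)           # 0 = Col, 1 = Ler
      k <- rpois(1, recomb_per_chrom)
      xover <- sort(runif(k, min = 0, max = m)) # positions on (0, m)
      states <- allele + vapply(seq_len(m) - 0.5, function(x) sum(xover < x),
                                numeric(1))
      geno[l, cols] <- c("Col", "Ler")[(states %% 2L) + 1L]
    }
  }
  phen <- apply(geno[, causal_loci[c("esp", "mam", "aop")], drop = FALSE], 1,
                function(a) ril_phenotype(a[1], a[2], a[3]))
  structure(
    list(genotypes = geno, marker_map = marker_map,
         phenotype = phen, causal_loci = causal_loci),
    class = "ril_population"
  )
}

#' Simulate a protein family with a designed monophyletic clade
#'
#' Background sequences mutate a common seed peptide independently at rate
#' \code{background_divergence}. The clade descends from a shared clade
#' ancestor (itself a background-level mutant of the seed) through two
#' subfamilies, each founded by one anchor sequence (mutated from the
#' ancestor at rate \code{clade_divergence / 2}); the remaining members
#' mutate one of the two anchors at a quarter of that rate, so each
#' subfamily clusters tightly around its anchor. Clade members are thus
#' mutually closer than to any background sequence, and the two anchors
#' straddle the clade's basal split -- as the functionally tested genes from
#' two different genera do in a real clade-calling analysis -- so their most
#' recent common ancestor is the clade root. Each sequence is assigned its
#' own genome and a taxonomic class cycling over the three Pseudomonadota
#' classes.
#'
#' @param n_background Background family members.
#' @param clade_size Members of the designed clade (>= 1).
#' @param clade_divergence,background_divergence Per-site substitution
#'   probabilities in (0, 1); the clade must be tighter than the background.
#' @param seq_length Peptide length.
#' @param seed Integer seed.
#' @return A list of class \code{"protein_family"}: \code{sequences} (named
#'   character vector), \code{metadata} (data.frame: seq_id, genome_id,
#'   class, is_anchor, true_clade).
#' @export
simulate_protein_family <- function(n_background = 30L, clade_size = 6L,
                                    clade_divergence = 0.1,
                                    background_divergence = 0.4,
                                    seq_length = 160L, seed = 1L) {
  if (n_background < 0) stop("n_background must be >= 0", call. = FALSE)
  clade_size <- .check_count(clade_size, "clade_size")
  for (d in c(clade_divergence, background_divergence)) {
    if (d <= 0 || d >= 1) {
      stop("divergences must lie in (0, 1)", call. = FALSE)
    }
  }
  if (clade_divergence >= background_divergence) {
    stop("clade_divergence must be smaller than background_divergence",
         call. = FALSE)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  seed_pep <- sample(aa, seq_length, replace = TRUE)
  mutate <- function(x, rate) {
    hit <- runif(length(x)) < rate
    x[hit] <- sample(aa, sum(hit), replace = TRUE)
    x
  }
  n <- n_background + clade_size
  seqs <- character(n)
  clade_anc <- mutate(seed_pep, background_divergence)
  anchor1 <- mutate(clade_anc, clade_divergence / 2)
  anchor2 <- mutate(clade_anc, clade_divergence / 2)
  seqs[1] <- paste(anchor1, collapse = "")
  if (clade_size >= 2L) seqs[2] <- paste(anchor2, collapse = "")
  if (clade_size >= 3L) {
    for (i in 3:clade_size) {
      parent <- if (i %% 2L == 1L) anchor1 else anchor2
      seqs[i] <- paste(mutate(parent, clade_divergence / 8), collapse = "")
    }
  }
  if (n_background > 0) {
    for (i in seq_len(n_background)) {
      seqs[clade_size + i] <- paste(mutate(seed_pep, background_divergence),
                                    collapse = "")
    }
  }
  ids <- c(sprintf("clade_%02d", seq_len(clade_size)),
           if (n_background > 0) sprintf("bg_%03d", seq_len(n_background)))
  names(seqs) <- ids
  meta <- data.frame(
    seq_id = ids,
    genome_id = sprintf("genome_%03d", seq_len(n)),
    class = rep_len(c("Alphaproteobacteria", "Betaproteobacteria",
                      "Gammaproteobacteria"), n),
    is_anchor = FALSE,
    true_clade = c(rep(TRUE, clade_size), rep(FALSE, n_background)),
    stringsAsFactors = FALSE
  )
  meta$is_anchor[seq_len(min(2L, clade_size))] <- TRUE
  structure(list(sequences = seqs, metadata = meta), class = "protein_family")
}

#' Simulate dose-response growth data under a decreasing Hill model
#'
#' OD(c) = top / (1 + (c / ic50)^hill) plus Gaussian noise, floored at 0.
#'
#' @param top OD at zero dose.
#' @param ic50 Concentration inhibiting half of growth (> 0).
#' @param hill Hill coefficient (> 0).
#' @param doses Concentration vector; defaults to a 12-point 1.5-fold serial
#'   dilution spanning the IC50 (as a serial-dilution toxicity assay would).
#' @param noise_sd Gaussian noise standard deviation (OD units).
#' @param replicates Replicates per dose.
#' @param seed Integer seed.
#' @return data.frame with columns \code{dose}, \code{replicate}, \code{od}.
#' @export
simulate_dose_response <- function(top = 1, ic50 = 10, hill = 2,
                                   doses = NULL, noise_sd = 0.02,
                                   replicates = 4L, seed = 1L) {
  .check_positive(ic50, "ic50")
  .check_positive(hill, "hill")
  replicates <- .check_count(replicates, "replicates")
  if (is.null(doses)) {
    doses <- ic50 * 1.5^seq(-5, 6)
  }
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- top / (1 + (d / ic50)^hill)
  od <- pmax(0, mu + rnorm(length(d), sd = noise_sd))
  data.frame(dose = d, replicate = rep(seq_len(replicates), length(doses)),
             od = od)
}
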