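test_that("library simulation is deterministic and respects its parameters", {
  p <- sim_params(n_genes = 2000, insertions_per_gene_mean = 8.5, seed = 5)
  lib1 <- simulate_library(p)
  lib2 <- simulate_library(p)
  expect_identical(lib1$map, lib2$map)
  expect_identical(lib1$inoculum, lib2$inoculum)

  # insertion density matches the Poisson mean (SE ~ sqrt(8.5/2000) = 0.065)
  per_gene <- table(factor(lib1$map$locus_tag,
                           levels = sprintf("gene_%04d", 1:2000)))
  expect_equal(mean(per_gene), 8.5, tolerance = 0.03)

  # barcodes are unique 20-mers
  expect_false(anyDuplicated(lib1$map$barcode) > 0)
  expect_true(all(nchar(lib1$map$barcode) == 20))

  # insertion positions stay inside the central 10-90% of the gene body
  one <- simulate_library(sim_params(n_genes = 1,
                                     insertions_per_gene_mean = 1000,
                                     seed = 2))
  expect_true(all(one$map$position >= 1 + 100))
  expect_true(all(one$map$position <= 900))
  expect_true(all(one$map$central))

  expect_error(
    simulate_library(sim_params(n_genes = 1,
                                insertions_per_gene_mean = 1e-9, seed = 1)),
    "zero barcodes"
  )
})

test_that("neutral counts carry no habitat signal beyond sampling error", {
  fx <- tiny_library(n_genes = 40, seed = 3, read_depth = 100000)
  design <- tiny_design()
  expected <- fx$lib$inoculum / sum(fx$lib$inoculum)
  rejections <- 0L
  for (s in 1:5) {
    p <- fx$params; p$seed <- s
    counts <- simulate_counts(fx$lib, design, params = p)
    for (col in c(1, 5)) { # one soil, one plant sample
      gof <- suppressWarnings(
        stats::chisq.test(counts[, col], p = expected)
      )
      if (gof$p.value < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 1L)
})

test_that("a planted effect shifts expected proportions by 2^effect", {
  fx <- tiny_library(n_genes = 20, seed = 4, read_depth = 50000)
  lib <- fx$lib
  genes <- unique(lib$map$locus_tag)
  effects <- make_effects(genes)
  g <- genes[1]
  effects[g, "At_shoot"] <- -2
  bc_g <- lib$map$barcode[lib$map$locus_tag == g]
  w <- lib$inoculum
  w_eff <- w
  w_eff[bc_g] <- w_eff[bc_g] * 2^-2
  # closed-form multinomial means
  p_soil <- sum(w[bc_g]) / sum(w)
  p_shoot <- sum(w_eff[bc_g]) / sum(w_eff)
  design <- tiny_design()
  shoot_cols <- design$sample_id[design$habitat == "At_shoot"]
  set.seed(42)
  obs <- replicate(50, {
    p <- fx$params; p$seed <- sample.int(1e6, 1)
    counts <- simulate_counts(lib, design, effects, p)
    sum(counts[bc_g, shoot_cols]) / sum(counts[, shoot_cols])
  })
  expect_equal(mean(obs), p_shoot, tolerance = 0.03)
  # and the shift itself is close to 2^-2 relative to the soil proportion
  expect_equal(p_shoot / p_soil, 2^-2, tolerance = 0.1)
})

test_that("the founder bottleneck reduces barcode diversity in plant samples", {
  fx <- tiny_library(n_genes = 100, seed = 6, read_depth = 50000,
                     bottleneck_founders = 50)
  design <- tiny_design()
  counts <- simulate_counts(fx$lib, design, params = fx$params)
  soil_cols <- design$habitat == "soil"
  n_soil <- colSums(counts[, soil_cols, drop = FALSE] > 0)
  n_plant <- colSums(counts[, !soil_cols, drop = FALSE] > 0)
  expect_true(all(n_plant < min(n_soil)))
  expect_true(all(n_plant <= 50))

  p_bad <- fx$params
  p_bad$bottleneck_founders <- nrow(fx$lib$map) + 1L
  expect_error(simulate_counts(fx$lib, design, params = p_bad),
               "exceeds the number of barcodes")
})

test_that("RIL simulation is deterministic, Mendelian and rule-consistent", {
  pop1 <- simulate_ril_population(n_lines = 30, seed = 9)
  pop2 <- simulate_ril_population(n_lines = 30, seed = 9)
  expect_identical(pop1$genotypes, pop2$genotypes)
  expect_identical(pop1$phenotype, pop2$phenotype)

  # no recombination: chromosomes are parental; Ler fraction ~ 0.5
  pop0 <- simulate_ril_population(n_lines = 200, recomb_per_chrom = 0,
                                  seed = 2)
  for (ch in 1:5) {
    cols <- pop0$marker_map$marker[pop0$marker_map$chrom == ch]
    per_chrom <- apply(pop0$genotypes[, cols], 1,
                       function(a) length(unique(a)))
    expect_true(all(per_chrom == 1))
  }
  frac <- mean(pop0$genotypes == "Ler")
  se <- sqrt(0.25 / (200 * 5))
  expect_lt(abs(frac - 0.5), 3 * se)

  # a line that is Col at all three causal loci is d90-toxic (Col-0-like)
  expect_identical(ril_phenotype("Col", "Col", "Col"), "d90_toxic")
  # phenotype in the population agrees with the rule engine
  alle <- pop1$genotypes[, pop1$causal_loci[c("esp", "mam", "aop")]]
  recomputed <- apply(alle, 1, function(a) ril_phenotype(a[1], a[2], a[3]))
  expect_identical(unname(pop1$phenotype), unname(recomputed))

  expect_error(simulate_ril_population(causal_loci = c(esp = "chr1_m01",
                                                       mam = "chr1_m10",
                                                       aop = "chr4_m10")),
               "distinct chromosomes")
  expect_error(simulate_ril_population(causal_loci = c(esp = "chr1_m99",
                                                       mam = "chr5_m10",
                                                       aop = "chr4_m10")),
               "not in marker map")
})

test_that("protein-family generator builds the designed clade structure", {
  fam <- simulate_protein_family(seed = 1)
  expect_identical(fam, simulate_protein_family(seed = 1))
  expect_equal(sum(fam$metadata$is_anchor), 2L)
  expect_true(all(fam$metadata$true_clade[fam$metadata$is_anchor]))

  # clade_size = 2, near-zero divergence: the two are mutual nearest neighbors
  fam2 <- simulate_protein_family(n_background = 10, clade_size = 2,
                                  clade_divergence = 0.01, seed = 2)
  D <- pairwise_distance(fam2$sequences)
  diag(D) <- Inf
  nn <- rownames(D)[apply(D, 1, which.min)]
  expect_identical(nn[1:2], c("clade_02", "clade_01"))

  # no background: every sequence is in the clade
  fam0 <- simulate_protein_family(n_background = 0, clade_size = 4, seed = 3)
  expect_true(all(fam0$metadata$true_clade))

  expect_error(simulate_protein_family(clade_divergence = 0), "in \\(0, 1\\)")
  expect_error(simulate_protein_family(clade_divergence = 0.5,
                                       background_divergence = 0.4),
               "smaller than")
})

test_that("dose-response generator obeys the Hill model limits", {
  d0 <- simulate_dose_response(top = 2, ic50 = 5, hill = 3,
                               doses = c(0, 5, 50), noise_sd = 1e-12,
                               replicates = 1, seed = 1)
  expect_equal(d0$od[d0$dose == 0], 2, tolerance = 1e-6)
  expect_equal(d0$od[d0$dose == 5], 1, tolerance = 1e-6)
  d_steep <- simulate_dose_response(top = 2, ic50 = 5, hill = 50,
                                    doses = 10, noise_sd = 1e-12,
                                    replicates = 1, seed = 1)
  expect_lt(d_steep$od, 1e-6)
  expect_error(simulate_dose_response(doses = c(-1, 2)), "non-negative")
})
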