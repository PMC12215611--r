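test_that("the glucosinolate rule engine maps genotypes to known products", {
  # parental chemotypes
  col <- gsl_product(gsl_genotype("non_functional", "MAM1", "inactive"))
  ler <- gsl_product(gsl_genotype("functional", "MAM2", "active"))
  expect_identical(col$name, "4MSO-ITC")
  expect_identical(col$toxicity, "d90_toxic")
  expect_identical(ler$name, "3OHP-Nitrile")
  expect_identical(ler$toxicity, "non_toxic")
  # recombinant combinations and cyclization products
  oxazinane <- gsl_product(gsl_genotype("non_functional", "MAM2", "active"))
  expect_identical(oxazinane$name, "1,3-Oxazinane-2-thione")
  expect_identical(oxazinane$toxicity, "WT_toxic")
  oxazepane <- gsl_product(gsl_genotype("non_functional", "MAM1", "active"))
  expect_identical(oxazepane$name, "1,3-Oxazepane-2-thione")
  expect_identical(oxazepane$toxicity, "d90_toxic")
  iberin <- gsl_product(gsl_genotype("non_functional", "MAM2", "inactive"))
  expect_identical(iberin$name, "3MSO-ITC")
  expect_identical(iberin$toxicity, "d90_toxic")
})

test_that("the product space enumerates to 8 products in 3 toxicity classes", {
  tab <- enumerate_gsl_products()
  expect_identical(nrow(tab), 8L)
  expect_identical(length(unique(tab$name)), 8L)
  expect_identical(sum(tab$toxicity == "d90_toxic"), 3L)
  expect_identical(sum(tab$toxicity == "non_toxic"), 4L)
  expect_identical(sum(tab$toxicity == "WT_toxic"), 1L)
  # functional ESP always yields a non-toxic nitrile
  expect_true(all(tab$toxicity[tab$esp == "functional"] == "non_toxic"))
  expect_true(all(tab$moiety[tab$esp == "functional"] == "nitrile"))
  # cyclized name present iff hydroxyl isothiocyanate
  expect_identical(!is.na(tab$cyclized_name),
                   tab$moiety == "isothiocyanate" &
                     tab$side_chain == "hydroxyl")
})

test_that("allele fractions and binomial p-values match direct computation", {
  pop <- simulate_ril_population(n_lines = 10, markers_per_chrom = 4,
                                 causal_loci = c(esp = "chr1_m02",
                                                 mam = "chr5_m02",
                                                 aop = "chr4_m02"),
                                 seed = 3)
  # overwrite one marker with a known configuration: 3 Ler of 10
  pop$genotypes[, "chr2_m01"] <- c(rep("Ler", 3), rep("Col", 7))
  pop$phenotype[] <- "non_toxic"  # one group holding all lines
  scan <- allele_fraction_scan(pop, "non_toxic")
  row <- scan[scan$marker == "chr2_m01", ]
  expect_equal(row$ler_fraction, 0.3)
  # exact two-sided binomial p by direct mass summation
  dens <- dbinom(0:10, 10, 0.5)
  oracle <- sum(dens[dens <= dbinom(3, 10, 0.5) * (1 + 1e-7)])
  expect_equal(row$p_value, oracle, tolerance = 1e-10)
  # all-Ler marker
  pop$genotypes[, "chr2_m02"] <- "Ler"
  scan <- allele_fraction_scan(pop, "non_toxic")
  expect_equal(scan$ler_fraction[scan$marker == "chr2_m02"], 1.0)
  # missing calls are excluded; all-missing markers are flagged NA
  pop$genotypes[1:2, "chr3_m01"] <- NA
  pop$genotypes[, "chr3_m02"] <- NA
  scan <- allele_fraction_scan(pop, "non_toxic")
  expect_identical(scan$n[scan$marker == "chr3_m01"], 8L)
  expect_true(is.na(scan$ler_fraction[scan$marker == "chr3_m02"]))
  expect_error(allele_fraction_scan(pop, "WT_toxic"), "empty")
})

test_that("peak intervals are maximal deviant runs per chromosome", {
  scan <- data.frame(
    marker = sprintf("chr1_m%02d", 1:10),
    chrom = 1L, index = 1:10, n = 20L,
    ler_fraction = c(0.5, 0.5, 0.05, 0.05, 0.05, 0.05, 0.05, 0.5, 0.5, 0.9),
    p_value = NA_real_
  )
  iv <- peak_intervals(scan, deviation_threshold = 0.25, min_run = 2)
  expect_identical(nrow(iv), 1L)
  expect_identical(iv$start_marker, "chr1_m03")
  expect_identical(iv$end_marker, "chr1_m07")
  expect_identical(iv$n_markers, 5L)
  expect_identical(iv$direction, "Col")
  # a single deviant marker does not qualify at min_run = 2
  flat <- scan; flat$ler_fraction <- 0.5; flat$ler_fraction[10] <- 0.9
  expect_identical(nrow(peak_intervals(flat)), 0L)
})

test_that("a neutral population shows no genome-wide allele skew", {
  pop <- simulate_ril_population(n_lines = 200, seed = 14)
  groups <- unique(pop$phenotype)
  for (grp in groups) {
    scan <- allele_fraction_scan(pop, grp)
    n_lines <- sum(pop$phenotype == grp)
    if (n_lines < 20) next
    # genome-wide mean fraction: SE over ~n_lines x 5 chromosome draws
    se <- sqrt(0.25 / (n_lines * 5))
    overall <- mean(scan$ler_fraction, na.rm = TRUE)
    # causal-locus conditioning skews the causal chromosomes, so check a
    # chromosome with no causal locus (chr2 and chr3 are neutral)
    neutral <- mean(scan$ler_fraction[scan$chrom %in% c(2, 3)])
    expect_lt(abs(neutral - 0.5), 4 * sqrt(0.25 / (n_lines * 2)))
  }
})

test_that("the scan localizes the causal ESP locus in the d90-toxic group", {
  set.seed(31)
  hits <- replicate(30, {
    pop <- simulate_ril_population(n_lines = 98,
                                   seed = sample.int(1e6, 1))
    if (sum(pop$phenotype == "d90_toxic") < 5) return(NA)
    scan <- allele_fraction_scan(pop, "d90_toxic")
    esp <- pop$causal_loci[["esp"]]
    scan$ler_fraction[scan$marker == esp] == min(scan$ler_fraction,
                                                 na.rm = TRUE)
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
  # the d90-toxic group is fixed Col at the ESP locus by the rule engine
  pop <- simulate_ril_population(n_lines = 98, seed = 77)
  scan <- allele_fraction_scan(pop, "d90_toxic")
  expect_equal(scan$ler_fraction[scan$marker == pop$causal_loci[["esp"]]], 0)
})
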