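# Host genetics: the combinatorial glucosinolate breakdown rule engine and
# the RIL allele-fraction linkage scan.

#' Glucosinolate genotype at the three segregating loci
#'
#' The three loci that differentiate the Col-0 and Ler-1 aliphatic
#' glucosinolate pathways: ESP (epithiospecifier protein; functional ESP
#' diverts breakdown to nitriles, otherwise isothiocyanates form
#' spontaneously), MAM (chain elongation; MAM1 yields 4-carbon chains, MAM2
#' 3-carbon), and AOP3 (side-chain modification; active AOP3 converts the
#' methylsulfinyl side chain to a hydroxyl).
#'
#' @param esp \code{"functional"} or \code{"non_functional"}.
#' @param mam \code{"MAM1"} or \code{"MAM2"}.
#' @param aop3 \code{"active"} or \code{"inactive"}.
#' @return A list of class \code{"gsl_genotype"}.
#' @export
#' @examples
#' # Col-0 and Ler-1 parental genotypes
#' gsl_genotype("non_functional", "MAM1", "inactive")
#' gsl_genotype("functional", "MAM2", "active")
gsl_genotype <- function(esp = c("functional", "non_functional"),
                         mam = c("MAM1", "MAM2"),
                         aop3 = c("active", "inactive")) {
  structure(list(esp = match.arg(esp), mam = match.arg(mam),
                 aop3 = match.arg(aop3)),
            class = "gsl_genotype")
}

#' Dominant glucosinolate breakdown product of a genotype
#'
#' Deterministic product rules: MAM1 gives a 4-carbon precursor chain, MAM2 a
#' 3-carbon one; active AOP3 converts the methylsulfinyl (MSO) side chain to
#' a hydroxyl; functional ESP yields the nitrile moiety, otherwise the
#' isothiocyanate (ITC) forms. Hydroxyl isothiocyanates cyclize
#' spontaneously and are reported as their cyclization products: the
#' 3-carbon 3OHP-ITC as 1,3-Oxazinane-2-thione and the 4-carbon 4OHB-ITC as
#' 1,3-Oxazepane-2-thione.
#'
#' Toxicity classes (against an efflux-pump deletion mutant, "d90"): all
#' nitriles are non-toxic; 4MSO-ITC (sulforaphane), 3MSO-ITC (iberin) and
#' 1,3-Oxazepane-2-thione inhibit only the mutant (\code{d90_toxic});
#' 1,3-Oxazinane-2-thione inhibits mutant and wild type alike
#' (\code{WT_toxic}).
#'
#' @param g A \code{\link{gsl_genotype}}.
#' @return A one-row data.frame: \code{name}, \code{precursor_chain}
#'   ("3C"/"4C"), \code{side_chain} ("MSO"/"hydroxyl"), \code{moiety}
#'   ("isothiocyanate"/"nitrile"), \code{cyclized_name} (NA unless a hydroxyl
#'   isothiocyanate), \code{toxicity}.
#' @export
#' @examples
#' gsl_product(gsl_genotype("non_functional", "MAM1", "inactive")) # 4MSO-ITC
gsl_product <- function(g) {
  stopifnot(inherits(g, "gsl_genotype"))
  chain <- if (g$mam == "MAM1") "4C" else "3C"
  side <- if (g$aop3 == "active") "hydroxyl" else "MSO"
  moiety <- if (g$esp == "functional") "nitrile" else "isothiocyanate"
  stem <- if (side == "MSO") {
    paste0(substr(chain, 1, 1), "MSO")
  } else {
    if (chain == "3C") "3OHP" else "4OHB"
  }
  base <- paste0(stem, "-", if (moiety == "nitrile") "Nitrile" else "ITC")
  cyclized <- NA_character_
  name <- base
  if (moiety == "isothiocyanate" && side == "hydroxyl") {
    cyclized <- if (chain == "3C") "1,3-Oxazinane-2-thione"
                else "1,3-Oxazepane-2-thione"
    name <- cyclized
  }
  toxicity <- if (moiety == "nitrile") {
    "non_toxic"
  } else if (name %in% c("4MSO-ITC", "3MSO-ITC", "1,3-Oxazepane-2-thione")) {
    "d90_toxic"
  } else {
    "WT_toxic"
  }
  data.frame(name = name, precursor_chain = chain, side_chain = side,
             moiety = moiety, cyclized_name = cyclized, toxicity = toxicity,
             stringsAsFactors = FALSE)
}

#' Enumerate breakdown products over all 2x2x2 genotypes
#'
#' @return data.frame of 8 rows: the genotype fields plus the
#'   \code{\link{gsl_product}} columns. The 8 products are distinct; 4 are
#'   non-toxic, 3 are d90-toxic and 1 is WT-toxic.
#' @export
enumerate_gsl_products <- function() {
  grid <- expand.grid(esp = c("functional", "non_functional"),
                      mam = c("MAM1", "MAM2"),
                      aop3 = c("active", "inactive"),
                      stringsAsFactors = FALSE)
  prods <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    gsl_product(gsl_genotype(grid$esp[i], grid$mam[i], grid$aop3[i]))
  }))
  cbind(grid, prods)
}

#' Phenotype of a RIL line from its causal-locus alleles
#'
#' Maps Col/Ler alleles at the ESP-, MAM- and AOP-like loci to a glucosinolate
#' genotype (Col: non-functional ESP, MAM1, inactive AOP3; Ler: functional
#' ESP, MAM2, active AOP3) and returns the toxicity class of the resulting
#' breakdown product.
#'
#' @param esp_allele,mam_allele,aop_allele \code{"Col"} or \code{"Ler"}.
#' @return \code{"non_toxic"}, \code{"d90_toxic"} or \code{"WT_toxic"}.
#' @export
#' @examples
#' ril_phenotype("Col", "Col", "Col") # d90_toxic (Col-0-like)
ril_phenotype <- function(esp_allele, mam_allele, aop_allele) {
  ok <- c("Col", "Ler")
  stopifnot(esp_allele %in% ok, mam_allele %in% ok, aop_allele %in% ok)
  g <- gsl_genotype(
    esp = if (esp_allele == "Col") "non_functional" else "functional",
    mam = if (mam_allele == "Col") "MAM1" else "MAM2",
    aop3 = if (aop_allele == "Col") "inactive" else "active"
  )
  gsl_product(g)$toxicity
}

#' Allele-fraction linkage scan over a RIL population
#'
#' For the lines of one phenotype group, computes at every marker the
#' fraction of non-missing lines carrying the Ler allele, with an exact
#' two-sided binomial test against the neutral expectation of 0.5. Markers
#' are ordered by concatenated chromosome position. Markers where all group
#' lines are missing get \code{NA} fraction and are flagged.
#'
#' @param pop A \code{\link{simulate_ril_population}} result, or a list with
#'   \code{genotypes}, \code{marker_map} and \code{phenotype} of that shape.
#' @param group Phenotype group to scan (\code{"non_toxic"},
#'   \code{"d90_toxic"} or \code{"WT_toxic"}).
#' @return data.frame per marker: \code{marker}, \code{chrom}, \code{index},
#'   \code{n} (non-missing group lines), \code{ler_fraction}, \code{p_value}.
#' @export
allele_fraction_scan <- function(pop, group) {
  lines <- names(pop$phenotype)[pop$phenotype == group]
  if (length(lines) == 0L) {
    stop("phenotype group '", group, "' is empty", call. = FALSE)
  }
  geno <- pop$genotypes[lines, , drop = FALSE]
  mm <- pop$marker_map
  stats <- lapply(mm$marker, function(mk) {
    a <- geno[, mk]
    a <- a[!is.na(a)]
    n <- length(a)
    if (n == 0L) {
      return(c(n = 0, frac = NA_real_, p = NA_real_))
    }
    x <- sum(a == "Ler")
    c(n = n, frac = x / n, p = binom.test(x, n, p = 0.5)$p.value)
  })
  stats <- do.call(rbind, stats)
  out <- data.frame(marker = mm$marker, chrom = mm$chrom, index = mm$index,
                    n = as.integer(stats[, "n"]),
                    ler_fraction = stats[, "frac"],
                    p_value = stats[, "p"],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$index), ]
}

#' Call linkage peak intervals from an allele-fraction scan
#'
#' Maximal runs of at least \code{min_run} consecutive markers (within a
#' chromosome) whose Ler fraction deviates from 0.5 by at least
#' \code{deviation_threshold}.
#'
#' @param scan Output of \code{\link{allele_fraction_scan}}.
#' @param deviation_threshold Minimum |fraction - 0.5|.
#' @param min_run Minimum run length in markers.
#' @return data.frame: \code{chrom}, \code{start_marker}, \code{end_marker},
#'   \code{n_markers}, \code{direction} ("Col" when Ler fraction is low,
#'   "Ler" when high).
#' @export
peak_intervals <- function(scan, deviation_threshold = 0.25, min_run = 2L) {
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    s <- s[order(s$index), ]
    dev <- !is.na(s$ler_fraction) &
      abs(s$ler_fraction - 0.5) >= deviation_threshold
    r <- rle(dev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_marker = s$marker[starts[k]],
        end_marker = s$marker[ends[k]],
        n_markers = length(idx),
        direction = if (mean(s$ler_fraction[idx]) < 0.5) "Col" else "Ler",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = integer(0), start_marker = character(0),
                      end_marker = character(0), n_markers = integer(0),
                      direction = character(0)))
  }
  do.call(rbind, out)
}
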