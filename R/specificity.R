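# Cross-habitat specificity: per-gene association profiles, upset
# intersection counts, and COG-category enrichment.

.classify_subset <- function(habs) {
  habs <- sort(habs)
  hosts <- unique(sub("_.*", "", habs))
  organs <- unique(sub(".*_", "", habs))
  n <- length(habs)
  if (n == 0L) return("none")
  if (n == 4L) return("general")
  if (n == 1L) return(paste0("single_habitat:", habs))
  if (n == 2L && length(hosts) == 1L) {
    return(paste0("host_specific:", hosts))
  }
  if (n == 2L && length(organs) == 1L && length(hosts) == 2L) {
    return(paste0("organ_specific:", organs))
  }
  "mixed"
}

#' Build per-gene specificity profiles
#'
#' From the classified differential-fitness results over the four
#' habitat-vs-soil contrasts, collects for each gene the habitats where it is
#' an association gene and where it is a negative-association gene, and
#' assigns a specificity class to each direction: \code{general} (all four
#' habitats), \code{host_specific:<host>} (both organs of one host),
#' \code{organ_specific:<organ>} (same organ in both hosts),
#' \code{single_habitat:<habitat>}, \code{mixed} (any other multi-habitat
#' pattern) or \code{none}.
#'
#' @param results Classified results from
#'   \code{\link{test_differential_fitness}}.
#' @return data.frame with one row per gene: \code{gene},
#'   \code{association_habitats}, \code{negative_habitats} (both "+"-joined
#'   strings in fixed habitat order), \code{class} (of the association set)
#'   and \code{class_negative}.
#' @export
build_profiles <- function(results) {
  genes <- unique(results$gene)
  ord <- plant_habitats()
  one <- function(g) {
    r <- results[results$gene == g, ]
    assoc <- intersect(ord, r$contrast[r$category == "association"])
    neg <- intersect(ord, r$contrast[r$category == "negative_association"])
    data.frame(
      gene = g,
      association_habitats = paste(assoc, collapse = "+"),
      negative_habitats = paste(neg, collapse = "+"),
      class = .classify_subset(assoc),
      class_negative = .classify_subset(neg),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(genes, one))
}

#' Upset intersection counts
#'
#' Tallies, separately for the association and negative-association
#' directions, how many genes show each exact habitat intersection pattern.
#' Each gene contributes to exactly one pattern per direction; pattern counts
#' therefore sum to the number of genes with a non-empty set in that
#' direction.
#'
#' @param profiles Output of \code{\link{build_profiles}}.
#' @return data.frame with columns \code{direction} ("association" or
#'   "negative"), \code{pattern} ("+"-joined habitats) and \code{count},
#'   sorted by decreasing count within direction.
#' @export
upset_counts <- function(profiles) {
  tally <- function(col, direction) {
    pat <- profiles[[col]]
    pat <- pat[pat != ""]
    if (length(pat) == 0L) {
      return(data.frame(direction = character(0), pattern = character(0),
                        count = integer(0)))
    }
    tab <- sort(table(pat), decreasing = TRUE)
    data.frame(direction = direction, pattern = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
  rbind(tally("association_habitats", "association"),
        tally("negative_habitats", "negative"))
}

#' COG-category enrichment of a gene set
#'
#' Per functional category, a two-sided Fisher exact test on the 2x2 table
#' (in set vs not) x (in category vs not) against the annotated background,
#' with Benjamini-Hochberg adjustment across categories.
#'
#' @param gene_set Character vector of genes of interest.
#' @param annotation Named character vector gene -> category covering the
#'   background.
#' @param background Character vector of all annotated genes (must be a
#'   superset of \code{gene_set}).
#' @return data.frame per category: counts and fractions in set and
#'   background, odds ratio, Fisher p, BH q.
#' @export
cog_enrichment <- function(gene_set, annotation, background = names(annotation)) {
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of the background", call. = FALSE)
  }
  categories <- sort(unique(annotation[background]))
  if (length(gene_set) == 0L) {
    return(data.frame(category = character(0), n_set = integer(0),
                      n_background = integer(0), fraction_set = numeric(0),
                      fraction_background = numeric(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  in_set <- background %in% gene_set
  rows <- lapply(categories, function(cat) {
    in_cat <- annotation[background] == cat
    a <- sum(in_set & in_cat)
    b <- sum(in_set & !in_cat)
    c <- sum(!in_set & in_cat)
    d <- sum(!in_set & !in_cat)
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(category = cat, n_set = a, n_background = a + c,
               fraction_set = a / (a + b),
               fraction_background = (a + c) / length(background),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}
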