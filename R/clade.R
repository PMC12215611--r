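# Protein-family clade calling: family selection by functional tag,
# alignment-score dissimilarity, neighbor joining, midpoint rooting, MRCA
# clade extraction, and prevalence/copy-number summaries.

#' Select a protein family by functional tag
#'
#' Returns all and only the proteins carrying the given functional annotation
#' tag (e.g. the COG identifier of the RND efflux-pump inner-membrane
#' subunit, COG0841), with their genome and class metadata.
#'
#' @param annotations data.frame with at least \code{seq_id} and \code{tag}
#'   columns (extra metadata columns are carried through).
#' @param tag Functional tag to select (exact match).
#' @return The matching rows of \code{annotations}.
#' @export
select_family <- function(annotations, tag = "COG0841") {
  if (!all(c("seq_id", "tag") %in% names(annotations))) {
    stop("annotations must have 'seq_id' and 'tag' columns", call. = FALSE)
  }
  out <- annotations[annotations$tag == tag, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no proteins carry tag '", tag, "'", call. = FALSE)
  }
  out
}

#' Pairwise alignment-score dissimilarity matrix
#'
#' Globally aligns every pair of protein sequences (affine gaps; gap cost =
#' \code{gap_open} + \code{gap_extend} x length) under a substitution matrix
#' and converts scores to dissimilarities
#' \deqn{d_{ij} = 1 - S_{ij} / \min(S_{ii}, S_{jj})}
#' where \eqn{S_{ii}} is the self-alignment score (sum of diagonal
#' substitution scores). Identical sequences get distance 0; very dissimilar
#' pairs can exceed 1 (negative cross scores), which is documented behaviour,
#' not clipped.
#'
#' @param proteins Named character vector or \code{Biostrings::AAStringSet}
#'   of protein sequences.
#' @param substitution Substitution matrix name (from Biostrings) or a
#'   numeric matrix; default \code{"BLOSUM50"}.
#' @param gap_open,gap_extend Affine gap penalties (costs, positive).
#' @return Symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
pairwise_distance <- function(proteins, substitution = "BLOSUM50",
                              gap_open = 10, gap_extend = 1) {
  if (is.character(proteins) && is.null(dim(proteins))) {
    if (any(nchar(proteins) == 0L)) {
      stop("empty sequence in input", call. = FALSE)
    }
    proteins <- Biostrings::AAStringSet(proteins)
  }
  n <- length(proteins)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  ids <- names(proteins)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  if (is.character(substitution)) {
    submat <- get(data(list = substitution, package = "Biostrings",
                       envir = environment()))
  } else {
    submat <- substitution
  }
  chars <- strsplit(as.character(proteins), "")
  self <- vapply(chars, function(x) sum(submat[cbind(x, x)]), numeric(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in 2:n) {
    s <- Biostrings::pairwiseAlignment(
      pattern = proteins[seq_len(j - 1L)], subject = proteins[[j]],
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    d <- 1 - s / pmin(self[seq_len(j - 1L)], self[j])
    D[seq_len(j - 1L), j] <- d
    D[j, seq_len(j - 1L)] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration minimizing the Q criterion.
#' For determinism, ties in Q are broken by the lexicographically smallest
#' pair of cluster ids (a cluster's id is its smallest leaf label). Negative
#' branch lengths are truncated to 0. Exactly additive input distances are
#' reproduced by tree path lengths.
#'
#' @param D Symmetric distance matrix with dimnames (n >= 3) and zero
#'   diagonal.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (anyNA(D) || any(!is.finite(D))) {
    stop("D contains missing or non-finite values", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("D must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active cluster: newick fragment + representative id (smallest leaf)
  nwk <- labels
  rep_id <- labels
  active <- seq_len(n)
  Dw <- D
  bl <- function(x) max(x, 0)
  fmt <- function(x) sprintf("%.12g", x)
  while (length(active) > 3L) {
    m <- length(active)
    sub <- Dw[active, active, drop = FALSE]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pair <- sort(c(rep_id[active[ij[1]]], rep_id[active[ij[2]]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- Dw[i, j]
    ri <- r[pick[1]]; rj <- r[pick[2]]
    li <- 0.5 * dij + (ri - rj) / (2 * (m - 2))
    lj <- dij - li
    li <- bl(li); lj <- bl(lj)
    if (rep_id[j] < rep_id[i]) { # canonical child order for a stable newick
      tmp <- i; i <- j; j <- tmp
      tmp <- li; li <- lj; lj <- tmp
      dij <- Dw[i, j]
    }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    # distances from the new node u to every other active cluster
    others <- setdiff(active, c(i, j))
    du <- 0.5 * (Dw[i, others] + Dw[j, others] - dij)
    Dw[i, others] <- du
    Dw[others, i] <- du
    Dw[i, i] <- 0
    nwk[i] <- new_nwk
    rep_id[i] <- min(rep_id[i], rep_id[j])
    active <- setdiff(active, j)
  }
  # resolve the final three clusters around a central node
  active <- active[order(rep_id[active])]
  a <- active[1]; b <- active[2]; c <- active[3]
  la <- bl((Dw[a, b] + Dw[a, c] - Dw[b, c]) / 2)
  lb <- bl((Dw[a, b] + Dw[b, c] - Dw[a, c]) / 2)
  lc <- bl((Dw[a, c] + Dw[b, c] - Dw[a, b]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nwk[a], fmt(la), nwk[b], fmt(lb), nwk[c], fmt(lc))
  ape::read.tree(text = newick)
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest leaf-to-leaf path. Leaf
#' path lengths are preserved. A tree whose branch lengths are all zero is
#' rooted arbitrarily with a warning.
#'
#' @param tree An \code{ape::phylo} tree with branch lengths.
#' @return A rooted \code{ape::phylo} tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (sum(tree$edge.length) == 0) {
    warning("all branch lengths are zero; rooting at an arbitrary node",
            call. = FALSE)
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  if (length(tree$tip.label) == 2L) {
    h <- sum(tree$edge.length) / 2
    return(ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                         tree$tip.label[1], h,
                                         tree$tip.label[2], h)))
  }
  phangorn::midpoint(tree)
}

#' Extract the MRCA clade of anchor leaves
#'
#' On a rooted tree, returns every leaf descending from the most recent
#' common ancestor of the anchor leaves. With a single anchor the clade is
#' that leaf alone. Adding anchors can only grow the clade.
#'
#' @param tree A rooted \code{ape::phylo} tree.
#' @param anchors Leaf ids (must all be present in the tree).
#' @return Character vector of clade member leaf ids.
#' @export
mrca_clade <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"))
  missing_ids <- setdiff(anchors, tree$tip.label)
  if (length(missing_ids)) {
    stop("anchor(s) not in tree: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(anchors)) == 1L) {
    return(anchors[1])
  }
  node <- ape::getMRCA(tree, unique(anchors))
  ape::extract.clade(tree, node)$tip.label
}

#' Prevalence and copy number of a clade across genomes
#'
#' @param members Clade member seq ids.
#' @param metadata data.frame with \code{seq_id}, \code{genome_id},
#'   \code{class} covering all genomes considered (genomes without members
#'   count toward the prevalence denominator).
#' @return A list: \code{prevalence} (data.frame class, n_genomes,
#'   n_with_member, prevalence) and \code{copy_number} (data.frame genome_id,
#'   class, copies). Classes with no genomes are omitted.
#' @export
prevalence_summary <- function(members, metadata) {
  if (!all(members %in% metadata$seq_id)) {
    stop("some members are missing from the metadata", call. = FALSE)
  }
  genomes <- unique(metadata[, c("genome_id", "class")])
  mem_genomes <- metadata$genome_id[metadata$seq_id %in% members]
  copies <- table(factor(mem_genomes, levels = genomes$genome_id))
  copy_number <- data.frame(
    genome_id = genomes$genome_id,
    class = genomes$class,
    copies = as.integer(copies[genomes$genome_id]),
    stringsAsFactors = FALSE
  )
  prevalence <- do.call(rbind, lapply(split(copy_number, copy_number$class),
    function(d) {
      data.frame(class = d$class[1], n_genomes = nrow(d),
                 n_with_member = sum(d$copies >= 1L),
                 prevalence = mean(d$copies >= 1L),
                 stringsAsFactors = FALSE)
    }))
  rownames(prevalence) <- NULL
  list(prevalence = prevalence, copy_number = copy_number)
}

#' Full clade-calling pipeline
#'
#' Distance matrix, neighbor joining, midpoint rooting and MRCA clade
#' extraction in one call, with a prevalence summary.
#'
#' @param proteins Named protein sequences (character or AAStringSet).
#' @param metadata Sequence metadata (seq_id, genome_id, class, is_anchor).
#' @param anchors Anchor seq ids; defaults to \code{metadata$seq_id[
#'   metadata$is_anchor]}.
#' @param ... Passed to \code{\link{pairwise_distance}}.
#' @return A list with \code{distance}, \code{tree} (rooted), \code{members},
#'   \code{prevalence} and \code{copy_number}.
#' @export
clade_pipeline <- function(proteins, metadata, anchors = NULL, ...) {
  if (is.null(anchors)) {
    anchors <- metadata$seq_id[metadata$is_anchor]
  }
  if (length(anchors) == 0L) stop("no anchors given", call. = FALSE)
  D <- pairwise_distance(proteins, ...)
  tree <- midpoint_root(neighbor_joining(D))
  members <- mrca_clade(tree, anchors)
  summ <- prevalence_summary(members, metadata)
  list(distance = D, tree = tree, members = members,
       prevalence = summ$prevalence, copy_number = summ$copy_number)
}
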