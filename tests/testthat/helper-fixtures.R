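# Small in-code fixtures shared across tests.

tiny_library <- function(n_genes = 20, seed = 1, read_depth = 50000,
                         insertions = 5, model = "fixed", ...) {
  p <- sim_params(n_genes = n_genes, insertions_per_gene_mean = insertions,
                  insertion_model = model, read_depth = read_depth,
                  seed = seed, ...)
  list(params = p, lib = simulate_library(p))
}

tiny_design <- function(n_per_habitat = 3, n_soil = 3, n_flats = 2) {
  make_design(n_per_habitat = n_per_habitat, n_soil = n_soil,
              n_flats = n_flats)
}

# Independent affine-gap global alignment (Gotoh three-state DP).
# Gap of length L costs open + ext * L, matching the package's convention.
oracle_global_score <- function(a, b, submat, open = 10, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum50 <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}
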