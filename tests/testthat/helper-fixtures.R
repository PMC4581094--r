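# Shared fixtures, all generated in code.

toy3_genome <- function() {
  build_toy_genome(n_chrom = 3,
                   arm_lengths = list(A = c(120000, 180000),
                                      B = c(200000, 100000),
                                      C = c(150000, 250000)),
                   rdna_chrom = NULL)
}

# random DNA string of length n (fixed RNG state handled by caller)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force oracle: fragment boundaries by direct substring scanning
scan_digest_oracle <- function(seq, site = "GATC") {
  n <- nchar(seq)
  cuts <- c()
  for (i in seq_len(n - nchar(site) + 1)) {
    if (substr(seq, i, i + nchar(site) - 1) == site) cuts <- c(cuts, i - 1)
  }
  bounds <- sort(unique(c(0, cuts, n)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# uniform-fragment genome + bead-resolution bins for pipeline tests
toy_pipeline_fixture <- function(seed = 42L) {
  g <- toy3_genome()
  fm <- tile_frag_map(g, 1000)
  bins <- bin_fragments(fm, 20)
  s <- simulate_structure(g, nucleus_config(mode = "uniform", seed = seed))
  list(genome = g, frag_map = fm, bins = bins, structure = s)
}

# Floyd-Warshall all-pairs shortest paths (independent oracle)
floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  D[W == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}
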