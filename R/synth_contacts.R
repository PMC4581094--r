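# Contact maps and read pairs sampled from a planted 3D structure. The
# generative model is the inverse of the reconstruction assumption: expected
# contact frequency between beads i and j is proportional to c0 / d(i,j)
# (optionally a power law c0 / d^alpha), so that shortest-path inversion of
# a dense noiseless map recovers the planted distances exactly.

#' Sample a raw contact map from a bead-chain structure
#'
#' Draws `n_contacts` unordered bead pairs with probability proportional to
#' `c0 / d(i,j)^alpha` (self-pairs excluded) and returns the symmetric count
#' matrix over the given bins. Requires one bead per bin, in bin order.
#'
#' @param structure A `Structure3D`.
#' @param bins A `BinTable` with exactly one bin per bead (see
#'   [bead_bin_table()]).
#' @param n_contacts Number of sampled contacts.
#' @param c0 Scale constant of the contact-frequency model (cancels in the
#'   sampling probabilities; kept for explicitness).
#' @param alpha Distance exponent; the default 1 matches the inverse
#'   relation assumed by the reconstruction.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A `ContactMatrix` (stage `"raw"`) of integer counts.
#' @export
structure_to_contact_map <- function(structure, bins, n_contacts,
                                     c0 = 1, alpha = 1, seed = 1L) {
  stopifnot(inherits(structure, "Structure3D"))
  if (nrow(structure) != nrow(bins)) {
    stop("need exactly one bead per bin (", nrow(structure), " beads vs ",
         nrow(bins), " bins)")
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  n <- nrow(D)
  ut <- upper.tri(D)
  if (any(D[ut] == 0)) {
    stop("degenerate structure: coincident beads give zero distance")
  }
  w <- c0 / D[ut]^alpha
  p <- w / sum(w)
  counts <- with_seed(seed, stats::rmultinom(1, n_contacts, p)[, 1])
  M <- matrix(0, n, n)
  M[ut] <- counts
  M <- M + t(M)
  contact_matrix(M, bins, stage = "raw")
}

#' Simulate mapped 3C read pairs from bin-pair contact probabilities
#'
#' Samples `n_pairs` bin pairs from `contact_probs` (normalized over
#' unordered pairs), places each mate at a uniform position within a random
#' restriction fragment of its bin, then appends exact PCR duplicates (same
#' coordinates, strands and adapter tag) for a binomial `dup_fraction` of
#' pairs and downgrades a binomial `lowq_fraction` of mates to mapping
#' quality <= 40. The planted per-bin-pair counts (before duplication) are
#' returned as ground truth.
#'
#' @param contact_probs A `ContactMatrix` of probabilities (or any symmetric
#'   nonnegative matrix container; it is normalized internally).
#' @param frag_map `RestrictionFragmentMap` used to place reads.
#' @param n_pairs Number of distinct molecule pairs to sample.
#' @param dup_fraction Probability that a pair receives a PCR duplicate.
#' @param lowq_fraction Probability that a mate is low-quality (MAPQ <= 40).
#' @param seed Integer seed.
#' @return A list with `pairs` (data.frame: chrom1, pos1, strand1, mapq1,
#'   chrom2, pos2, strand2, mapq2, umi), `truth` (planted symmetric bin-pair
#'   count matrix), and `bins`.
#' @export
simulate_read_pairs <- function(contact_probs, frag_map, n_pairs,
                                dup_fraction = 0, lowq_fraction = 0,
                                seed = 1L) {
  if (dup_fraction < 0 || dup_fraction > 1 ||
      lowq_fraction < 0 || lowq_fraction > 1) {
    stop("dup_fraction and lowq_fraction must lie in [0, 1]")
  }
  P <- contact_probs$mat
  bins <- contact_probs$bins
  n <- nrow(P)
  keep <- upper.tri(P, diag = TRUE)
  w <- P[keep]
  if (sum(w) <= 0) stop("contact probabilities sum to zero")
  w <- w / sum(w)
  idx <- which(keep, arr.ind = TRUE)

  with_seed(seed, {
    counts <- stats::rmultinom(1, n_pairs, w)[, 1]
    pick <- rep.int(seq_along(counts), counts)
    bi <- idx[pick, 1]
    bj <- idx[pick, 2]

    place <- function(bin_idx) {
      ch <- bins$chrom[bin_idx]
      # random fragment within the bin, uniform position within the fragment
      f_lo <- bins$frag_first[bin_idx]
      f_hi <- bins$frag_last[bin_idx]
      f <- f_lo + floor(stats::runif(length(bin_idx)) * (f_hi - f_lo + 1))
      key <- paste0(ch, ":", f)
      fm_key <- paste0(frag_map$chrom, ":", frag_map$frag)
      row <- match(key, fm_key)
      if (anyNA(row)) stop("bin references fragments missing from frag_map")
      s <- frag_map$start[row]
      e <- frag_map$end[row]
      floor(s + stats::runif(length(bin_idx)) * (e - s))
    }
    pos1 <- place(bi)
    pos2 <- place(bj)
    m <- length(bi)
    mapq_hi <- function(k) 41L + floor(stats::runif(k) * 20)
    mq1 <- mapq_hi(m)
    mq2 <- mapq_hi(m)
    low1 <- stats::runif(m) < lowq_fraction
    low2 <- stats::runif(m) < lowq_fraction
    mq1[low1] <- floor(stats::runif(sum(low1)) * 41)
    mq2[low2] <- floor(stats::runif(sum(low2)) * 41)
    umi <- random_umi(m)
    pairs <- data.frame(
      chrom1 = bins$chrom[bi], pos1 = pos1,
      strand1 = ifelse(stats::runif(m) < 0.5, "+", "-"), mapq1 = mq1,
      chrom2 = bins$chrom[bj], pos2 = pos2,
      strand2 = ifelse(stats::runif(m) < 0.5, "+", "-"), mapq2 = mq2,
      umi = umi, stringsAsFactors = FALSE
    )
    dup <- stats::runif(m) < dup_fraction
    if (any(dup)) pairs <- rbind(pairs, pairs[dup, , drop = FALSE])
    truth <- matrix(0, n, n)
    for (k in seq_len(m)) {
      truth[bi[k], bj[k]] <- truth[bi[k], bj[k]] + 1
      if (bi[k] != bj[k]) truth[bj[k], bi[k]] <- truth[bj[k], bi[k]] + 1
    }
    rownames(pairs) <- NULL
    list(pairs = pairs, truth = truth, bins = bins)
  })
}

random_umi <- function(n, width = 6L) {
  letters4 <- c("A", "C", "G", "T")
  m <- matrix(letters4[1L + floor(stats::runif(n * width) * 4)], nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Write / read mapped pairs as a tab-separated pairs-style file
#'
#' Columns `chrom1 pos1 strand1 mapq1 chrom2 pos2 strand2 mapq2 umi`; lines
#' starting with `#` are comments.
#'
#' @param pairs Pairs data.frame.
#' @param path File path.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom1\tpos1\tstrand1\tmapq1\tchrom2\tpos2\tstrand2\tmapq2\tumi",
             con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom1", "pos1", "strand1", "mapq1",
                                  "chrom2", "pos2", "strand2", "mapq2",
                                  "umi"))
}
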