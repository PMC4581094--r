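# From mapped read pairs to filtered, SCN-normalized contact matrices.

#' Filter mapped pairs by mapping quality and collapse PCR duplicates
#'
#' Pairs are kept only when both mates exceed `mapq_min` (strictly greater,
#' default 40). PCR duplicates — records identical in both coordinates, both
#' strands and the adapter random-hexamer tag (UMI) — are collapsed to one
#' representative. Mate order within a pair is canonicalized first, so
#' swapped mates of the same ligation product count as duplicates.
#'
#' @param pairs Data.frame with columns `chrom1, pos1, strand1, mapq1,
#'   chrom2, pos2, strand2, mapq2` and optionally `umi`.
#' @param mapq_min Mapping-quality threshold; mates with `mapq <= mapq_min`
#'   reject the pair.
#' @return Filtered pairs data.frame with attributes `n_lowq` (pairs removed
#'   by the quality rule) and `n_dup` (duplicate records collapsed).
#' @export
preprocess_pairs <- function(pairs, mapq_min = 40L) {
  keep <- pairs$mapq1 > mapq_min & pairs$mapq2 > mapq_min
  n_lowq <- sum(!keep)
  p <- pairs[keep, , drop = FALSE]

  # canonical mate order: (chrom, pos) lexicographic
  swap <- p$chrom2 < p$chrom1 | (p$chrom2 == p$chrom1 & p$pos2 < p$pos1)
  if (any(swap)) {
    tmp <- p[swap, c("chrom1", "pos1", "strand1", "mapq1")]
    p[swap, c("chrom1", "pos1", "strand1", "mapq1")] <-
      p[swap, c("chrom2", "pos2", "strand2", "mapq2")]
    p[swap, c("chrom2", "pos2", "strand2", "mapq2")] <- tmp
  }

  if ("umi" %in% names(p)) {
    key <- paste(p$chrom1, p$pos1, p$strand1, p$chrom2, p$pos2, p$strand2,
                 p$umi, sep = "\r")
  } else {
    warning("no 'umi' column: collapsing duplicates on coordinates alone")
    key <- paste(p$chrom1, p$pos1, p$strand1, p$chrom2, p$pos2, p$strand2,
                 sep = "\r")
  }
  dup <- duplicated(key)
  out <- p[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_lowq") <- n_lowq
  attr(out, "n_dup") <- sum(dup)
  out
}

#' Build a raw contact matrix from preprocessed pairs
#'
#' Each mate is assigned to the restriction fragment whose half-open
#' interval contains its position, fragments map to bins through the bin
#' table, and each unordered bin pair increments the symmetric count matrix
#' (diagonal entries increment once per pair).
#'
#' @param pairs Preprocessed pairs data.frame.
#' @param frag_map `RestrictionFragmentMap`.
#' @param bins `BinTable` built from the same fragment map.
#' @return A `ContactMatrix` (stage `"raw"`) with attribute `n_rejected`:
#'   the number of pairs with a coordinate outside every fragment.
#' @export
build_contact_matrix <- function(pairs, frag_map, bins) {
  n <- nrow(bins)
  # per-chromosome fragment lookup, then fragment -> bin
  frag_bin <- frag_to_bin_map(frag_map, bins)
  assign_bin <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      fr <- frag_map[frag_map$chrom == cn, , drop = FALSE]
      if (!nrow(fr)) next
      fr <- fr[order(fr$start), , drop = FALSE]
      i <- findInterval(pos[sel], fr$start)
      ok <- i >= 1 & pos[sel] >= 0 & pos[sel] < fr$end[pmax(i, 1)]
      fi <- rep(NA_integer_, sum(sel))
      fi[ok] <- fr$frag[i[ok]]
      key <- paste0(cn, ":", fi)
      out[sel] <- frag_bin[key]
    }
    out
  }
  b1 <- assign_bin(pairs$chrom1, pairs$pos1)
  b2 <- assign_bin(pairs$chrom2, pairs$pos2)
  ok <- !is.na(b1) & !is.na(b2)
  M <- matrix(0, n, n)
  if (any(ok)) {
    tab <- table(factor(pmin(b1[ok], b2[ok]), levels = seq_len(n)),
                 factor(pmax(b1[ok], b2[ok]), levels = seq_len(n)))
    U <- matrix(as.numeric(tab), n, n)
    M <- U + t(U) - diag(diag(U))
  }
  cm <- contact_matrix(M, bins, stage = "raw")
  attr(cm, "n_rejected") <- sum(!ok)
  cm
}

frag_to_bin_map <- function(frag_map, bins) {
  keys <- character(0)
  vals <- integer(0)
  for (k in seq_len(nrow(bins))) {
    f <- bins$frag_first[k]:bins$frag_last[k]
    keys <- c(keys, paste0(bins$chrom[k], ":", f))
    vals <- c(vals, rep.int(k, length(f)))
  }
  stats::setNames(vals, keys)
}

#' Mask low-coverage bins of a raw contact matrix
#'
#' Bins whose marginal sum is zero, or below the given quantile of the
#' nonzero marginals, are masked and the matrix is restricted to the
#' retained bins. The mask (over the original bins) is recorded on the
#' result.
#'
#' @param M A raw `ContactMatrix`.
#' @param min_coverage_quantile Quantile of the nonzero marginal sums below
#'   which bins are dropped (default 0.01).
#' @return A `ContactMatrix` (stage `"filtered"`).
#' @export
filter_bins <- function(M, min_coverage_quantile = 0.01) {
  marg <- rowSums(M$mat)
  nz <- marg[marg > 0]
  if (!length(nz)) stop("all bins have zero coverage; nothing to retain")
  thr <- stats::quantile(nz, min_coverage_quantile, names = FALSE)
  keep <- marg > 0 & marg >= thr
  if (!any(keep)) stop("all bins masked at quantile ", min_coverage_quantile)
  bins <- M$bins[keep, , drop = FALSE]
  rownames(bins) <- NULL
  mask <- M$mask
  mask[mask] <- keep   # compose with any earlier mask
  contact_matrix(M$mat[keep, keep, drop = FALSE], bins,
                 stage = "filtered", mask = mask)
}

#' Sequential component normalization (SCN) of a contact matrix
#'
#' Iteratively normalizes columns to unit sum, then rows, then symmetrizes
#' with `(M + t(M)) / 2`, until every row and column sum equals 1 within
#' `tol`. The result is a symmetric, doubly stochastic matrix: each bin's
#' contact profile becomes a probability vector, removing coverage biases.
#'
#' @param M A filtered `ContactMatrix` with no zero rows or columns.
#' @param tol Convergence tolerance on `max |row/col sum - 1|`.
#' @param max_iter Maximum number of normalization rounds.
#' @return A `ContactMatrix` (stage `"normalized"`) with attribute
#'   `iterations`.
#' @export
scn_normalize <- function(M, tol = 1e-6, max_iter = 200L) {
  m <- M$mat
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero rows/columns present; run filter_bins() first")
  }
  res <- Inf
  for (it in seq_len(max_iter)) {
    m <- sweep(m, 2, colSums(m), `/`)
    m <- sweep(m, 1, rowSums(m), `/`)
    m <- (m + t(m)) / 2
    res <- max(abs(rowSums(m) - 1), abs(colSums(m) - 1))
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf(
      "SCN did not converge in %d iterations (residual %.3g > tol %.3g)",
      max_iter, res, tol))
  }
  out <- contact_matrix(m, M$bins, stage = "normalized", mask = M$mask)
  attr(out, "iterations") <- it
  out
}
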