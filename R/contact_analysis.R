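# Contact-map statistics: subtelomere contact profiles with distance from
# the telomere, random-segment coverage controls, centromere contact scores
# and inter-chromosomal submatrix views.

# bins of one chromosome intersecting [lo, hi) (bp); returns matrix row idx
bins_in_window <- function(bins, chrom, lo, hi) {
  which(bins$chrom == chrom & bins$end > lo & bins$start < hi)
}

# per-arm window interval measured from the telomere
arm_window <- function(chrom_len, cen_pos, arm, offset, window) {
  if (arm == "L") c(offset, min(offset + window, cen_pos))
  else c(max(chrom_len - offset - window, cen_pos), chrom_len - offset)
}

#' Mean subtelomere contact as a function of distance from the telomere
#'
#' For every chromosome arm and every window of `window` bp at offset
#' `0, window, 2*window, ...` from the telomere (moving toward the
#' centromere), computes the mean contact between that window's bins and
#' the telomere-proximal (offset 0) windows of all arms of *other*
#' chromosomes; the profile value at an offset is the mean over arms.
#' A rising value toward offset 0 reveals specific subtelomere-subtelomere
#' contact; a flat profile indicates none.
#'
#' @param M A normalized `ContactMatrix` whose resolution is at most
#'   `window` bp.
#' @param genome A [GenomeModel].
#' @param window Window size in bp (3 kb in the classic fragment-resolution
#'   analysis; use the bin size for coarser maps).
#' @param extent How far from the telomere to profile, in bp.
#' @return A `ContactProfile` data.frame: `offset_start`, `offset_end`,
#'   `mean_contact`, `n_pairs`.
#' @export
subtelomere_contact_profile <- function(M, genome, window = 3000,
                                        extent = 30000) {
  bins <- M$bins
  if (max(bins$end - bins$start) > window) {
    stop("matrix resolution is coarser than the window size")
  }
  chrom <- genome$chromosomes
  arms <- merge(
    data.frame(chrom = rep(chrom$name, each = 2),
               arm = rep(c("L", "R"), nrow(chrom))),
    data.frame(chrom = chrom$name, len = chrom$length,
               cen = chrom$centromere_pos),
    by = "chrom"
  )
  if (extent > min(genome$telomeres$arm_length)) {
    warning("extent exceeds the shortest arm; short arms contribute only ",
            "their available windows")
  }
  offsets <- seq(0, extent - 1, by = window)
  # offset-0 bin sets per arm
  zero_sets <- lapply(seq_len(nrow(arms)), function(i) {
    w <- arm_window(arms$len[i], arms$cen[i], arms$arm[i], 0, window)
    bins_in_window(bins, arms$chrom[i], w[1], w[2])
  })
  prof <- lapply(offsets, function(off) {
    vals <- c(); npair <- 0L
    for (i in seq_len(nrow(arms))) {
      arm_len <- if (arms$arm[i] == "L") arms$cen[i]
                 else arms$len[i] - arms$cen[i]
      if (off + window > arm_len) next  # window would cross the centromere
      w <- arm_window(arms$len[i], arms$cen[i], arms$arm[i], off, window)
      wi <- bins_in_window(bins, arms$chrom[i], w[1], w[2])
      if (!length(wi)) next
      others <- unlist(zero_sets[arms$chrom != arms$chrom[i]])
      others <- setdiff(others, wi)
      if (!length(others)) next
      vals <- c(vals, mean(M$mat[wi, others, drop = FALSE]))
      npair <- npair + length(wi) * length(others)
    }
    data.frame(offset_start = off, offset_end = off + window,
               mean_contact = if (length(vals)) mean(vals) else NA_real_,
               n_pairs = npair)
  })
  out <- do.call(rbind, prof)
  class(out) <- c("ContactProfile", "data.frame")
  out
}

#' Random-segment contact control
#'
#' Samples `n_segments` non-telomeric segments of `seg_length` bp uniformly
#' from the genome (excluding the terminal `exclude_terminal` bp of every
#' arm) and computes, for each segment, the mean contact with all segments
#' on other chromosomes. Equality of the control between conditions
#' demonstrates absence of coverage bias after normalization.
#'
#' @param M A normalized `ContactMatrix`.
#' @param genome A [GenomeModel].
#' @param seg_length Segment length in bp (the classic control uses 35 kb).
#' @param n_segments Number of segments (>= 2).
#' @param exclude_terminal Terminal region of each arm excluded from
#'   sampling, in bp.
#' @param seed Integer seed.
#' @return List with `mean` (grand mean contact), `sd` (standard deviation
#'   over per-segment means), `se` (`sd / sqrt(n_segments)`), `n_pairs`,
#'   and `segments` (data.frame chrom/start/end).
#' @export
random_segment_control <- function(M, genome, seg_length = 35000,
                                   n_segments = 100, exclude_terminal = 30000,
                                   seed = 1L) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  bins <- M$bins
  chrom <- genome$chromosomes
  eligible <- chrom[chrom$length > 2 * exclude_terminal + seg_length, ,
                    drop = FALSE]
  if (nrow(eligible) < 2) stop("no two chromosomes can host control segments")
  with_seed(seed, {
    ci <- sample.int(nrow(eligible), n_segments, replace = TRUE,
                     prob = eligible$length)
    lo <- exclude_terminal
    hi <- eligible$length[ci] - exclude_terminal - seg_length
    start <- floor(lo + stats::runif(n_segments) * (hi - lo))
    segs <- data.frame(chrom = eligible$name[ci], start = start,
                       end = start + seg_length, stringsAsFactors = FALSE)
    sets <- lapply(seq_len(n_segments), function(k) {
      bins_in_window(bins, segs$chrom[k], segs$start[k], segs$end[k])
    })
    seg_means <- rep(NA_real_, n_segments)
    n_pairs <- 0L
    for (k in seq_len(n_segments)) {
      others <- unlist(sets[segs$chrom != segs$chrom[k]])
      if (!length(sets[[k]]) || !length(others)) next
      seg_means[k] <- mean(M$mat[sets[[k]], others, drop = FALSE])
      n_pairs <- n_pairs + length(sets[[k]]) * length(others)
    }
    seg_means <- seg_means[!is.na(seg_means)]
    list(mean = mean(seg_means), sd = stats::sd(seg_means),
         se = stats::sd(seg_means) / sqrt(length(seg_means)),
         n_pairs = n_pairs, segments = segs)
  })
}

#' Mean inter-chromosomal centromere-centromere contact
#'
#' Averages the normalized contact between centromere-containing windows of
#' different chromosomes. High values indicate centromere clustering (the
#' Rabl hallmark of cycling cells).
#'
#' @param M A normalized `ContactMatrix`.
#' @param genome A [GenomeModel].
#' @param window Window in bp centered on each centromere.
#' @return Scalar mean contact.
#' @export
centromere_contact_score <- function(M, genome, window = 20000) {
  bins <- M$bins
  chrom <- genome$chromosomes
  if (nrow(chrom) < 2) {
    stop("centromere score requires at least two chromosomes")
  }
  sets <- lapply(seq_len(nrow(chrom)), function(i) {
    cen <- chrom$centromere_pos[i]
    bins_in_window(bins, chrom$name[i], cen - window / 2, cen + window / 2)
  })
  empty <- vapply(sets, length, 0L) == 0
  if (any(empty)) {
    warning("centromere bin masked for: ",
            paste(chrom$name[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) < 2) stop("fewer than two centromere windows retained")
  vals <- c()
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j) vals <- c(vals, mean(M$mat[sets[[i]], sets[[j]],
                                            drop = FALSE]))
    }
  }
  mean(vals)
}

#' Rectangular inter-chromosomal submatrix view
#'
#' @param M A `ContactMatrix`.
#' @param chrom_a,chrom_b Chromosome names (rows = `chrom_a` bins,
#'   columns = `chrom_b` bins).
#' @return Rectangular numeric matrix with `chrom:start-end` dimnames.
#' @export
interchromosomal_submatrix <- function(M, chrom_a, chrom_b) {
  bins <- M$bins
  ia <- which(bins$chrom == chrom_a)
  ib <- which(bins$chrom == chrom_b)
  if (!length(ia)) stop("unknown or fully masked chromosome: ", chrom_a)
  if (!length(ib)) stop("unknown or fully masked chromosome: ", chrom_b)
  sub <- M$mat[ia, ib, drop = FALSE]
  dimnames(sub) <- list(bin_ids(bins)[ia], bin_ids(bins)[ib])
  sub
}

#' Write a contact profile as tab-separated text
#'
#' @param profile A `ContactProfile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
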