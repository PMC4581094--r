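# Genome coordinate system: chromosomes, centromeres, telomeres, rDNA,
# restriction fragments and fragment-group bins. All coordinates are 0-based,
# half-open [start, end) in bp, BED-style.

#' Approximate budding-yeast karyotype used as the default toy genome
#'
#' Arm lengths (left arm = telomere to centromere, right arm = centromere to
#' telomere) in bp for a 16-chromosome karyotype resembling *S. cerevisiae*.
#' Values are rounded to the kb; they are a synthetic stand-in, not an
#' annotation release.
#'
#' @return A list of 16 numeric length-2 vectors, named by roman numeral.
#' @export
yeast_arm_lengths <- function() {
  kb <- 1000
  list(
    I    = c(151,  79) * kb,
    II   = c(238, 575) * kb,
    III  = c(115, 202) * kb,
    IV   = c(450, 1082) * kb,
    V    = c(152, 425) * kb,
    VI   = c(148, 122) * kb,
    VII  = c(497, 594) * kb,
    VIII = c(105, 457) * kb,
    IX   = c(356,  84) * kb,
    X    = c(436, 310) * kb,
    XI   = c(440, 227) * kb,
    XII  = c(151, 927) * kb,
    XIII = c(268, 656) * kb,
    XIV  = c(629, 155) * kb,
    XV   = c(327, 764) * kb,
    XVI  = c(556, 392) * kb
  )
}

#' Build a toy genome model
#'
#' Constructs a [GenomeModel]: an ordered set of chromosomes, each defined by
#' two arm lengths joined at the centromere, with the derived table of
#' `2 * n_chrom` telomeres annotated by arm length. Defaults mimic a
#' 16-chromosome budding-yeast karyotype with the rDNA array on chromosome
#' XII.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param arm_lengths List of numeric length-2 vectors `(left_arm, right_arm)`
#'   in bp, one per chromosome. Optionally named; names become chromosome
#'   names. Defaults to [yeast_arm_lengths()] truncated/recycled to
#'   `n_chrom`.
#' @param rdna_chrom Chromosome name carrying the rDNA array, or `NULL`.
#' @param rdna_interval Length-2 vector `(start, end)` of the rDNA interval
#'   in bp on `rdna_chrom`.
#' @return An object of class `GenomeModel`: a list with elements
#'   `chromosomes` (data.frame: name, length, centromere_pos, rdna_start,
#'   rdna_end) and `telomeres` (data.frame: chrom, arm one of "L"/"R",
#'   pos, arm_length), telomeres ordered by increasing arm length.
#' @examples
#' g <- build_toy_genome()
#' nrow(g$telomeres)  # 32
#' @export
build_toy_genome <- function(n_chrom = 16L,
                             arm_lengths = NULL,
                             rdna_chrom = if (n_chrom == 16L) "XII" else NULL,
                             rdna_interval = c(451000, 469000)) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (is.null(arm_lengths)) {
    arm_lengths <- yeast_arm_lengths()
    if (n_chrom > length(arm_lengths)) {
      stop("default karyotype has 16 chromosomes; supply arm_lengths for n_chrom > 16")
    }
    arm_lengths <- arm_lengths[seq_len(n_chrom)]
  }
  if (length(arm_lengths) != n_chrom) {
    stop("arm_lengths must have one (left, right) pair per chromosome")
  }
  arms <- lapply(arm_lengths, as.numeric)
  if (any(vapply(arms, length, 0L) != 2L)) {
    stop("each arm_lengths entry must be a (left, right) pair")
  }
  if (any(unlist(arms) <= 0)) stop("all arm lengths must be > 0")
  nms <- names(arm_lengths)
  if (is.null(nms)) nms <- as.character(utils::as.roman(seq_len(n_chrom)))

  chrom <- data.frame(
    name = nms,
    length = vapply(arms, sum, 0),
    centromere_pos = vapply(arms, `[`, 0, 1L),
    rdna_start = NA_real_,
    rdna_end = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(rdna_chrom)) {
    i <- match(rdna_chrom, chrom$name)
    if (is.na(i)) stop("rdna_chrom not among chromosome names")
    rd <- as.numeric(rdna_interval)
    if (rd[1] < 0 || rd[2] > chrom$length[i] || rd[1] >= rd[2]) {
      stop("rdna_interval must lie within the chromosome")
    }
    chrom$rdna_start[i] <- rd[1]
    chrom$rdna_end[i] <- rd[2]
  }
  telo <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(
      chrom = chrom$name[i],
      arm = c("L", "R"),
      pos = c(0, chrom$length[i]),
      arm_length = c(chrom$centromere_pos[i],
                     chrom$length[i] - chrom$centromere_pos[i]),
      stringsAsFactors = FALSE
    )
  }))
  telo <- telo[order(telo$arm_length, telo$chrom, telo$arm), , drop = FALSE]
  rownames(telo) <- NULL
  structure(list(chromosomes = chrom, telomeres = telo),
            class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosomes, %d telomeres, %.2f Mb\n",
              nrow(x$chromosomes), nrow(x$telomeres),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' In-silico restriction digestion of genome sequences
#'
#' Scans each sequence for the recognition site and cuts at the first base of
#' every occurrence (DpnII-style blunt assignment: the cut coordinate is the
#' 5' start of GATC). Fragments are half-open intervals tiling each
#' chromosome; a zero-length leading fragment (site at position 0) is
#' dropped.
#'
#' @param sequences A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param site Recognition sequence, default `"GATC"` (DpnII).
#' @return A `RestrictionFragmentMap`: data.frame with columns `chrom`,
#'   `start`, `end`, `frag` (0-based fragment index within chromosome).
#' @examples
#' digest_genome(c(chrA = "AAGATCAA"))  # fragments [0,2) and [2,8)
#' @export
digest_genome <- function(sequences, site = "GATC") {
  if (!nzchar(site)) stop("site must be a nonempty recognition sequence")
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("chr", seq_along(sequences))
  }
  pat <- Biostrings::DNAString(site)
  out <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    n <- length(s)
    if (n == 0L) {
      warning(sprintf("empty sequence '%s': no fragments", names(sequences)[i]))
      return(NULL)
    }
    hits <- Biostrings::matchPattern(pat, s)
    cuts <- Biostrings::start(hits) - 1L  # 0-based cut at 5' start of site
    bounds <- unique(c(0, cuts, n))
    bounds <- sort(bounds)
    data.frame(
      chrom = names(sequences)[i],
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      stringsAsFactors = FALSE
    )
  })
  fr <- do.call(rbind, out)
  if (is.null(fr)) {
    fr <- data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  fr <- fr[fr$end > fr$start, , drop = FALSE]
  fr$frag <- stats::ave(fr$start, fr$chrom, FUN = seq_along) - 1
  rownames(fr) <- NULL
  class(fr) <- c("RestrictionFragmentMap", "data.frame")
  fr
}

#' Uniformly tiled restriction-fragment map
#'
#' Builds a synthetic fragment map by tiling each chromosome of a genome
#' model with fixed-length fragments (the last fragment of a chromosome may
#' be shorter). Convenient when no sequence is available, e.g. to pair a
#' simulated bead-chain structure with a matching bin table: `frag_len =
#' 1000` with `bin_fragments(F = 20)` gives 20-kb bins, one per bead.
#'
#' @param genome A [GenomeModel].
#' @param frag_len Fragment length in bp.
#' @return A `RestrictionFragmentMap` data.frame.
#' @export
tile_frag_map <- function(genome, frag_len = 1000) {
  stopifnot(inherits(genome, "GenomeModel"), frag_len >= 1)
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    starts <- seq(0, len - 1, by = frag_len)
    data.frame(
      chrom = genome$chromosomes$name[i],
      start = starts,
      end = pmin(starts + frag_len, len),
      frag = seq_along(starts) - 1,
      stringsAsFactors = FALSE
    )
  })
  fr <- do.call(rbind, out)
  rownames(fr) <- NULL
  class(fr) <- c("RestrictionFragmentMap", "data.frame")
  fr
}

#' Group restriction fragments into bins
#'
#' Bins each chromosome's fragments into consecutive groups of `F`
#' fragments; the last bin of a chromosome may hold fewer. Bin coordinates
#' are the union of the member fragments' intervals. Bins never span
#' chromosomes and the genome-wide index `bin` is contiguous from 0.
#'
#' @param frag_map A `RestrictionFragmentMap` (from [digest_genome()] or
#'   [tile_frag_map()]).
#' @param F Fragments per bin (>= 1); the classic choices are 20 and 10.
#' @return A `BinTable`: data.frame with columns `bin`, `chrom`, `start`,
#'   `end`, `frag_first`, `frag_last` (0-based, inclusive fragment range
#'   within the chromosome).
#' @export
bin_fragments <- function(frag_map, F = 20L) {
  if (F < 1) stop("F must be >= 1")
  F <- as.integer(F)
  chroms <- unique(frag_map$chrom)
  out <- lapply(chroms, function(cn) {
    fr <- frag_map[frag_map$chrom == cn, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    n <- nrow(fr)
    grp <- (seq_len(n) - 1L) %/% F
    grp <- factor(grp, levels = sort(unique(grp)))  # keep numeric order
    data.frame(
      chrom = cn,
      start = tapply(fr$start, grp, min),
      end = tapply(fr$end, grp, max),
      frag_first = tapply(fr$frag, grp, min),
      frag_last = tapply(fr$frag, grp, max),
      stringsAsFactors = FALSE
    )
  })
  bins <- do.call(rbind, out)
  bins <- data.frame(bin = seq_len(nrow(bins)) - 1L, bins,
                     stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  class(bins) <- c("BinTable", "data.frame")
  bins
}

#' Bead-resolution bin table for a genome model
#'
#' One 20-kb bin per bead, matching the bead chains produced by
#' [simulate_structure()].
#'
#' @param genome A [GenomeModel].
#' @param bead_bp Bead size in bp (default 20 kb).
#' @return A `BinTable`.
#' @export
bead_bin_table <- function(genome, bead_bp = 20000) {
  bin_fragments(tile_frag_map(genome, frag_len = bead_bp), F = 1L)
}

#' Write a fragment map or bin table as a BED-like file
#'
#' Tab-separated `chrom start end index`, no header.
#'
#' @param x A `RestrictionFragmentMap` or `BinTable`.
#' @param path Output file path.
#' @export
write_bed_like <- function(x, path) {
  idx <- if ("bin" %in% names(x)) x$bin else x$frag
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE), idx)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
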