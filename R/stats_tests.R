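# Rank and proportion tests used for the population comparisons.

#' Mann-Whitney U test
#'
#' Computes the U statistic of the first sample from midranks. The p-value
#' is exact (full enumeration of rank assignments) when the combined sample
#' size is at most 12 and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param sample_a,sample_b Numeric samples (nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives on sample_a's tendency relative to sample_b).
#' @return List with `U` (statistic of `sample_a`), `p.value`, and
#'   `method` ("exact" or "normal approximation").
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b))  # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(sample_a, sample_b)))

  if (na + nb <= 12 && !ties) {
    # exact null distribution of U by enumeration of rank assignments
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(combos, nrow = na)) - na * (na + 1) / 2
    p_le <- mean(u_all <= U)
    p_ge <- mean(u_all >= U)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "exact"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * (N + 1 - tie_term))
    # continuity-corrected z
    z <- switch(alternative,
                two.sided = (U - mu - sign(U - mu) * 0.5) / sigma,
                less = (U - mu + 0.5) / sigma,
                greater = (U - mu - 0.5) / sigma)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(U = U, p.value = p, method = method)
}

#' Two-proportion Z test
#'
#' Pooled-proportion z statistic for comparing `x1/n1` against `x2/n2`,
#' with a two-sided p-value from the standard normal.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p.value`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("successes must lie in [0, n]")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}
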