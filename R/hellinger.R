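#' Orientation scores for a trait's corrected p-value profile
#'
#' Maps corrected p-values to scores 1 - p before binning, so the bulk of
#' non-significant associations (p close to 1) falls near zero (the small
#' bins) and an exceptional association approaches 1 (the largest bin),
#' matching the orientation of the cubic reference distribution. The
#' `"neglog10"` alternative uses -log10(p).
#'
#' @param p Numeric vector of corrected p-values, all in (0, 1].
#' @param transform `"one-minus-p"` (default) or `"neglog10"`.
#' @return Numeric vector of scores, same length.
#' @export
significance_scores <- function(p, transform = c("one-minus-p", "neglog10")) {
  transform <- match.arg(transform)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("corrected p-values must lie in (0, 1]")
  switch(transform,
         "one-minus-p" = 1 - p,
         "neglog10" = -log10(p))
}

#' Build an equal-width histogram
#'
#' Bins values into `n_bins` equal-width bins over the value range, with
#' binwidth = (max - min) / n_bins. Bins are half-open [lo, hi) except the
#' last, which is closed so the maximum is counted. If all values are equal
#' the whole mass goes into bin 1.
#'
#' @param values Numeric vector (>= 1 finite value).
#' @param n_bins Number of bins (>= 1); default 30.
#' @return Object of class `"hd_histogram"`: list with `counts`, `n_bins`,
#'   `binwidth`, `range_min`, `range_max`, `total`.
#' @export
make_histogram <- function(values, n_bins = 30) {
  if (length(values) == 0) stop("cannot build a histogram of zero values")
  if (anyNA(values) || any(!is.finite(values)))
    stop("histogram input must be finite")
  if (n_bins < 1) stop("n_bins must be >= 1")
  lo <- min(values)
  hi <- max(values)
  bw <- (hi - lo) / n_bins
  if (bw == 0) {
    counts <- c(length(values), rep(0L, n_bins - 1))
  } else {
    idx <- floor((values - lo) / bw) + 1
    idx[idx > n_bins] <- n_bins  # maximum lands in the closed last bin
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(counts = as.integer(counts), n_bins = as.integer(n_bins),
                 binwidth = bw, range_min = lo, range_max = hi,
                 total = length(values)),
            class = "hd_histogram")
}

#' @export
print.hd_histogram <- function(x, ...) {
  cat("Histogram: ", x$total, " values in ", x$n_bins,
      " bins over [", signif(x$range_min, 4), ", ", signif(x$range_max, 4),
      "], binwidth ", signif(x$binwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Hellinger distance between two histograms
#'
#' Compares the bin proportions of two histograms positionally (bin a of P
#' against bin a of Q), so only the shapes, not the scales, of the two
#' distributions matter. The default formula is the true Hellinger distance
#'
#'   HD = sqrt( sum_a ( sqrt(P_a/|P|) - sqrt(Q_a/|Q|) )^2 ),
#'
#' with range \[0, sqrt(2)\]; `formula = "printed"` computes the plain
#' squared-proportion form sum_a (P_a/|P| - Q_a/|Q|)^2, with range \[0, 2\].
#'
#' @param P,Q `hd_histogram` objects with equal `n_bins` and positive totals.
#' @param formula `"hellinger"` (default) or `"printed"`.
#' @return A single non-negative distance.
#' @export
hellinger_distance <- function(P, Q, formula = c("hellinger", "printed")) {
  formula <- match.arg(formula)
  stopifnot(inherits(P, "hd_histogram"), inherits(Q, "hd_histogram"))
  if (P$n_bins != Q$n_bins)
    stop("histograms have different bin counts (", P$n_bins, " vs ",
         Q$n_bins, ")")
  if (P$total <= 0 || Q$total <= 0)
    stop("histograms must have positive totals")
  p <- P$counts / P$total
  q <- Q$counts / Q$total
  if (formula == "hellinger") sqrt(sum((sqrt(p) - sqrt(q))^2))
  else sum((p - q)^2)
}

#' Reference histogram for a single-locus association profile
#'
#' Histogram of the reference distribution \{x^3 : x = 1..L\} over the L
#' loci, binned over its own range [1, L^3] with the same binning rules as
#' [make_histogram()]. The cubic growth concentrates most values in the
#' smallest bins with a long sparse tail up to the single largest value,
#' modelling a trait whose profile is dominated by one exceptional
#' association. As L grows the first-bin proportion tends to
#' (1/n_bins)^(1/3).
#'
#' @param L Number of loci (>= 1).
#' @param n_bins Number of bins; default 30. A warning is given if L <
#'   n_bins.
#' @return An `hd_histogram` object.
#' @export
reference_histogram <- function(L, n_bins = 30) {
  if (L < 1) stop("L must be >= 1")
  if (L < n_bins)
    warning("fewer loci (", L, ") than bins (", n_bins,
            "); reference histogram will be sparse")
  make_histogram(as.numeric(seq_len(L))^3, n_bins = n_bins)
}

#' Hellinger distance statistic for one trait
#'
#' The package's core statistic: the Hellinger distance between the
#' histogram of the trait's transformed corrected p-value profile and the
#' reference histogram of the cubic distribution over the same number of
#' loci. Each histogram is binned over its own range. Small distances flag
#' traits whose profile is dominated by a single exceptional association.
#'
#' @param p_row Corrected p-values for one trait across all L markers
#'   (names = marker ids). `NA` entries (undefined associations) are dropped
#'   from the histogram but disqualify a marker from `best_marker`.
#' @param n_bins Number of bins; default 30.
#' @param formula,transform Passed to [hellinger_distance()] and
#'   [significance_scores()].
#' @return List with `hd`, `best_marker` (smallest corrected p; ties go to
#'   the lowest marker index), `best_p`, `n_ties`, `n_bins`.
#' @export
trait_hd <- function(p_row, n_bins = 30,
                     formula = c("hellinger", "printed"),
                     transform = c("one-minus-p", "neglog10")) {
  formula <- match.arg(formula)
  transform <- match.arg(transform)
  L <- length(p_row)
  ok <- !is.na(p_row)
  if (!any(ok)) stop("trait has no defined corrected p-values")
  scores <- significance_scores(p_row[ok], transform = transform)
  P <- make_histogram(scores, n_bins = n_bins)
  Q <- reference_histogram(L, n_bins = n_bins)
  best_idx <- which.min(p_row)  # lowest index wins on ties
  best_p <- p_row[[best_idx]]
  n_ties <- sum(p_row == best_p, na.rm = TRUE)
  list(hd = hellinger_distance(P, Q, formula = formula),
       best_marker = if (!is.null(names(p_row))) names(p_row)[best_idx]
                     else best_idx,
       best_p = best_p, n_ties = as.integer(n_ties),
       n_bins = as.integer(n_bins))
}

#' Hellinger distance statistics for all traits
#'
#' @param pvals Traits x markers corrected p-value matrix.
#' @inheritParams trait_hd
#' @return Data frame with one row per trait: `trait`, `hd`, `best_marker`,
#'   `best_p`, `n_ties`.
#' @export
hd_statistics <- function(pvals, n_bins = 30,
                          formula = c("hellinger", "printed"),
                          transform = c("one-minus-p", "neglog10")) {
  formula <- match.arg(formula)
  transform <- match.arg(transform)
  res <- lapply(seq_len(nrow(pvals)), function(i) {
    row <- pvals[i, ]
    names(row) <- colnames(pvals)
    trait_hd(row, n_bins = n_bins, formula = formula, transform = transform)
  })
  data.frame(
    trait = rownames(pvals),
    hd = vapply(res, `[[`, numeric(1), "hd"),
    best_marker = vapply(res, `[[`, character(1), "best_marker"),
    best_p = vapply(res, `[[`, numeric(1), "best_p"),
    n_ties = vapply(res, `[[`, integer(1), "n_ties"),
    stringsAsFactors = FALSE)
}

#' Tails of the Hellinger distance distribution
#'
#' Selects the traits with the smallest and largest Hellinger distances.
#' With `tail_fraction`, the small tail is traits with hd at or below the
#' `tail_fraction` quantile and the large tail those at or above the
#' (1 - tail_fraction) quantile (type-7 quantiles). With `n`, exactly `n`
#' traits are taken from each end of the hd ordering (count-matched mode,
#' e.g. matching the number of eQTL traits); ties are broken by trait id.
#'
#' @param hd_table Data frame from [hd_statistics()].
#' @param tail_fraction Fraction in (0, 0.5); default 0.05. Ignored if `n`
#'   is given.
#' @param n Optional count per tail.
#' @return List with character vectors `small` and `large`.
#' @export
hd_tails <- function(hd_table, tail_fraction = 0.05, n = NULL) {
  ord <- order(hd_table$hd, hd_table$trait)
  if (!is.null(n)) {
    n <- min(n, nrow(hd_table))
    small <- hd_table$trait[ord[seq_len(n)]]
    large <- hd_table$trait[rev(ord)[seq_len(n)]]
  } else {
    if (!(tail_fraction > 0 && tail_fraction < 0.5))
      stop("tail_fraction must be in (0, 0.5)")
    qs <- stats::quantile(hd_table$hd, c(tail_fraction, 1 - tail_fraction),
                          type = 7, names = FALSE)
    if (qs[1] == qs[2])
      warning("degenerate hd distribution: tails selected by rank tie-break")
    n_tail <- max(1L, floor(tail_fraction * nrow(hd_table)))
    small <- hd_table$trait[ord[seq_len(n_tail)]]
    large <- hd_table$trait[rev(ord)[seq_len(n_tail)]]
  }
  list(small = small, large = large)
}

#' Robustness of the hd ranking to the number of bins
#'
#' Recomputes the per-trait Hellinger distances for each bin count and
#' reports the Spearman rank correlation between every pair of bin counts.
#'
#' @param pvals Corrected p-value matrix.
#' @param bins Integer vector of bin counts; default 10..100 step 10.
#' @inheritParams trait_hd
#' @return List with `hd` (traits x bin-counts matrix) and `rho` (pairwise
#'   Spearman correlation matrix; `NA` when undefined, e.g. a single trait).
#' @export
bin_sweep <- function(pvals, bins = seq(10, 100, by = 10),
                      formula = c("hellinger", "printed"),
                      transform = c("one-minus-p", "neglog10")) {
  if (length(bins) == 0) stop("bins must be non-empty")
  formula <- match.arg(formula)
  transform <- match.arg(transform)
  hd <- sapply(bins, function(b)
    hd_statistics(pvals, n_bins = b, formula = formula,
                  transform = transform)$hd)
  hd <- matrix(hd, nrow = nrow(pvals),
               dimnames = list(rownames(pvals), paste0("bins", bins)))
  rho <- if (nrow(hd) < 2) {
    matrix(NA_real_, length(bins), length(bins),
           dimnames = list(colnames(hd), colnames(hd)))
  } else {
    suppressWarnings(stats::cor(hd, method = "spearman"))
  }
  list(hd = hd, rho = rho)
}
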