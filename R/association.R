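#' Single-marker LOD score for a haploid cross
#'
#' Computes the standard single-marker regression LOD through the correlation
#' identity LOD = -(n/2) log10(1 - r^2), where r is the Pearson correlation
#' between the 0/1 genotype codes and the expression values over the n
#' pairwise-complete strains. For a haploid (backcross-coded) panel this is
#' the two-group regression LOD.
#'
#' The score is undefined (returned as `NA`) when fewer than 3
#' pairwise-complete strains remain or when genotype or expression is
#' constant on the complete set; it is never silently zero. Perfect
#' separation (r^2 = 1) is capped at `cap`.
#'
#' @param genotype Numeric vector of 0/1 calls (NA allowed).
#' @param expression Numeric vector of expression values, same length.
#' @param cap Ceiling applied to the LOD (default 300).
#' @return A single non-negative LOD, or `NA` if undefined.
#' @export
lod_score <- function(genotype, expression, cap = 300) {
  if (length(genotype) != length(expression))
    stop("genotype and expression vectors differ in length")
  ok <- !is.na(genotype) & !is.na(expression)
  n <- sum(ok)
  if (n < 3) return(NA_real_)
  g <- genotype[ok]
  e <- expression[ok]
  if (stats::sd(g) == 0 || stats::sd(e) == 0) return(NA_real_)
  r2 <- stats::cor(g, e)^2
  lod <- -(n / 2) * log10(max(1 - r2, 0))
  min(lod, cap)
}

#' LOD scores for every trait x marker pair
#'
#' Vectorized over the whole cross: returns a traits x markers matrix of
#' single-marker LODs, `NA` where the score is undefined (constant genotype
#' or expression on the pairwise-complete strains, or fewer than 3 such
#' strains).
#'
#' @param geno An `hd_genotypes` object.
#' @param expr An `hd_expression` object with the same strains in the same
#'   order (see [align_strains()]).
#' @param cap LOD ceiling (default 300).
#' @return Numeric matrix, traits x markers, with dimnames.
#' @export
lod_matrix <- function(geno, expr, cap = 300) {
  G <- t(geno$calls)    # strains x markers
  E <- t(expr$values)   # strains x traits
  if (!identical(rownames(G), rownames(E)))
    stop("genotype and expression strains are not aligned; run align_strains()")
  if (anyNA(G) || anyNA(E)) {
    r <- suppressWarnings(stats::cor(E, G, use = "pairwise.complete.obs"))
    n <- crossprod((!is.na(E)) * 1, (!is.na(G)) * 1)
    r[n < 3] <- NA
  } else {
    r <- suppressWarnings(stats::cor(E, G))
    n <- nrow(E)
  }
  lod <- -(n / 2) * log10(pmax(1 - r^2, 0))
  lod <- pmin(lod, cap)
  dimnames(lod) <- list(rownames(expr$values), rownames(geno$calls))
  lod
}

#' Null distribution of genome-wide maximum LODs by permutation
#'
#' For each iteration the strain labels of the genotype set are permuted by
#' one random permutation shared across all traits (preserving linkage among
#' markers and correlation among traits), all trait x marker LODs are
#' recomputed, and the single genome-wide maximum is recorded. The shared
#' scheme is the standard family-wise construction for genome-wide
#' significance; `mode = "per-trait"` instead permutes each trait's strains
#' independently.
#'
#' @param geno,expr Aligned `hd_genotypes` / `hd_expression` objects.
#' @param n_iterations Number of permutations (>= 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param mode `"shared"` (default) or `"per-trait"`.
#' @param cap LOD ceiling.
#' @param perm_fun Permutation generator `function(n)` returning an index
#'   permutation of `1:n`; defaults to [sample()]. Exposed so a forced
#'   identity permutation can be tested.
#' @return Object of class `"hd_null"`: list with `maxima` (length
#'   `n_iterations`), `n_iterations`, `seed`, `mode`.
#' @export
permutation_null <- function(geno, expr, n_iterations = 1000, seed = 1,
                             mode = c("shared", "per-trait"), cap = 300,
                             perm_fun = sample) {
  mode <- match.arg(mode)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  set.seed(seed)
  n_strains <- ncol(expr$values)
  maxima <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    e <- expr
    if (mode == "shared") {
      perm <- perm_fun(n_strains)
      e$values <- expr$values[, perm, drop = FALSE]
    } else {
      e$values <- t(apply(expr$values, 1,
                          function(row) row[perm_fun(n_strains)]))
    }
    colnames(e$values) <- colnames(expr$values)
    lods <- lod_matrix(geno, e, cap = cap)
    m <- suppressWarnings(max(lods, na.rm = TRUE))
    maxima[i] <- if (is.finite(m)) max(m, 0) else 0
  }
  structure(list(maxima = maxima, n_iterations = n_iterations, seed = seed,
                 mode = mode),
            class = "hd_null")
}

#' @export
print.hd_null <- function(x, ...) {
  cat("Permutation null of genome-wide maximum LODs: ", x$n_iterations,
      " iterations (", x$mode, " permutation), 95th percentile = ",
      signif(stats::quantile(x$maxima, 0.95), 4), "\n", sep = "")
  invisible(x)
}

#' Genome-wide corrected p-values
#'
#' Converts a LOD matrix to genome-wide corrected p-values against the null
#' distribution of per-permutation maximum LODs, with the add-one
#' correction p = (1 + #\{null maxima >= LOD\}) / (N + 1), so p lies in
#' \[1/(N+1), 1\] and is a non-increasing step function of LOD. `NA` LODs
#' (undefined associations) propagate as `NA`.
#'
#' @param lods Traits x markers LOD matrix from [lod_matrix()].
#' @param null An `hd_null` object from [permutation_null()].
#' @return Matrix of corrected p-values, same shape and dimnames as `lods`.
#' @export
corrected_pvalues <- function(lods, null) {
  stopifnot(inherits(null, "hd_null"))
  s <- sort(null$maxima)
  N <- length(s)
  if (N < 1) stop("empty null distribution")
  # number of null maxima >= x, via the ECDF of the sorted null
  n_ge <- N - findInterval(lods, s, left.open = TRUE)
  p <- (1 + n_ge) / (N + 1)
  p[is.na(lods)] <- NA
  p <- matrix(p, nrow = nrow(lods), dimnames = dimnames(lods))
  p
}

#' Call genome-wide significant eQTLs
#'
#' Thresholds the corrected p-value matrix at `alpha`; returns the
#' significant (trait, marker) pairs and the set of traits with at least one
#' eQTL.
#'
#' @param pvals Corrected p-value matrix.
#' @param alpha Genome-wide significance level in (0, 1); default 0.05.
#' @return List with `pairs` (data frame: trait, marker, p_corrected) and
#'   `traits` (character vector).
#' @export
call_eqtls <- function(pvals, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  hit <- which(!is.na(pvals) & pvals <= alpha, arr.ind = TRUE)
  pairs <- data.frame(
    trait = rownames(pvals)[hit[, 1]],
    marker = colnames(pvals)[hit[, 2]],
    p_corrected = pvals[hit],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$trait, pairs$marker), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, traits = sort(unique(pairs$trait)))
}
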