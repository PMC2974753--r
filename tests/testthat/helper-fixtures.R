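# Small in-code fixtures and independent oracles shared across test files.

tiny_map <- function(n = 3, chrom = "chr1") {
  data.frame(marker = sprintf("m%02d", seq_len(n)), chrom = chrom,
             pos = 10 * seq_len(n), stringsAsFactors = FALSE)
}

tiny_geno <- function(calls = NULL, strains = c("a", "b", "c", "d"),
                      n_markers = 3) {
  if (is.null(calls)) {
    calls <- matrix(c(0, 0, 1, 1,
                      0, 1, 0, 1,
                      1, 1, 0, 0)[seq_len(n_markers * length(strains))],
                    nrow = n_markers, byrow = TRUE)
  }
  colnames(calls) <- strains
  hd_genotypes(calls, tiny_map(nrow(calls)))
}

tiny_expr <- function(values = NULL, strains = c("a", "b", "c", "d"),
                      traits = c("t1", "t2"), trait_chrom = NULL) {
  if (is.null(values)) {
    values <- matrix(rnorm(length(traits) * length(strains)),
                     nrow = length(traits))
  }
  dimnames(values) <- list(traits, strains)
  hd_expression(values, trait_chrom)
}

# Independent direct-summation Hellinger evaluator: plain loop, no shared
# code with the package implementation.
hd_brute <- function(p_counts, q_counts, formula = "hellinger") {
  tot_p <- 0
  tot_q <- 0
  for (a in seq_along(p_counts)) tot_p <- tot_p + p_counts[a]
  for (a in seq_along(q_counts)) tot_q <- tot_q + q_counts[a]
  acc <- 0
  for (a in seq_along(p_counts)) {
    pa <- p_counts[a] / tot_p
    qa <- q_counts[a] / tot_q
    if (formula == "hellinger") acc <- acc + (sqrt(pa) - sqrt(qa))^2
    else acc <- acc + (pa - qa)^2
  }
  if (formula == "hellinger") sqrt(acc) else acc
}

# Build an hd_histogram object directly from counts (the totals and ranges
# are all hellinger_distance() consumes besides the counts).
hist_from_counts <- function(counts) {
  structure(list(counts = as.integer(counts),
                 n_bins = length(counts), binwidth = 1,
                 range_min = 0, range_max = length(counts),
                 total = sum(counts)),
            class = "hd_histogram")
}

rand_hist_pair <- function(n_bins, max_count = 50) {
  repeat {
    p <- sample(0:max_count, n_bins, replace = TRUE)
    q <- sample(0:max_count, n_bins, replace = TRUE)
    if (sum(p) > 0 && sum(q) > 0) break
  }
  list(P = hist_from_counts(p), Q = hist_from_counts(q))
}

# Independent single-pair LOD oracle: residual sums of squares from explicit
# least-squares fits of the null and single-marker models.
lod_rss_oracle <- function(g, e) {
  rss0 <- sum((e - mean(e))^2)
  fit <- lm(e ~ g)
  rss1 <- sum(residuals(fit)^2)
  (length(e) / 2) * log10(rss0 / rss1)
}

# Shorthand: run the association stage on a simulated cross.
map_and_correct <- function(sim, n_perm, seed) {
  al <- align_strains(sim$geno, sim$expr)
  lods <- lod_matrix(al$geno, al$expr)
  null <- permutation_null(al$geno, al$expr, n_iterations = n_perm,
                           seed = seed)
  list(geno = al$geno, expr = al$expr, lods = lods, null = null,
       pvals = corrected_pvalues(lods, null))
}
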