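#' Run the full trait-prioritization pipeline
#'
#' Chains the stages: single-marker LOD mapping, permutation-based
#' genome-wide corrected p-values, eQTL calling, per-trait Hellinger
#' distances against the cubic reference, tail selection, hotspot calling on
#' the small-tail traits, cis/trans classification, and tail-overlap
#' summaries.
#'
#' @param geno An `hd_genotypes` object.
#' @param expr An `hd_expression` object (strains need not be pre-aligned).
#' @param n_perm Number of permutations for the genome-wide null.
#' @param seed Integer seed controlling the permutation and hotspot nulls.
#' @param alpha Genome-wide significance level for eQTL calls.
#' @param n_bins Histogram bins for the Hellinger distance.
#' @param formula,transform Hellinger distance options (see
#'   [hellinger_distance()], [significance_scores()]).
#' @param tail_fraction Fraction of traits per hd tail.
#' @param hotspot_percentile Percentile of the hotspot null used as
#'   threshold.
#' @param hotspot_null_iter Iterations of the hotspot null.
#' @param hotspot_tail `"small"` (default) or `"large"`: which hd tail is
#'   assigned to hotspots.
#' @param perm_mode Permutation scheme, `"shared"` or `"per-trait"`.
#' @param lod_cap LOD ceiling.
#' @return Object of class `"hd_run"`: list with `lods`, `pvals`, `null`,
#'   `eqtls`, `hd`, `tails`, `assignment`, `hotspots`, `cis_trans`,
#'   `overlap` (small/large tail counts and fractions), and `config`.
#' @export
run_pipeline <- function(geno, expr, n_perm = 1000, seed = 1, alpha = 0.05,
                         n_bins = 30,
                         formula = c("hellinger", "printed"),
                         transform = c("one-minus-p", "neglog10"),
                         tail_fraction = 0.05, hotspot_percentile = 0.95,
                         hotspot_null_iter = 1000,
                         hotspot_tail = c("small", "large"),
                         perm_mode = c("shared", "per-trait"),
                         lod_cap = 300) {
  formula <- match.arg(formula)
  transform <- match.arg(transform)
  hotspot_tail <- match.arg(hotspot_tail)
  perm_mode <- match.arg(perm_mode)
  aligned <- align_strains(geno, expr)
  geno <- aligned$geno
  expr <- aligned$expr
  lods <- lod_matrix(geno, expr, cap = lod_cap)
  null <- permutation_null(geno, expr, n_iterations = n_perm, seed = seed,
                           mode = perm_mode, cap = lod_cap)
  pvals <- corrected_pvalues(lods, null)
  eqtls <- call_eqtls(pvals, alpha = alpha)
  hd <- hd_statistics(pvals, n_bins = n_bins, formula = formula,
                      transform = transform)
  tails <- hd_tails(hd, tail_fraction = tail_fraction)
  hotspot_traits <- if (hotspot_tail == "small") tails$small else tails$large
  assignment <- assign_traits(hotspot_traits, pvals)
  hnull <- hotspot_null(length(hotspot_traits), ncol(pvals),
                        n_iter = hotspot_null_iter, seed = seed + 1,
                        percentile = hotspot_percentile)
  hotspots <- call_hotspots(assignment, hnull, geno$map,
                            method = paste0("hd-", hotspot_tail, "-tail"))
  cis_trans <- classify_cis_trans(assignment, expr$trait_chrom, geno$map)
  n_match <- length(eqtls$traits)
  matched <- hd_tails(hd, n = max(n_match, 1))
  overlap <- list(
    small = tail_overlap(matched$small, eqtls$traits),
    large = tail_overlap(matched$large, eqtls$traits))
  structure(list(
    lods = lods, pvals = pvals, null = null, eqtls = eqtls, hd = hd,
    tails = tails, assignment = assignment, hotspots = hotspots,
    cis_trans = cis_trans, overlap = overlap,
    config = list(n_perm = n_perm, seed = seed, alpha = alpha,
                  n_bins = n_bins, formula = formula, transform = transform,
                  tail_fraction = tail_fraction,
                  hotspot_percentile = hotspot_percentile,
                  hotspot_null_iter = hotspot_null_iter,
                  hotspot_tail = hotspot_tail, perm_mode = perm_mode,
                  lod_cap = lod_cap)),
    class = "hd_run")
}

#' @export
print.hd_run <- function(x, ...) {
  cat("Hellinger-distance eQTL run\n")
  cat("  traits: ", nrow(x$pvals), ", markers: ", ncol(x$pvals),
      ", permutations: ", x$config$n_perm, "\n", sep = "")
  cat("  eQTL traits at alpha = ", x$config$alpha, ": ",
      length(x$eqtls$traits), "\n", sep = "")
  cat("  hd range: [", signif(min(x$hd$hd), 4), ", ",
      signif(max(x$hd$hd), 4), "]; ", length(x$tails$small),
      " traits per tail\n", sep = "")
  cat("  hotspot markers flagged: ", sum(x$hotspots$table$is_hotspot),
      " (threshold ", x$hotspots$threshold, ")\n", sep = "")
  ov <- x$overlap
  cat("  count-matched tail overlap with eQTL traits: small ",
      ov$small$count, " (", signif(100 * ov$small$fraction, 3),
      "%), large ", ov$large$count, " (",
      signif(100 * ov$large$fraction, 3), "%)\n", sep = "")
  invisible(x)
}

#' Write pipeline outputs as TSV files
#'
#' Writes `assoc.tsv` (long format: trait, marker, lod, p_corrected),
#' `hd.tsv`, `hotspots.tsv`, `cis_trans.tsv`, `overlap.tsv` and a
#' `run_metadata.txt` key-value sidecar recording the effective
#' configuration.
#'
#' @param run An `hd_run` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- data.frame(
    trait = rep(rownames(run$lods), times = ncol(run$lods)),
    marker = rep(colnames(run$lods), each = nrow(run$lods)),
    lod = signif(as.vector(run$lods), 6),
    p_corrected = signif(as.vector(run$pvals), 6),
    stringsAsFactors = FALSE)
  w(assoc, "assoc.tsv")
  hd <- run$hd
  hd$hd <- signif(hd$hd, 6)
  hd$best_p <- signif(hd$best_p, 6)
  w(hd, "hd.tsv")
  w(run$hotspots$table, "hotspots.tsv")
  w(run$cis_trans, "cis_trans.tsv")
  w(data.frame(tail = c("small", "large"),
               n = c(length(run$tails$small), length(run$tails$large)),
               overlap_count = c(run$overlap$small$count,
                                 run$overlap$large$count),
               overlap_fraction = signif(c(run$overlap$small$fraction,
                                           run$overlap$large$fraction), 6)),
    "overlap.tsv")
  cfg <- run$config
  meta <- c(sprintf("%s\t%s", names(cfg), unlist(cfg)),
            sprintf("hdeqtl_version\t%s",
                    as.character(utils::packageVersion("hdeqtl"))),
            sprintf("r_version\t%s", R.version.string))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}
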