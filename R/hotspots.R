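#' Assign traits to their most strongly associated marker
#'
#' Each trait is assigned to the locus with its smallest genome-wide
#' corrected p-value (ties broken by lowest marker index, consistent with
#' the `best_marker` field of [hd_statistics()]).
#'
#' @param traits Character vector of trait ids to assign.
#' @param pvals Corrected p-value matrix containing those traits as rows.
#' @return Named character vector: trait id -> marker id.
#' @export
assign_traits <- function(traits, pvals) {
  missing_t <- setdiff(traits, rownames(pvals))
  if (length(missing_t) > 0)
    stop("traits without p-value rows: ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  vapply(traits, function(tr) {
    row <- pvals[tr, ]
    colnames(pvals)[which.min(row)]
  }, character(1))
}

#' Null distribution for hotspot counts
#'
#' Simulates the null in which `n_traits` traits are assigned to the L
#' markers uniformly at random. Each iteration records the per-marker
#' assignment counts; the hotspot threshold is the `percentile` quantile of
#' either the pooled per-marker counts across iterations (default) or the
#' per-iteration maximum counts (`mode = "max"`).
#'
#' @param n_traits Number of traits assigned per iteration.
#' @param n_markers Number of markers L.
#' @param n_iter Number of iterations; >= 100 recommended.
#' @param seed Integer seed.
#' @param percentile Quantile of the null used as threshold; default 0.95.
#' @param mode `"pooled"` (default) or `"max"`.
#' @return Object of class `"hd_hotspot_null"`: list with `threshold`,
#'   `percentile`, `mode`, `n_traits`, `n_markers`, `n_iter`.
#' @export
hotspot_null <- function(n_traits, n_markers, n_iter = 1000, seed = 1,
                         percentile = 0.95, mode = c("pooled", "max")) {
  mode <- match.arg(mode)
  if (n_traits == 0) {
    return(structure(list(threshold = 0, percentile = percentile,
                          mode = mode, n_traits = 0L,
                          n_markers = as.integer(n_markers),
                          n_iter = as.integer(n_iter)),
                     class = "hd_hotspot_null"))
  }
  set.seed(seed)
  stat <- if (mode == "pooled") numeric(n_iter * n_markers)
          else numeric(n_iter)
  for (i in seq_len(n_iter)) {
    counts <- tabulate(sample.int(n_markers, n_traits, replace = TRUE),
                       nbins = n_markers)
    if (mode == "pooled")
      stat[((i - 1) * n_markers + 1):(i * n_markers)] <- counts
    else stat[i] <- max(counts)
  }
  # inverse-ECDF quantile keeps the threshold on the integer count scale
  thr <- unname(stats::quantile(stat, percentile, type = 1))
  structure(list(threshold = thr, percentile = percentile, mode = mode,
                 n_traits = as.integer(n_traits),
                 n_markers = as.integer(n_markers),
                 n_iter = as.integer(n_iter)),
            class = "hd_hotspot_null")
}

#' @export
print.hd_hotspot_null <- function(x, ...) {
  cat("Hotspot null (", x$mode, "): ", x$n_traits, " traits over ",
      x$n_markers, " markers, ", x$n_iter, " iterations; ",
      100 * x$percentile, "th percentile threshold = ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Call regulatory hotspots
#'
#' Counts the traits assigned to each marker and flags markers whose count
#' strictly exceeds the null threshold as hotspots. Optionally aggregates
#' runs of adjacent flagged markers into chromosome-level regions.
#'
#' @param assignment Named vector from [assign_traits()] (trait -> marker).
#' @param null An `hd_hotspot_null` object, or a bare numeric threshold.
#' @param map Marker map data frame (`marker`, `chrom`, `pos`) giving the
#'   full marker set and order.
#' @param method Free-text tag recorded in the table (e.g. "genome-wide",
#'   "hd-small-tail").
#' @return Object of class `"hd_hotspots"`: list with `table` (data frame:
#'   marker, chrom, pos, count, is_hotspot), `threshold`, `method`, and
#'   `regions` (data frame of merged runs of adjacent flagged markers).
#' @export
call_hotspots <- function(assignment, null, map, method = "hd-small-tail") {
  thr <- if (inherits(null, "hd_hotspot_null")) null$threshold else null
  counts <- table(factor(assignment, levels = map$marker))
  tab <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$is_hotspot <- tab$count > thr  # strictly exceeds
  regions <- do.call(rbind, lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$pos), ]
    r <- rle(d$is_hotspot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) == 0) return(NULL)
    data.frame(chrom = d$chrom[1],
               start_marker = d$marker[starts[keep]],
               end_marker = d$marker[ends[keep]],
               n_markers = r$lengths[keep],
               n_traits = vapply(keep, function(k)
                 sum(d$count[starts[k]:ends[k]]), integer(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start_marker = character(),
                          end_marker = character(), n_markers = integer(),
                          n_traits = integer(), stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  structure(list(table = tab, threshold = thr, method = method,
                 regions = regions),
            class = "hd_hotspots")
}

#' @export
print.hd_hotspots <- function(x, ...) {
  cat("Hotspot table (", x$method, "): ", sum(x$table$count),
      " assigned traits over ", nrow(x$table), " markers; threshold ",
      x$threshold, "; ", sum(x$table$is_hotspot), " hotspot marker(s) in ",
      nrow(x$regions), " region(s)\n", sep = "")
  invisible(x)
}

#' Classify traits as cis- or trans-acting
#'
#' A trait is cis if its most strongly associated marker lies on the same
#' chromosome as the trait's own gene, trans otherwise, and unknown if the
#' trait has no chromosome annotation.
#'
#' @param assignment Named vector from [assign_traits()].
#' @param trait_chrom Named character vector: trait id -> chromosome (may
#'   omit traits or hold `NA`).
#' @param map Marker map data frame.
#' @return Data frame: `trait`, `marker`, `marker_chrom`, `trait_chrom`,
#'   `class` in \{"cis", "trans", "unknown"\}.
#' @export
classify_cis_trans <- function(assignment, trait_chrom, map) {
  marker_chrom <- map$chrom[match(assignment, map$marker)]
  tc <- if (is.null(trait_chrom)) rep(NA_character_, length(assignment))
        else unname(trait_chrom[names(assignment)])
  cls <- ifelse(is.na(tc), "unknown",
                ifelse(tc == marker_chrom, "cis", "trans"))
  data.frame(trait = names(assignment), marker = unname(assignment),
             marker_chrom = marker_chrom, trait_chrom = tc, class = cls,
             stringsAsFactors = FALSE)
}

#' Overlap between an hd tail and the eQTL trait set
#'
#' @param tail Character vector of trait ids (an hd tail).
#' @param eqtl_traits Character vector of traits with at least one eQTL.
#' @return List with `count` (size of the intersection) and `fraction`
#'   (count / |tail|; `NA` with a warning if the tail is empty).
#' @export
tail_overlap <- function(tail, eqtl_traits) {
  count <- length(intersect(tail, eqtl_traits))
  if (length(tail) == 0) {
    warning("empty tail: overlap fraction undefined")
    return(list(count = 0L, fraction = NA_real_))
  }
  list(count = as.integer(count), fraction = count / length(tail))
}
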