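#' Construct a genotype set for a haploid biparental cross
#'
#' Bundles a markers x strains call matrix with its marker map. Calls are
#' coded 0/1 for the two parental alleles (haploid progeny); heterozygote or
#' other codes are rejected rather than recoded. Missing calls are allowed
#' and handled pairwise-complete downstream.
#'
#' @param calls Numeric matrix, markers in rows, strains in columns; values
#'   in \{0, 1, NA\}.
#' @param map Data frame with columns `marker`, `chrom`, `pos`; one row per
#'   row of `calls`, positions strictly increasing within a chromosome.
#' @param drop_uninformative Drop markers lacking both alleles among
#'   non-missing calls (default `FALSE`; they are always flagged).
#' @return An object of class `"hd_genotypes"`: a list with elements `calls`
#'   (rownames = marker ids, colnames = strain ids), `map`, and
#'   `uninformative` (character vector of flagged marker ids).
#' @export
hd_genotypes <- function(calls, map, drop_uninformative = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("marker", "chrom", "pos")
  if (!all(req %in% names(map)))
    stop("marker map must have columns 'marker', 'chrom', 'pos'")
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != nrow(calls))
    stop("marker map has ", nrow(map), " rows but call matrix has ",
         nrow(calls))
  if (anyDuplicated(map$marker))
    stop("duplicate marker ids: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (is.null(colnames(calls)))
    stop("call matrix must have strain ids as column names")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate strain ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  if (any(map$pos < 0) || anyNA(map$pos))
    stop("marker positions must be non-negative numbers")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  bad <- which(!(calls %in% c(0, 1)) & !is.na(calls), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid genotype code ", calls[bad[1, 1], bad[1, 2]],
         " at marker '", map$marker[bad[1, 1]],
         "', strain '", colnames(calls)[bad[1, 2]],
         "' (calls must be 0, 1 or NA)")
  }
  rownames(calls) <- map$marker
  n0 <- rowSums(calls == 0, na.rm = TRUE)
  n1 <- rowSums(calls == 1, na.rm = TRUE)
  uninf <- map$marker[n0 == 0 | n1 == 0]
  if (drop_uninformative && length(uninf) > 0) {
    keep <- !(map$marker %in% uninf)
    calls <- calls[keep, , drop = FALSE]
    map <- map[keep, , drop = FALSE]
    rownames(map) <- NULL
  }
  structure(list(calls = calls, map = map, uninformative = uninf),
            class = "hd_genotypes")
}

#' Construct an expression-trait set
#'
#' @param values Numeric matrix, traits in rows, strains in columns; all
#'   values finite.
#' @param trait_chrom Optional named character vector mapping trait ids to
#'   the chromosome the trait's gene lies on (used by cis/trans
#'   classification; `NA` entries are allowed).
#' @return An object of class `"hd_expression"`: a list with elements
#'   `values` and `trait_chrom`.
#' @export
hd_expression <- function(values, trait_chrom = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("expression matrix must have trait ids as row names")
  if (is.null(colnames(values)))
    stop("expression matrix must have strain ids as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate trait ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate strain ids")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (!is.null(trait_chrom)) {
    trait_chrom <- vapply(trait_chrom, as.character, character(1))
    if (is.null(names(trait_chrom)))
      stop("trait_chrom must be a named vector (names = trait ids)")
    trait_chrom <- trait_chrom[names(trait_chrom) %in% rownames(values)]
  }
  structure(list(values = values, trait_chrom = trait_chrom),
            class = "hd_expression")
}

#' @export
print.hd_genotypes <- function(x, ...) {
  cat("Haploid genotype set: ", nrow(x$calls), " markers x ",
      ncol(x$calls), " strains on ", length(unique(x$map$chrom)),
      " chromosome(s)\n", sep = "")
  if (length(x$uninformative) > 0)
    cat("  uninformative markers flagged: ", length(x$uninformative), "\n",
        sep = "")
  invisible(x)
}

#' @export
print.hd_expression <- function(x, ...) {
  cat("Expression traits: ", nrow(x$values), " traits x ", ncol(x$values),
      " strains", sep = "")
  if (!is.null(x$trait_chrom))
    cat("; ", sum(!is.na(x$trait_chrom)), " traits with chromosome annotation",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Read a genotype TSV
#'
#' Expects a tab-separated file with header `marker`, `chrom`, `pos` followed
#' by one column per strain; calls in \{0, 1, NA\}.
#'
#' @param path File path.
#' @param drop_uninformative Passed to [hd_genotypes()].
#' @return An `hd_genotypes` object.
#' @export
read_genotypes <- function(path, drop_uninformative = FALSE) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character", na.strings = "NA")
  req <- c("marker", "chrom", "pos")
  if (!all(req %in% names(d)[seq_len(3)]))
    stop("genotype file must start with columns 'marker', 'chrom', 'pos'")
  strain_cols <- setdiff(names(d), req)
  if (length(strain_cols) == 0) stop("genotype file has no strain columns")
  calls <- sapply(d[strain_cols], function(col) {
    v <- suppressWarnings(as.numeric(col))
    v[!is.na(col) & is.na(v)] <- -1  # non-numeric token -> invalid code
    v
  })
  calls <- matrix(calls, nrow = nrow(d),
                  dimnames = list(d$marker, strain_cols))
  hd_genotypes(calls,
               data.frame(marker = d$marker, chrom = d$chrom,
                          pos = as.numeric(d$pos),
                          stringsAsFactors = FALSE),
               drop_uninformative = drop_uninformative)
}

#' Read an expression TSV
#'
#' Expects columns `trait`, optionally `trait_chrom`, then one column per
#' strain.
#'
#' @param path File path.
#' @return An `hd_expression` object.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  if (names(d)[1] != "trait")
    stop("expression file must start with a 'trait' column")
  trait_chrom <- NULL
  strain_cols <- setdiff(names(d), "trait")
  if ("trait_chrom" %in% names(d)) {
    trait_chrom <- as.character(d$trait_chrom)
    names(trait_chrom) <- as.character(d$trait)
    strain_cols <- setdiff(strain_cols, "trait_chrom")
  }
  values <- as.matrix(d[strain_cols])
  rownames(values) <- as.character(d$trait)
  hd_expression(values, trait_chrom)
}

#' Write genotype / expression sets as TSV
#'
#' Floating point values are written at 6 significant digits; round trips of
#' 0/1 calls are exact.
#'
#' @param geno An `hd_genotypes` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  d <- data.frame(geno$map, geno$calls, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param expr An `hd_expression` object.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(trait = rownames(expr$values),
                  signif(expr$values, 6), check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!is.null(expr$trait_chrom)) {
    d <- cbind(d[1], trait_chrom = unname(
      expr$trait_chrom[rownames(expr$values)]), d[-1])
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict genotype and expression sets to their shared strains
#'
#' Both matrices are subset to the strains present in both, in the genotype
#' set's order. At least 3 shared strains are required.
#'
#' @param geno An `hd_genotypes` object.
#' @param expr An `hd_expression` object.
#' @return List with elements `geno` and `expr`, aligned.
#' @export
align_strains <- function(geno, expr) {
  shared <- intersect(colnames(geno$calls), colnames(expr$values))
  if (length(shared) < 3)
    stop("only ", length(shared),
         " shared strains between genotype and expression sets (need >= 3)")
  geno$calls <- geno$calls[, shared, drop = FALSE]
  expr$values <- expr$values[, shared, drop = FALSE]
  list(geno = geno, expr = expr)
}
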