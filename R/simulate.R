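#' Configuration for simulating a haploid biparental cross
#'
#' Defaults describe a small segregant panel of the kind used in haploid
#' cross eQTL studies: 5 chromosomes of 20 markers, 50 strains,
#' recombination fraction 0.1 between adjacent markers, 50 single-locus
#' traits with standardized effect size beta/sd = 2, 50 polygenic traits
#' each driven by 5 loci at beta/sd = 1 per locus, and 100 unregulated
#' (null) traits with unit Gaussian noise.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers per chromosome.
#' @param n_strains Number of haploid progeny strains.
#' @param recomb_fraction Recombination fraction per adjacent-marker
#'   interval, in (0, 0.5]; 0.5 means unlinked adjacent markers.
#' @param n_single,beta_single Count and per-locus effect of single-locus
#'   traits.
#' @param n_polygenic,k_loci,beta_polygenic Count, number of causal loci,
#'   and per-locus effect of polygenic traits.
#' @param n_null Count of null (noise-only) traits.
#' @param noise_sd Standard deviation of the Gaussian noise (effects are
#'   interpreted as beta/sd when this is 1).
#' @param hotspot_marker Optional marker id; `hotspot_n` single-locus traits
#'   are planted on this shared marker (in addition to `n_single`).
#' @param hotspot_n Number of traits targeting the hotspot marker.
#' @param missing_rate Fraction of genotype calls set missing (default 0),
#'   exercising the pairwise-complete association path.
#' @param cis_mode `"random"` assigns trait chromosomes uniformly;
#'   `"force-cis"` / `"force-trans"` place each regulated trait on / off the
#'   chromosome of its (first) causal marker.
#' @return Object of class `"hd_sim_config"` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 5, markers_per_chromosome = 20,
                       n_strains = 50, recomb_fraction = 0.1,
                       n_single = 50, beta_single = 2,
                       n_polygenic = 50, k_loci = 5, beta_polygenic = 1,
                       n_null = 100, noise_sd = 1,
                       hotspot_marker = NULL, hotspot_n = 0,
                       missing_rate = 0,
                       cis_mode = c("random", "force-cis", "force-trans")) {
  cis_mode <- match.arg(cis_mode)
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1, n_strains >= 3,
            recomb_fraction > 0, recomb_fraction <= 0.5,
            n_single >= 0, n_polygenic >= 0, n_null >= 0, k_loci >= 1,
            noise_sd > 0, hotspot_n >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "hd_sim_config")
}

#' Simulate genotypes of a haploid cross
#'
#' Each strain's chromosome is an independent two-state Markov chain along
#' the marker order: the first marker is Bernoulli(0.5), and each subsequent
#' marker switches parental origin with probability `recomb_fraction` (no
#' interference). Marker positions are laid out at 10 cM spacing per
#' chromosome (only the ordering matters downstream).
#'
#' @param cfg An `hd_sim_config`.
#' @param seed Integer seed.
#' @return An `hd_genotypes` object.
#' @export
simulate_genotypes <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "hd_sim_config"))
  set.seed(seed)
  L_chr <- cfg$markers_per_chromosome
  strains <- sprintf("strain%03d", seq_len(cfg$n_strains))
  chrom_calls <- vector("list", cfg$n_chromosomes)
  map_list <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    g <- matrix(0, nrow = L_chr, ncol = cfg$n_strains)
    g[1, ] <- stats::rbinom(cfg$n_strains, 1, 0.5)
    if (L_chr > 1) {
      flips <- matrix(stats::rbinom((L_chr - 1) * cfg$n_strains, 1,
                                    cfg$recomb_fraction),
                      nrow = L_chr - 1)
      for (i in 2:L_chr) g[i, ] <- (g[i - 1, ] + flips[i - 1, ]) %% 2
    }
    chrom_calls[[ch]] <- g
    map_list[[ch]] <- data.frame(
      marker = sprintf("chr%02d_m%03d", ch, seq_len(L_chr)),
      chrom = sprintf("chr%02d", ch),
      pos = 10 * seq_len(L_chr),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, chrom_calls)
  map <- do.call(rbind, map_list)
  colnames(calls) <- strains
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(calls)) < cfg$missing_rate
    calls[miss] <- NA
  }
  hd_genotypes(calls, map)
}

#' Simulate expression traits with planted genetic architectures
#'
#' Single-locus traits are beta * g_m + noise, polygenic traits are
#' sum_k beta_k * g_mk + noise, null traits pure noise; noise is iid
#' Gaussian. Causal markers are drawn without replacement per trait. Trait
#' chromosomes are assigned per `cfg$cis_mode`, enabling cis/trans ground
#' truth. If a hotspot is configured, `hotspot_n` extra single-locus traits
#' all target `hotspot_marker`.
#'
#' @param geno An `hd_genotypes` object from [simulate_genotypes()].
#' @param cfg The same `hd_sim_config`.
#' @param seed Integer seed.
#' @return List with `expr` (an `hd_expression`) and `truth` (data frame:
#'   trait, class, causal_markers (comma-separated), betas, trait_chrom).
#' @export
simulate_expression <- function(geno, cfg, seed = 1) {
  stopifnot(inherits(cfg, "hd_sim_config"))
  set.seed(seed)
  map <- geno$map
  L <- nrow(map)
  if (cfg$k_loci > L)
    stop("more causal loci requested (", cfg$k_loci, ") than markers (", L,
         ")")
  hotspot_n <- cfg$hotspot_n
  if (hotspot_n > 0) {
    if (is.null(cfg$hotspot_marker) ||
        !(cfg$hotspot_marker %in% map$marker))
      stop("hotspot_marker must name an existing marker")
  }
  n_traits <- cfg$n_single + hotspot_n + cfg$n_polygenic + cfg$n_null
  classes <- c(rep("single", cfg$n_single + hotspot_n),
               rep("polygenic", cfg$n_polygenic),
               rep("null", cfg$n_null))
  traits <- sprintf("trait%04d", seq_len(n_traits))
  G <- geno$calls
  G0 <- G
  G0[is.na(G0)] <- 0.5  # mean-impute for signal construction only
  values <- matrix(stats::rnorm(n_traits * ncol(G), sd = cfg$noise_sd),
                   nrow = n_traits,
                   dimnames = list(traits, colnames(G)))
  causal <- character(n_traits)
  betas <- character(n_traits)
  chroms <- sort(unique(map$chrom))
  trait_chrom <- character(n_traits)
  first_causal_chrom <- rep(NA_character_, n_traits)
  for (i in seq_len(n_traits)) {
    if (classes[i] == "null") {
      causal[i] <- ""
      betas[i] <- ""
    } else if (classes[i] == "single") {
      m <- if (i > cfg$n_single && i <= cfg$n_single + hotspot_n)
        cfg$hotspot_marker else map$marker[sample.int(L, 1)]
      b <- cfg$beta_single * cfg$noise_sd
      values[i, ] <- values[i, ] + b * G0[m, ]
      causal[i] <- m
      betas[i] <- format(b)
      first_causal_chrom[i] <- map$chrom[match(m, map$marker)]
    } else {
      ms <- map$marker[sample.int(L, cfg$k_loci)]
      b <- rep(cfg$beta_polygenic * cfg$noise_sd, cfg$k_loci)
      values[i, ] <- values[i, ] + colSums(b * G0[ms, , drop = FALSE])
      causal[i] <- paste(ms, collapse = ",")
      betas[i] <- paste(format(b), collapse = ",")
      first_causal_chrom[i] <- map$chrom[match(ms[1], map$marker)]
    }
    trait_chrom[i] <- switch(cfg$cis_mode,
      "random" = sample(chroms, 1),
      "force-cis" = if (is.na(first_causal_chrom[i])) sample(chroms, 1)
                    else first_causal_chrom[i],
      "force-trans" = if (is.na(first_causal_chrom[i])) sample(chroms, 1)
                      else sample(setdiff(chroms, first_causal_chrom[i]), 1))
  }
  names(trait_chrom) <- traits
  truth <- data.frame(trait = traits, class = classes,
                      causal_markers = causal, betas = betas,
                      trait_chrom = unname(trait_chrom),
                      stringsAsFactors = FALSE)
  list(expr = hd_expression(values, trait_chrom), truth = truth)
}

#' Simulate a complete cross (genotypes + expression + ground truth)
#'
#' @inheritParams simulate_expression
#' @param seed Integer seed; genotype and expression stages use derived
#'   sub-seeds so the pair is reproducible as a unit.
#' @return List with `geno`, `expr`, `truth`, `cfg`, `seed`.
#' @export
simulate_cross <- function(cfg = sim_config(), seed = 1) {
  geno <- simulate_genotypes(cfg, seed = seed)
  sim <- simulate_expression(geno, cfg, seed = seed + 1e6)
  list(geno = geno, expr = sim$expr, truth = sim$truth, cfg = cfg,
       seed = seed)
}
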