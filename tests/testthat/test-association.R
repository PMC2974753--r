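test_that("lod_score matches the residual-sum-of-squares regression oracle", {
  g <- c(0, 0, 1, 1)
  e <- c(1.0, 1.2, 3.0, 3.4)
  expect_equal(lod_score(g, e), lod_rss_oracle(g, e), tolerance = 1e-10)

  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    e <- rnorm(n) + g * rnorm(1)
    expect_equal(lod_score(g, e), lod_rss_oracle(g, e), tolerance = 1e-10)
  }
})

test_that("lod_score handles orthogonality, perfect separation, degeneracy", {
  # r = 0 exactly
  expect_equal(lod_score(c(0, 0, 1, 1), c(-1, 1, -1, 1)), 0)
  # r^2 = 1 capped at the configured ceiling
  expect_equal(lod_score(c(0, 0, 1, 1), c(1, 1, 2, 2)), 300)
  expect_equal(lod_score(c(0, 0, 1, 1), c(1, 1, 2, 2), cap = 50), 50)
  # undefined cases propagate as missing, never silently zero
  expect_true(is.na(lod_score(c(1, 1, 1, 1), c(1, 2, 3, 4))))
  expect_true(is.na(lod_score(c(0, 1, 0, 1), c(2, 2, 2, 2))))
  expect_true(is.na(lod_score(c(0, 1, NA, NA), c(1, 2, 3, 4))))
})

test_that("lod_matrix equals elementwise lod_score, including missing calls", {
  set.seed(7)
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 8,
                    n_strains = 12, n_single = 2, n_polygenic = 1,
                    k_loci = 2, n_null = 2, missing_rate = 0.15)
  sim <- simulate_cross(cfg, seed = 7)
  lods <- lod_matrix(sim$geno, sim$expr)
  for (t in rownames(lods)) {
    for (m in colnames(lods)) {
      expect_equal(lods[t, m],
                   lod_score(sim$geno$calls[m, ], sim$expr$values[t, ]))
    }
  }
})

test_that("a trait tracking one marker attains its row maximum there", {
  set.seed(11)
  sim <- simulate_cross(sim_config(n_single = 0, n_polygenic = 0,
                                   n_null = 5), seed = 11)
  target <- "chr02_m005"
  vals <- rbind(sim$expr$values,
                tracker = sim$geno$calls[target, ] + rnorm(50, sd = 1e-3))
  expr <- hd_expression(vals)
  lods <- lod_matrix(sim$geno, expr)
  expect_identical(names(which.max(lods["tracker", ])), target)
})

test_that("null-trait row maxima are distributed as the permutation null", {
  set.seed(13)
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 10,
                    n_strains = 30, n_single = 0, n_polygenic = 0,
                    n_null = 200)
  sim <- simulate_cross(cfg, seed = 13)
  al <- align_strains(sim$geno, sim$expr)
  lods <- lod_matrix(al$geno, al$expr)
  obs_max <- apply(lods, 1, max, na.rm = TRUE)
  # single-trait permutation null so maxima are comparable per trait
  one <- hd_expression(al$expr$values[1, , drop = FALSE])
  null <- permutation_null(al$geno, one, n_iterations = 400, seed = 14)
  ks <- suppressWarnings(stats::ks.test(obs_max, null$maxima))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation_null is reproducible and honors its test hook", {
  set.seed(3)
  sim <- simulate_cross(sim_config(n_chromosomes = 1,
                                   markers_per_chromosome = 5,
                                   n_strains = 10, n_single = 1,
                                   n_polygenic = 0, n_null = 2), seed = 3)
  one <- permutation_null(sim$geno, sim$expr, n_iterations = 1, seed = 5)
  expect_length(one$maxima, 1)
  expect_error(permutation_null(sim$geno, sim$expr, n_iterations = 0),
               "n_iterations")

  # identity permutation: recorded maximum equals the observed maximum
  ident <- permutation_null(sim$geno, sim$expr, n_iterations = 2, seed = 5,
                            perm_fun = function(n) seq_len(n))
  expect_equal(ident$maxima,
               rep(max(lod_matrix(sim$geno, sim$expr), na.rm = TRUE), 2))

  a <- permutation_null(sim$geno, sim$expr, n_iterations = 20, seed = 9)
  b <- permutation_null(sim$geno, sim$expr, n_iterations = 20, seed = 9)
  expect_identical(a, b)
  pt <- permutation_null(sim$geno, sim$expr, n_iterations = 5, seed = 9,
                         mode = "per-trait")
  expect_length(pt$maxima, 5)
})

test_that("corrected p-values follow the add-one counting formula", {
  null <- structure(list(maxima = c(1, 2, 3), n_iterations = 3L, seed = 1L,
                         mode = "shared"), class = "hd_null")
  lods <- matrix(c(2.5, 0, 3.5, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), c("m1", "m2")))
  p <- corrected_pvalues(lods, null)
  expect_equal(p["t1", "m1"], (1 + 1) / 4)   # one null maximum >= 2.5
  expect_equal(p["t1", "m2"], 1)             # every null maximum >= 0
  expect_equal(p["t2", "m1"], 1 / 4)         # above every null maximum
  expect_equal(p["t2", "m2"], 1)             # ties count (1 >= 1)

  big <- structure(list(maxima = runif(999, 0, 3), n_iterations = 999L,
                        seed = 1L, mode = "shared"), class = "hd_null")
  expect_equal(corrected_pvalues(matrix(5), big)[1, 1], 0.001)
})

test_that("corrected p is a non-increasing step function of LOD", {
  set.seed(17)
  null <- structure(list(maxima = rexp(50), n_iterations = 50L, seed = 1L,
                         mode = "shared"), class = "hd_null")
  lods <- matrix(sort(runif(200, 0, 5)), nrow = 1)
  p <- corrected_pvalues(lods, null)
  expect_true(all(diff(p[1, ]) <= 0))
  expect_true(all(p >= 1 / 51 & p <= 1))
  expect_lte(length(unique(as.vector(p))), 51)
})

test_that("call_eqtls thresholds pairs and collects trait sets", {
  p <- matrix(1, 2, 2, dimnames = list(c("t1", "t2"), c("m1", "m2")))
  empty <- call_eqtls(p, alpha = 0.05)
  expect_equal(nrow(empty$pairs), 0)
  expect_length(empty$traits, 0)

  p["t2", "m1"] <- 0.01
  one <- call_eqtls(p, alpha = 0.05)
  expect_equal(one$pairs$trait, "t2")
  expect_equal(one$pairs$marker, "m1")
  expect_identical(one$traits, "t2")
  expect_error(call_eqtls(p, alpha = 1.5), "alpha")
})

test_that("a strong planted eQTL is recovered at a linked marker", {
  # single-locus trait explaining ~60% of variance, 50 strains, 100 markers
  beta <- sqrt(6)  # beta^2 * Var(g) / (beta^2 * Var(g) + 1) = 0.6
  hits <- vapply(1:50, function(rep) {
    cfg <- sim_config(n_single = 1, beta_single = beta, n_polygenic = 0,
                      n_null = 0)
    sim <- simulate_cross(cfg, seed = 600 + rep)
    st <- map_and_correct(sim, n_perm = 500, seed = 1600 + rep)
    eq <- call_eqtls(st$pvals, alpha = 0.05)
    if (length(eq$traits) == 0) return(FALSE)
    called <- assign_traits(eq$traits, st$pvals)[1]
    planted <- sim$truth$causal_markers[1]
    map <- sim$geno$map
    ic <- match(called, map$marker)
    ip <- match(planted, map$marker)
    map$chrom[ic] == map$chrom[ip] && abs(ic - ip) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
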