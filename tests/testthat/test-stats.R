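mk_cov <- function(values, ids = NULL, samples = NULL, stage = "raw") {
  if (is.null(ids)) ids <- paste0("pt", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  coverage_matrix(`dimnames<-`(values, list(ids, samples)), stage = stage)
}

test_that("alpha diversity: closed forms and the direct summation", {
  m <- mk_cov(matrix(c(3, 0, 0, 2, 2, 2, 1, 2, 3, 0, 0, 0), 3, 4))
  ad <- alpha_diversity(m)
  expect_equal(ad$richness, c(1L, 3L, 3L, 0L))
  expect_equal(ad$shannon[1], 0)
  expect_equal(ad$shannon[2], log(3))
  p <- c(1, 2, 3) / 6
  expect_equal(ad$shannon[3], -sum(p * log(p)))
  expect_true(is.na(ad$shannon[4]))
})

test_that("Kruskal-Wallis matches the rank closed form and degenerates to 0", {
  expect_equal(kruskal_wallis(rep(5, 9), rep(1:3, 3)),
               list(statistic = 0, df = 2L, p = 1))
  # fully separated two groups of 5: ranks 1-5 vs 6-10
  kw <- kruskal_wallis(c(1:5, 101:105), rep(c("a", "b"), each = 5))
  H <- 12 / (10 * 11) * (5 * (3 - 5.5)^2 + 5 * (8 - 5.5)^2)
  expect_equal(kw$statistic, H)
  # tie-corrected fixture against kruskal.test directly is redundant;
  # check the tie-corrected statistic against the textbook formula instead
  x <- c(1, 2, 2, 3, 5, 5, 5, 7, 8)
  g <- rep(1:3, each = 3)
  r <- oracle_avg_rank(x)
  n <- length(x)
  Rbar <- tapply(r, g, mean)
  Hraw <- 12 / (n * (n + 1)) * sum(3 * (Rbar - (n + 1) / 2)^2)
  ties <- table(x)
  Hcorr <- Hraw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(x, g)$statistic, Hcorr)
})

test_that("Bray-Curtis handles identity, disjoint support and the hand case", {
  m <- mk_cov(matrix(c(1, 2, 0, 0, 2, 4, 1, 2, 0, 2, 0, 3), 3, 4))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s4"], oracle_bray(c(1, 2, 0), c(2, 0, 3)))
  expect_equal(d["s1", "s2"], 5 / 9)
  expect_equal(bray_curtis(mk_cov(cbind(c(1, 2), c(1, 2))))["s1", "s2"], 0)
  expect_equal(bray_curtis(mk_cov(cbind(c(1, 0), c(0, 2))))["s1", "s2"], 1)
  # two empty samples: flagged zero, not NaN
  e <- bray_curtis(mk_cov(cbind(c(0, 0), c(0, 0), c(1, 1))))
  expect_equal(e["s1", "s2"], 0)
  expect_equal(attr(e, "empty_pairs"), 1)
})

test_that("Bray-Curtis equals the brute-force formula on random matrices", {
  set.seed(5)
  for (rep in 1:10) {
    m <- mk_cov(matrix(rexp(7 * 5) * rbinom(35, 1, 0.7), 7, 5))
    d <- bray_curtis(m)
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(d[i, j], oracle_bray(unclass(m)[, i], unclass(m)[, j]),
                   tolerance = 1e-12)
  }
})

test_that("haversine distances: zero, quarter meridian, symmetry", {
  st <- validate_sample_table(data.frame(
    sample_id = c("a", "b", "c"), habitat = "mine", read_count = 1e7,
    LON = c(0, 0, 30), LAT = c(0, 90, 10)))
  d <- haversine_matrix(st)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], pi / 2 * 6371.0088, tolerance = 1e-6)
  expect_equal(d["a", "c"], d["c", "a"])
})

test_that("PERMANOVA pseudo-F and exhaustive p match full enumeration", {
  set.seed(6)
  for (rep in 1:5) {
    x <- matrix(rnorm(12), 6, 2)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
    g <- rep(c("a", "b"), each = 3)
    got <- permanova(d, g, exhaustive = TRUE, seed = 1)
    want <- oracle_permanova_exhaustive(d, g)
    expect_equal(got$f, want$f, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("PERMANOVA attains the permutation floor on separated clusters", {
  set.seed(7)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 50), 10))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(d, g, n_perm = 999, seed = 3)
  expect_equal(pm$p, 1 / 1000)
  expect_error(permanova(d[1:3, 1:3], c("a", "a", "b")), "at least 2 samples")
})

test_that("Mantel recovers identity and the partial test removes a confounder", {
  set.seed(8)
  x <- matrix(rnorm(30), 15, 2)
  dA <- as.matrix(dist(x)); dimnames(dA) <- list(paste0("s", 1:15), paste0("s", 1:15))
  mt <- mantel_test(distance_matrix_for_test(dA), distance_matrix_for_test(dA),
                    n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
  # planted confounder: dB == dC, dA independent; r(A,B) may stray but
  # r(A,B|C) collapses towards zero
  z <- matrix(rnorm(30), 15, 2)
  dB <- as.matrix(dist(z)); dimnames(dB) <- dimnames(dA)
  pm <- partial_mantel(distance_matrix_for_test(dA), distance_matrix_for_test(dB),
                       distance_matrix_for_test(dB), n_perm = 99, seed = 1)
  expect_lt(abs(pm$r), 0.05)
  # zero-variance triangle flagged
  z0 <- matrix(0, 15, 15); dimnames(z0) <- dimnames(dA)
  expect_true(is.na(mantel_test(distance_matrix_for_test(dA),
                                distance_matrix_for_test(z0))$r))
})

test_that("distance-decay slope matches closed-form least squares on 4 points", {
  geo <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  geo[upper.tri(geo)] <- c(9, 99, 999, 99, 999, 999)
  geo <- geo + t(geo)
  comm <- matrix(0, 4, 4, dimnames = dimnames(geo))
  comm[upper.tri(comm)] <- c(0.2, 0.4, 0.6, 0.4, 0.6, 0.6)
  comm <- comm + t(comm)
  dd <- distance_decay(distance_matrix_for_test(comm, "bray-curtis"),
                       distance_matrix_for_test(geo, "haversine-km"),
                       n_perm = 23, seed = 1)
  x <- log10(comm_pairs <- geo[lower.tri(geo)] + 1)
  y <- comm[lower.tri(comm)]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(dd$slope, b, tolerance = 1e-12)
  zero <- matrix(0, 4, 4, dimnames = dimnames(geo))
  expect_error(distance_decay(distance_matrix_for_test(comm, "bray-curtis"),
                              distance_matrix_for_test(zero, "haversine-km")),
               "co-located")
})

test_that("variation partitioning fractions are exhaustive and confounding-aware", {
  set.seed(9)
  n <- 60
  m <- mk_cov(matrix(rexp(5 * n), 5, n))
  b1 <- data.frame(MAP = rnorm(n))
  b2 <- data.frame(LON = rnorm(n), LAT = rnorm(n))
  b3 <- data.frame(a = rnorm(n), b = rnorm(n))
  # duplicated block is intentional; vegan warns about the collinearity
  vp <- suppressWarnings(
    variation_partition(m, list(climatic = b1, geographical = b2,
                                physicochemical = b3, eukaryotic = b1),
                        pca_blocks = character(0)))
  expect_equal(sum(vp$individual), 1, tolerance = 1e-9)
  # identical blocks 1 and 4: their uniques vanish, shared carries the signal
  expect_lt(abs(vp$individual[["[a] = X1 | X2+X3+X4"]]), 0.02)
  expect_lt(abs(vp$individual[["[d] = X4 | X1+X2+X3"]]), 0.02)
  # pure-noise predictors: adjusted block totals near zero
  vp0 <- variation_partition(m, list(climatic = data.frame(x = rnorm(n)),
                                     geographical = data.frame(y = rnorm(n)),
                                     physicochemical = data.frame(z = rnorm(n)),
                                     eukaryotic = data.frame(w = rnorm(n))),
                             pca_blocks = character(0))
  expect_true(all(abs(vp0$block_totals) < 0.1))
})
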