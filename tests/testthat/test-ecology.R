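mk_cov <- function(values, ids = NULL, samples = NULL, stage = "raw") {
  if (is.null(ids)) ids <- paste0("pt", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  coverage_matrix(`dimnames<-`(values, list(ids, samples)), stage = stage)
}

test_that("depth normalization follows the divide-then-rescale formula", {
  m <- mk_cov(matrix(c(4, 0, 2, 6), 2, 2))
  reads <- c(s1 = 50e6, s2 = 150e6) # mean 100e6
  norm <- normalize_coverage(m, reads)
  expect_equal(unclass(norm)[1, 1], 4 / 50e6 * 100e6) # = 8
  expect_equal(unclass(norm)[, 2], c(pt1 = 2 / 1.5, pt2 = 4))
  # a sample at exactly the mean depth is unchanged
  norm2 <- normalize_coverage(m, c(s1 = 1e8, s2 = 1e8))
  expect_equal(unclass(norm2), unclass(m), ignore_attr = TRUE)
  expect_error(normalize_coverage(m, c(s1 = 50e6)), "missing for sample")
})

test_that("relative abundance columns sum to 100, empty samples flagged", {
  m <- mk_cov(matrix(c(2, 2, 0, 0), 2, 2), stage = "normalized")
  rel <- relative_abundance(m)
  expect_equal(unclass(rel)[, 1], c(pt1 = 50, pt2 = 50))
  expect_equal(unclass(rel)[, 2], c(pt1 = 0, pt2 = 0))
  expect_identical(attr(rel, "empty_samples"), "s2")
  set.seed(1)
  r <- mk_cov(matrix(rexp(60), 10, 6), stage = "normalized")
  expect_true(all(abs(colSums(relative_abundance(r)) - 100) < 1e-9))
  expect_error(relative_abundance(mk_cov(matrix(1, 1, 1))), "normalized")
})

five_hab_samples <- function(n_per = 4) {
  validate_sample_table(data.frame(
    sample_id = paste0("s", seq_len(5 * n_per)),
    habitat = rep(habitat_levels(), each = n_per),
    read_count = 1e7, stringsAsFactors = FALSE))
}

test_that("occurrence frequency is the percent of habitat samples with a detection", {
  st <- five_hab_samples(4)
  v <- matrix(0, 2, 20, dimnames = list(c("pt1", "pt2"), st$sample_id))
  v[1, st$habitat == "mine"][1:3] <- 5  # 3 of 4 mine samples
  v[2, st$habitat == "forest"] <- 1     # all forest samples
  m <- coverage_matrix(v)
  f <- occurrence_frequency(m, st)
  expect_equal(f["pt1", "mine"], 75)
  expect_equal(f["pt1", "forest"], 0)
  expect_equal(f["pt2", "forest"], 100)
})

test_that("occupancy summary tallies unique and shared phylotypes exactly", {
  st <- five_hab_samples(2)
  v <- matrix(0, 4, 10, dimnames = list(paste0("pt", 1:4), st$sample_id))
  v[1, st$habitat == "mine"] <- 1            # mine-unique
  v[2, ] <- 1                                # everywhere
  v[3, st$habitat %in% c("forest", "gobi")] <- 1
  v[4, st$sample_id == st$sample_id[st$habitat == "farmland"][1]] <- 2
  m <- coverage_matrix(v)
  occ <- occupancy_summary(m, st)
  expect_equal(unname(occ$habitats_per_phylotype), c(1L, 5L, 2L, 1L))
  expect_identical(occ$unique_by_habitat$mine, "pt1")
  expect_identical(occ$unique_by_habitat$farmland, "pt4")
  expect_identical(occ$shared_all, "pt2")
  expect_equal(sum(occ$count_by_n_habitats), occ$n_phylotypes)
  # invariance to sample order
  p <- sample(ncol(m))
  occ2 <- occupancy_summary(coverage_matrix(unclass(m)[, p]), st[p, ])
  expect_identical(occ2$habitats_per_phylotype, occ$habitats_per_phylotype)
})

sev_fixture <- function() {
  validate_sample_table(data.frame(
    sample_id = c("s1", "s2", "s3"),
    habitat = c("mine", "mine", "forest"),
    read_count = 1e7,
    MAP = c(10, 20, 30), pH = c(7, 7, 7), stringsAsFactors = FALSE))
}

test_that("SEV and environmental range follow the four standardization steps", {
  st <- sev_fixture()
  expect_message(sev <- sample_sev(st), "constant")
  expect_equal(unname(sev), c(0, 0.5, 1)) # pH constant -> dropped
  m <- mk_cov(matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3,
                     byrow = TRUE), samples = c("s1", "s2", "s3"))
  # pt1 occupies {s1, s3}: range 1; pt2 occupies {s2}: range 0
  suppressMessages(ert <- environmental_range(m, st))
  expect_equal(ert$raw_range, c(1, 0, 0))
  expect_equal(ert$std_range, c(1, 0, 0))
  expect_equal(ert$n_samples, c(2L, 1L, 1L))
  # identical occupied sets give identical ranges (pt3 == a copy of pt1 support)
  m2 <- mk_cov(rbind(unclass(m), pt4 = c(2, 0, 9)), samples = c("s1", "s2", "s3"))
  suppressMessages(ert2 <- environmental_range(m2, st))
  expect_equal(ert2$raw_range[4], ert2$raw_range[1])
})

test_that("environmental range is invariant to positive affine rescaling of variables", {
  sim <- toy_survey(seed = 14)
  e1 <- environmental_range(sim$coverage, sim$samples)
  st2 <- sim$samples
  st2$MAP <- 3.7 * st2$MAP + 100
  st2$pH <- 2 * st2$pH + 3
  e2 <- environmental_range(sim$coverage, st2)
  expect_equal(e2$raw_range, e1$raw_range, tolerance = 1e-12)
})

test_that("adding an occupied sample never shrinks the raw range", {
  sim <- toy_survey(seed = 15)
  sev <- sample_sev(sim$samples)
  set.seed(1)
  for (i in sample(nrow(sim$coverage), 10)) {
    pres <- unclass(sim$coverage)[i, ] > 0
    if (all(pres)) next
    r0 <- max(sev[pres]) - min(sev[pres])
    extra <- sample(which(!pres), 1)
    pres[extra] <- TRUE
    expect_gte(max(sev[pres]) - min(sev[pres]), r0)
  }
})

test_that("abundance-occupancy correlations need three phylotypes and flag constants", {
  sim <- toy_survey(seed = 16)
  ert <- environmental_range(sim$coverage, sim$samples)
  expect_error(abundance_occupancy_stats(ert[1:2, ]), "at least 3")
  stats <- abundance_occupancy_stats(ert)
  expect_identical(nrow(stats), 5L)
  expect_true(all(is.finite(stats$r)))
  # constant x -> undefined, not zero
  ert_const <- ert
  ert_const$n_habitats <- 2L
  s2 <- abundance_occupancy_stats(ert_const)
  expect_true(is.na(s2$r[1]))
  expect_match(s2$note[1], "constant")
})

test_that("rarefaction closed forms: saturated and disjoint communities", {
  full <- mk_cov(matrix(1, 5, 6))
  rc <- rarefaction_curve(full, method = "exact")
  expect_equal(rc$curve$richness, rep(5, 6))
  expect_equal(rc$terminal_slope_pct, 0)
  disj <- mk_cov(diag(6) * 2)
  rc2 <- rarefaction_curve(disj, method = "exact")
  expect_equal(rc2$curve$richness, 1:6)
  expect_equal(rc2$terminal_slope_pct, 100 / 6)
})

test_that("exact rarefaction equals enumeration over all orderings", {
  set.seed(20)
  v <- matrix(rbinom(8 * 6, 1, 0.4) * rexp(48), 8, 6)
  m <- mk_cov(v)
  rc <- rarefaction_curve(m, method = "exact")
  expect_equal(rc$curve$richness, oracle_rarefaction(unclass(m) > 0),
               tolerance = 1e-12)
  # random method converges to the exact mean
  rr <- rarefaction_curve(m, n_perm = 2000, seed = 1, method = "random")
  expect_equal(rr$curve$richness, rc$curve$richness, tolerance = 0.1)
})

test_that("redundancy filter removes collinear variables, keeps independent ones", {
  set.seed(30)
  n <- 40
  base <- data.frame(sample_id = paste0("s", 1:n), habitat = "mine",
                     read_count = 1e7)
  base$pH <- rnorm(n)
  base$MAP <- rnorm(n)
  base$TC <- rnorm(n)
  base$TN <- base$TC            # rho^2 = 1
  st <- validate_sample_table(base)
  kept <- env_redundancy_filter(st)
  expect_length(attr(kept, "removed"), 1)
  expect_true(xor("TC" %in% kept, "TN" %in% kept))

  base$TN <- rnorm(n)           # now all independent
  kept2 <- env_redundancy_filter(validate_sample_table(base))
  expect_setequal(kept2, c("pH", "MAP", "TC", "TN"))
})

test_that("redundancy filter resolves a collinear triple minimally", {
  set.seed(31)
  n <- 60
  x <- rnorm(n)
  df <- data.frame(sample_id = paste0("s", 1:n), habitat = "forest",
                   read_count = 1e7,
                   pH = x + rnorm(n, 0, 0.1),
                   MAP = x + rnorm(n, 0, 0.1),
                   TC = x + rnorm(n, 0, 0.1),
                   TN = rnorm(n), TP = rnorm(n))
  st <- validate_sample_table(df)
  kept <- env_redundancy_filter(st)
  # brute force: the largest subset with no pair above the threshold
  env <- sample_env(st)
  rho2 <- cor(env, method = "spearman")^2
  vars <- colnames(env)
  ok <- function(s) all(rho2[s, s][upper.tri(diag(length(s)))] <= 0.7)
  best <- 0
  for (k in rev(seq_along(vars))) {
    combs <- utils::combn(vars, k, simplify = FALSE)
    if (any(vapply(combs, ok, TRUE))) { best <- k; break }
  }
  expect_length(kept, best)
  expect_true(ok(kept))
})
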