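#' Per-sample alpha diversity
#'
#' Richness is the number of phylotypes detected in a sample; the Shannon
#' index is computed on the sample's relative abundances (natural log).
#' Empty samples get richness 0 and an undefined (NA) Shannon index.
#'
#' @param m A `coverage_matrix`.
#' @param presence_min Detection threshold for richness.
#' @return Data frame: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(m, presence_min = 0) {
  x <- t(unclass(m))
  rich <- rowSums(x > presence_min)
  sh <- vegan::diversity(x, index = "shannon")
  sh[rowSums(x) == 0] <- NA_real_
  data.frame(sample_id = colnames(m), richness = as.integer(rich),
             shannon = unname(sh), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' g - 1 degrees of freedom. When every observation is identical the
#' statistic is 0 and p is 1 (the tie correction would otherwise be
#' degenerate).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (>= 2 groups, each >= 1 value).
#' @return List with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

# symmetric distance container with a metric tag
distance_matrix <- function(d, metric) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  structure(d, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d samples\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`. A pair of empty
#' samples is undefined under the formula and is reported as 0, flagged
#' in the `empty_pairs` attribute.
#'
#' @param m A `coverage_matrix` (samples in columns).
#' @return A `distance_matrix` with metric `bray-curtis`.
#' @export
bray_curtis <- function(m) {
  x <- t(unclass(m))
  empty <- rowSums(x) == 0
  # vegan warns about empty samples; their pairs are handled below
  d <- as.matrix(if (any(empty)) suppressWarnings(vegan::vegdist(x, method = "bray"))
                 else vegan::vegdist(x, method = "bray"))
  n_empty_pairs <- sum(empty) * (sum(empty) - 1) / 2
  if (n_empty_pairs > 0) d[empty, empty] <- 0
  diag(d) <- 0
  out <- distance_matrix(d, "bray-curtis")
  if (n_empty_pairs > 0) attr(out, "empty_pairs") <- n_empty_pairs
  out
}

#' Great-circle (haversine) distances between samples, in km
#'
#' Uses the mean Earth radius 6371.0088 km.
#'
#' @param samples A `sample_table` with `LON`/`LAT` columns.
#' @return A `distance_matrix` with metric `haversine-km`.
#' @export
haversine_matrix <- function(samples) {
  if (!all(c("LON", "LAT") %in% colnames(samples)))
    stop("sample table needs LON and LAT")
  xy <- cbind(samples$LON, samples$LAT)
  if (anyNA(xy)) stop("missing coordinates")
  d <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  distance_matrix(d, "haversine-km")
}

#' Euclidean distance between samples over environmental variables
#'
#' Variables are scaled to unit variance before the distance is taken.
#'
#' @param samples A `sample_table`.
#' @param variables Variables to use.
#' @param scale Standardize variables first (default TRUE).
#' @return A `distance_matrix` with metric `euclidean`.
#' @export
euclidean_matrix <- function(samples, variables = NULL, scale = TRUE) {
  env <- sample_env(samples, variables)
  if (scale) env <- base::scale(env)
  d <- as.matrix(stats::dist(env))
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  distance_matrix(d, "euclidean")
}

# all permutations of 1..n (n! rows); used for exhaustive permutation tests
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutations limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F
#' via the Gower-centred inner-product matrix, as implemented in
#' `vegan::adonis2`), with the permutation p-value convention
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under free permutation
#' of sample labels. With `exhaustive = TRUE` all label permutations are
#' enumerated instead (small n only).
#'
#' @param d A `distance_matrix` (or `dist`).
#' @param groups Group labels, >= 2 groups of >= 2 samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all permutations (n <= 8).
#' @return List with `f`, `r2`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  dd <- stats::as.dist(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  dat <- data.frame(g = groups)
  if (exhaustive) {
    perms <- all_permutations(attr(dd, "Size"))
    perms <- perms[rowSums(perms != rep(seq_len(ncol(perms)),
                                        each = nrow(perms))) > 0, , drop = FALSE]
    set.seed(seed)
    fit <- vegan::adonis2(dd ~ g, data = dat, permutations = perms)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    fit <- vegan::adonis2(dd ~ g, data = dat, permutations = n_perm)
    n_used <- n_perm
  }
  list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       n_perm = n_used, seed = seed)
}

# correlation over the lower triangle of two aligned distance matrices
check_aligned <- function(...) {
  mats <- list(...)
  ids <- lapply(mats, function(m) rownames(as.matrix(m)))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]])))
    stop("distance matrices must share sample ids in the same order")
}

#' Mantel test between two distance matrices
#'
#' Correlation over the lower triangles with significance from jointly
#' permuting rows and columns of the first matrix;
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param dA,dB `distance_matrix` objects over the same samples.
#' @param method Correlation method (`"pearson"` or `"spearman"`).
#' @param n_perm Permutations (default 999).
#' @param seed RNG seed.
#' @return List with `r`, `p`, `n_perm`, `seed` (`r = NA` flagged when a
#'   triangle has zero variance).
#' @export
mantel_test <- function(dA, dB, method = "pearson", n_perm = 999, seed = 1L) {
  check_aligned(dA, dB)
  a <- stats::as.dist(as.matrix(dA))
  b <- stats::as.dist(as.matrix(dB))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, seed = seed,
                note = "undefined: zero-variance distances"))
  set.seed(seed)
  fit <- vegan::mantel(a, b, method = method, permutations = n_perm)
  list(r = fit$statistic, p = fit$signif, n_perm = n_perm, seed = seed)
}

#' Partial Mantel test
#'
#' First-order partial correlation of the triangles of `dA` and `dB`
#' given `dC`, with significance by permuting the first matrix
#' (simple Mantel permutation of the residual association).
#'
#' @param dA,dB,dC `distance_matrix` objects over the same samples.
#' @param method Correlation method.
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return List with `r`, `p`, `n_perm`, `seed`.
#' @export
partial_mantel <- function(dA, dB, dC, method = "pearson", n_perm = 999,
                           seed = 1L) {
  check_aligned(dA, dB, dC)
  a <- stats::as.dist(as.matrix(dA))
  b <- stats::as.dist(as.matrix(dB))
  cc <- stats::as.dist(as.matrix(dC))
  if (stats::sd(a) == 0 || stats::sd(b) == 0 || stats::sd(cc) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, seed = seed,
                note = "undefined: zero-variance distances"))
  set.seed(seed)
  fit <- vegan::mantel.partial(a, b, cc, method = method,
                               permutations = n_perm)
  list(r = fit$statistic, p = fit$signif, n_perm = n_perm, seed = seed)
}

#' Distance-decay of community similarity
#'
#' Least-squares fit of community dissimilarity against
#' `log10(geographic km + 1)` over sample pairs; the significance comes
#' from a Mantel permutation test on the two matrices, not from the
#' naive pair-level regression p (pairs are not independent).
#'
#' @param d_comm Community `distance_matrix` (e.g. Bray-Curtis).
#' @param d_geo Geographic `distance_matrix` in km.
#' @param n_perm Mantel permutations.
#' @param seed RNG seed.
#' @return List with `slope`, `intercept`, `r`, `p_mantel`, `n_pairs`.
#' @export
distance_decay <- function(d_comm, d_geo, n_perm = 999, seed = 1L) {
  check_aligned(d_comm, d_geo)
  n <- nrow(as.matrix(d_comm))
  if (n < 4) stop("need at least 4 samples")
  g <- stats::as.dist(as.matrix(d_geo))
  if (all(g == 0)) stop("all samples co-located")
  x <- log10(as.vector(g) + 1)
  y <- as.vector(stats::as.dist(as.matrix(d_comm)))
  fit <- stats::lm(y ~ x)
  lg <- distance_matrix(log10(as.matrix(d_geo) + 1), "log10-km")
  mt <- mantel_test(d_comm, lg, n_perm = n_perm, seed = seed)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), p_mantel = mt$p, n_pairs = length(x))
}

# reduce a predictor block to principal components keeping >= var_keep
pca_reduce <- function(x, var_keep = 0.8) {
  x <- as.matrix(x)
  sdv <- apply(x, 2, stats::sd)
  x <- x[, sdv > 0, drop = FALSE]
  if (ncol(x) == 0) stop("predictor block has no varying columns")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- which(cum >= var_keep)[1]
  p$x[, seq_len(k), drop = FALSE]
}

#' Variation partitioning of community composition over four predictor blocks
#'
#' Partitions the (adjusted) redundancy-analysis R-squared of the
#' community matrix among four predictor blocks -- canonically climatic
#' (MAP), geographical (LON, LAT, ALT), physicochemical (the remaining
#' edaphic variables) and eukaryotic community composition -- via
#' inclusion-exclusion over all 15 block subsets (`vegan::varpart`). The
#' community matrix is Hellinger-transformed by default; blocks named in
#' `pca_blocks` are first reduced to principal components retaining at
#' least `pca_var` of their variance.
#'
#' @param m A `coverage_matrix` (samples in columns).
#' @param blocks Named list of 4 data frames/matrices of per-sample
#'   predictors (rows aligned with the samples of `m`).
#' @param pca_blocks Names of blocks to reduce by PCA (default
#'   `c("physicochemical", "eukaryotic")` when present).
#' @param pca_var Variance fraction retained by the PCA reduction.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return List of class `vpa_result`: `individual` (named vector of the
#'   16 unique/shared fractions incl. residual, adjusted R-squared),
#'   `block_totals` (named vector: sum of fractions containing each
#'   block), `residual`, and the underlying `vegan::varpart` object in
#'   `$fit`.
#' @export
variation_partition <- function(m, blocks,
                                pca_blocks = c("physicochemical", "eukaryotic"),
                                pca_var = 0.8,
                                transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  if (length(blocks) != 4 || is.null(names(blocks)))
    stop("`blocks` must be a named list of 4 predictor blocks")
  y <- t(unclass(m))
  if (transform == "hellinger") y <- vegan::decostand(y, "hellinger")
  xs <- lapply(names(blocks), function(nm) {
    b <- as.matrix(blocks[[nm]])
    if (nrow(b) != ncol(m))
      stop("block '", nm, "' rows must match the samples of the matrix")
    if (nm %in% pca_blocks && ncol(b) > 1) b <- pca_reduce(b, pca_var)
    b
  })
  n_pred <- sum(vapply(xs, ncol, 0L))
  if (ncol(m) <= n_pred + 1)
    stop("more predictors (", n_pred, ") than samples support after reduction")
  fit <- vegan::varpart(y, xs[[1]], xs[[2]], xs[[3]], xs[[4]])
  ind <- fit$part$indfract$Adj.R.square
  names(ind) <- rownames(fit$part$indfract)
  labels <- c("X1", "X2", "X3", "X4")
  # fractions [a]..[o] carry a testable subset structure; map each to the
  # blocks it contains to form per-block totals by inclusion
  contains <- list(
    a = 1, b = 2, c = 3, d = 4,
    e = c(1, 2), f = c(2, 3), g = c(1, 3), h = c(1, 4), i = c(2, 4),
    j = c(3, 4), k = c(1, 2, 4), l = c(1, 2, 3), m = c(2, 3, 4),
    n = c(1, 3, 4), o = c(1, 2, 3, 4))
  frac_names <- sub("\\[([a-p])\\].*", "\\1", names(ind))
  totals <- vapply(1:4, function(bi)
    sum(ind[frac_names %in% names(contains)[vapply(contains, function(s)
      bi %in% s, TRUE)]]), numeric(1))
  names(totals) <- names(blocks)
  out <- list(individual = ind,
              block_totals = totals,
              residual = unname(ind[frac_names == "p"]),
              fit = fit)
  class(out) <- "vpa_result"
  out
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R-squared)\n")
  cat("  block totals:\n")
  for (nm in names(x$block_totals))
    cat(sprintf("    %-16s %.3f\n", nm, x$block_totals[nm]))
  cat(sprintf("  residual: %.3f\n", x$residual))
  invisible(x)
}
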