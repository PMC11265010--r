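#' Normalize raw coverage by sequencing depth
#'
#' Each sample's coverages are divided by that sample's read count and
#' multiplied by the mean read count over all samples, so that values are
#' comparable across metagenomes of different depth.
#'
#' @param raw A `coverage_matrix` at stage `raw`.
#' @param reads Named numeric vector of per-sample read counts, or a
#'   `sample_table` with `read_count`.
#' @return A `coverage_matrix` at stage `normalized`.
#' @export
normalize_coverage <- function(raw, reads) {
  if (inherits(reads, "data.frame")) {
    rc <- reads$read_count
    names(rc) <- reads$sample_id
    reads <- rc
  }
  miss <- setdiff(colnames(raw), names(reads))
  if (length(miss))
    stop("read count missing for sample(s): ", paste(miss, collapse = ", "))
  reads <- reads[colnames(raw)]
  if (any(!is.finite(reads)) || any(reads <= 0))
    stop("read counts must be positive and finite")
  norm <- sweep(unclass(raw), 2, reads, "/") * mean(reads)
  coverage_matrix(norm, stage = "normalized")
}

#' Relative abundance (percent) per sample
#'
#' Converts a normalized coverage table into a proportional table whose
#' columns each sum to 100. Samples with zero total coverage stay all
#' zero and are flagged in the `empty_samples` attribute.
#'
#' @param norm A `coverage_matrix` at stage `normalized`.
#' @return A `coverage_matrix` at stage `relative` (percent).
#' @export
relative_abundance <- function(norm) {
  if (!identical(coverage_stage(norm), "normalized"))
    stop("relative_abundance expects a matrix at stage 'normalized'")
  tot <- colSums(norm)
  empty <- colnames(norm)[tot == 0]
  tot[tot == 0] <- 1  # keep empty columns at zero
  rel <- sweep(unclass(norm), 2, tot, "/") * 100
  out <- coverage_matrix(rel, stage = "relative")
  if (length(empty)) attr(out, "empty_samples") <- empty
  out
}

# phylotype x sample presence matrix under the detection threshold
presence_matrix <- function(m, presence_min = 0) {
  unclass(m) > presence_min
}

#' Occurrence frequency of phylotypes per habitat
#'
#' Percentage of a habitat's samples in which each phylotype is detected
#' (abundance strictly above `presence_min`).
#'
#' @param m A `coverage_matrix`.
#' @param samples A `sample_table` covering the matrix's samples.
#' @param presence_min Detection threshold (default 0).
#' @return Matrix phylotype x habitat of percentages.
#' @export
occurrence_frequency <- function(m, samples, presence_min = 0) {
  samples <- match_samples(m, samples)
  pres <- presence_matrix(m, presence_min)
  habs <- habitat_levels()
  n_by_h <- table(factor(samples$habitat, levels = habs))
  used <- habs[habs %in% as.character(unique(samples$habitat))]
  out <- sapply(used, function(h) {
    idx <- samples$habitat == h
    if (!any(idx)) stop("habitat with zero samples: ", h)
    100 * rowSums(pres[, idx, drop = FALSE]) / sum(idx)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), used))
  out
}

#' Habitat occupancy summary
#'
#' Tallies, for each phylotype, the number of habitat types where it is
#' detected, the sets unique to each habitat, and the set shared by all
#' habitats, together with percentages of the phylotype total (reported
#' at 2 significant digits).
#'
#' @param m A `coverage_matrix` (>= 1 phylotype).
#' @param samples A `sample_table`.
#' @param presence_min Detection threshold (default 0).
#' @return List of class `occupancy_summary`: `n_phylotypes`,
#'   `habitats_per_phylotype` (named integer vector), `count_by_n_habitats`,
#'   `unique_by_habitat` (list of id vectors), `shared_all` (ids),
#'   `pct_unique_one`, `pct_shared_all`.
#' @export
occupancy_summary <- function(m, samples, presence_min = 0) {
  if (nrow(m) < 1) stop("need at least one phylotype")
  samples <- match_samples(m, samples)
  pres <- presence_matrix(m, presence_min)
  habs <- as.character(unique(samples$habitat))
  occ <- sapply(habs, function(h)
    rowSums(pres[, samples$habitat == h, drop = FALSE]) > 0)
  occ <- matrix(occ, nrow = nrow(m), dimnames = list(rownames(m), habs))
  n_hab <- rowSums(occ)
  counts <- table(factor(n_hab, levels = 0:length(habs)))
  uniq <- lapply(habs, function(h)
    rownames(m)[occ[, h] & n_hab == 1])
  names(uniq) <- habs
  shared <- rownames(m)[n_hab == length(habs)]
  out <- list(n_phylotypes = nrow(m),
              habitats_per_phylotype = stats::setNames(as.integer(n_hab), rownames(m)),
              count_by_n_habitats = counts,
              unique_by_habitat = uniq,
              shared_all = shared,
              pct_unique_one = percent_of(sum(n_hab == 1), nrow(m)),
              pct_shared_all = percent_of(length(shared), nrow(m)))
  class(out) <- "occupancy_summary"
  out
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("occupancy_summary over %d phylotypes\n", x$n_phylotypes))
  cat(sprintf("  unique to one habitat: %d (%s%%)\n",
              sum(x$habitats_per_phylotype == 1), format(x$pct_unique_one)))
  cat(sprintf("  shared by all habitats: %d (%s%%)\n",
              length(x$shared_all), format(x$pct_shared_all)))
  invisible(x)
}

#' Per-sample mean standardized environmental value (SEV)
#'
#' Each environmental variable is min-max standardized to [0, 1] across
#' samples; the SEV of a sample is the mean of its standardized variables.
#' Constant variables carry no range information and are dropped (with a
#' message); missing values are excluded from both the standardization
#' and the averaging.
#'
#' @param samples A `sample_table`.
#' @param variables Environmental variables to use (default: the 14 of
#'   [env_variable_names()] present in the table).
#' @return Named numeric vector of SEV per sample.
#' @export
sample_sev <- function(samples, variables = NULL) {
  env <- sample_env(samples, variables)
  if (nrow(env) < 2) stop("need at least two samples")
  rng <- apply(env, 2, function(v) diff(range(v, na.rm = TRUE)))
  keep <- is.finite(rng) & rng > 0
  if (any(!keep))
    message("dropping constant/empty variable(s): ",
            paste(colnames(env)[!keep], collapse = ", "))
  if (!any(keep)) stop("no usable environmental variables")
  env <- env[, keep, drop = FALSE]
  std <- apply(env, 2, function(v)
    (v - min(v, na.rm = TRUE)) / diff(range(v, na.rm = TRUE)))
  sev <- rowMeans(std, na.rm = TRUE)
  stats::setNames(sev, samples$sample_id)
}

#' Environmental range of each phylotype
#'
#' The environmental-range (niche breadth) statistic: per sample, the
#' mean of the min-max standardized environmental variables (SEV); per
#' phylotype, the spread max SEV - min SEV over its occupied samples,
#' then min-max standardized across phylotypes to [0, 1]. Phylotypes
#' occupying a single sample have raw range 0.
#'
#' @param m A `coverage_matrix`.
#' @param samples A `sample_table` (>= 2 samples).
#' @param variables Environmental variables (default as [sample_sev()]).
#' @param presence_min Detection threshold (default 0).
#' @return Data frame of class `env_range_table`: `phylotype`,
#'   `n_samples`, `n_sites`, `n_habitats`, `total_abundance`,
#'   `average_abundance` (total / samples occupied), `raw_range`,
#'   `std_range`.
#' @export
environmental_range <- function(m, samples, variables = NULL,
                                presence_min = 0) {
  samples <- match_samples(m, samples)
  sev <- sample_sev(samples, variables)
  pres <- presence_matrix(m, presence_min)
  if (any(rowSums(pres) == 0))
    stop("phylotype present in zero samples: ",
         paste(utils::head(rownames(m)[rowSums(pres) == 0], 5), collapse = ", "))
  site <- if ("site_id" %in% colnames(samples)) samples$site_id else samples$sample_id
  hab <- as.character(samples$habitat)
  tot <- rowSums(unclass(m))
  n_samp <- rowSums(pres)
  stats_per <- t(apply(pres, 1, function(p) {
    c(n_sites = length(unique(site[p])),
      n_habitats = length(unique(hab[p])),
      raw_range = max(sev[p]) - min(sev[p]))
  }))
  raw <- stats_per[, "raw_range"]
  span <- diff(range(raw))
  std <- if (span > 0) (raw - min(raw)) / span else rep(0, length(raw))
  out <- data.frame(phylotype = rownames(m),
                    n_samples = as.integer(n_samp),
                    n_sites = as.integer(stats_per[, "n_sites"]),
                    n_habitats = as.integer(stats_per[, "n_habitats"]),
                    total_abundance = tot,
                    average_abundance = tot / n_samp,
                    raw_range = raw,
                    std_range = std,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("env_range_table", "data.frame")
  out
}

# Pearson correlation with a guard for constant vectors
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, note = "undefined: constant vector"))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, note = NA_character_)
}

#' Abundance-occupancy-range correlations
#'
#' Pearson correlations relating phylotype abundance to distribution
#' breadth: log average abundance against the number of habitat types,
#' the log number of occupied sites, and the log standardized
#' environmental range; plus log total abundance and log site count
#' against log range. Zero ranges receive an offset of (smallest positive
#' value)/10 before the log; the offset is recorded in the output.
#'
#' @param ert An `env_range_table` (>= 3 phylotypes with positive
#'   abundance).
#' @return Data frame with one row per relationship: `x`, `y`, `r`, `p`,
#'   `n`, `note`; the log offset is in attribute `log_eps`.
#' @export
abundance_occupancy_stats <- function(ert) {
  ert <- ert[ert$total_abundance > 0, , drop = FALSE]
  if (nrow(ert) < 3) stop("need at least 3 phylotypes with positive abundance")
  eps_of <- function(v) {
    pos <- v[v > 0]
    if (!length(pos)) 1e-12 else min(pos) / 10
  }
  eps <- eps_of(ert$std_range)
  lr <- log(ert$std_range + ifelse(ert$std_range == 0, eps, 0))
  la <- log(ert$average_abundance)
  lt <- log(ert$total_abundance)
  ls <- log(ert$n_sites)
  rel <- list(
    c("n_habitats", "log_average_abundance"),
    c("log_n_sites", "log_average_abundance"),
    c("log_env_range", "log_average_abundance"),
    c("log_env_range", "log_total_abundance"),
    c("log_env_range", "log_n_sites"))
  xs <- list(ert$n_habitats, ls, lr, lr, lr)
  ys <- list(la, la, la, lt, ls)
  rows <- mapply(function(nm, x, y) {
    s <- safe_cor(x, y)
    data.frame(x = nm[1], y = nm[2], r = s$r, p = s$p, n = length(x),
               note = s$note, stringsAsFactors = FALSE)
  }, rel, xs, ys, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "log_eps") <- eps
  out
}

#' Fit the abundance-occupancy tradeoff slope
#'
#' Least-squares slope of each phylotype's mean log abundance over its
#' occupied samples on its log number of occupied samples. Under a
#' log-normal abundance law the mean of logs estimates the phylotype's
#' location parameter without an occupancy-dependent offset (the log of
#' an arithmetic mean would carry one), so the slope estimates the
#' occupancy-abundance tradeoff coefficient directly.
#'
#' @param m A `coverage_matrix`.
#' @param presence_min Detection threshold.
#' @return List with `slope`, `se`, `p`.
#' @export
occupancy_tradeoff_slope <- function(m, presence_min = 0) {
  pres <- presence_matrix(m, presence_min)
  occ <- rowSums(pres)
  keep <- occ > 0
  occ <- occ[keep]
  mlog <- vapply(which(keep), function(i)
    mean(log(unclass(m)[i, pres[i, ]])), numeric(1))
  fit <- stats::lm(mlog ~ log(occ))
  s <- summary(fit)$coefficients
  list(slope = unname(s[2, 1]), se = unname(s[2, 2]), p = unname(s[2, 4]))
}

#' Sample-based rarefaction (species accumulation) curve
#'
#' Mean number of distinct phylotypes detected after k samples, either
#' averaged over `n_perm` random sample orderings (`method = "random"`,
#' seeded) or computed analytically as the mean over all orderings
#' (`method = "exact"`). The terminal slope, reported as a percentage, is
#' `100 * (S_n - S_{n-1}) / S_n`.
#'
#' @param m A `coverage_matrix` (columns restricted to the samples of
#'   interest, e.g. one habitat).
#' @param n_perm Number of random orderings (random method).
#' @param seed RNG seed (random method).
#' @param method `"random"` or `"exact"`.
#' @param presence_min Detection threshold.
#' @return List of class `rarefaction_curve`: `curve` (data frame `k`,
#'   `richness`), `terminal_slope_pct`, `method`, `seed`.
#' @export
rarefaction_curve <- function(m, n_perm = 100, seed = 1L,
                              method = c("random", "exact"),
                              presence_min = 0) {
  method <- match.arg(method)
  pres <- presence_matrix(m, presence_min)
  n <- ncol(pres)
  if (n < 2) stop("need at least 2 samples")
  if (method == "exact") {
    n_i <- rowSums(pres)
    mean_rich <- vapply(seq_len(n), function(k) {
      sum(1 - exp(lchoose(n - n_i, k) - lchoose(n, k)))
    }, numeric(1))
  } else {
    set.seed(seed)
    acc <- matrix(0, n_perm, n)
    for (r in seq_len(n_perm)) {
      ordn <- sample.int(n)
      seen <- rep(FALSE, nrow(pres))
      for (k in seq_len(n)) {
        seen <- seen | pres[, ordn[k]]
        acc[r, k] <- sum(seen)
      }
    }
    mean_rich <- colMeans(acc)
  }
  slope <- 100 * (mean_rich[n] - mean_rich[n - 1]) / mean_rich[n]
  out <- list(curve = data.frame(k = seq_len(n), richness = mean_rich),
              terminal_slope_pct = slope, method = method,
              seed = if (method == "random") seed else NA_integer_)
  class(out) <- "rarefaction_curve"
  out
}

#' Remove redundant environmental variables
#'
#' Greedy collinearity filter: while any pair of retained variables has
#' Spearman rho^2 above `rho2_max`, the member of a violating pair with
#' the larger mean absolute correlation to all other retained variables
#' is removed (ties broken alphabetically), so the retained set has no
#' strongly redundant pair.
#'
#' @param samples A `sample_table`.
#' @param variables Candidate variables (default: all present).
#' @param rho2_max Squared Spearman correlation threshold (default 0.7).
#' @return Character vector of retained variable names; removed variables
#'   are recorded in the `removed` attribute.
#' @export
env_redundancy_filter <- function(samples, variables = NULL, rho2_max = 0.7) {
  env <- sample_env(samples, variables)
  if (ncol(env) < 2) stop("need at least two variables")
  keep <- colnames(env)
  removed <- character(0)
  repeat {
    if (length(keep) < 2) break
    rho <- stats::cor(env[, keep, drop = FALSE], method = "spearman",
                      use = "pairwise.complete.obs")
    diag(rho) <- 0
    if (max(rho^2, na.rm = TRUE) <= rho2_max) break
    viol <- unique(rownames(which(rho^2 > rho2_max, arr.ind = TRUE)))
    mean_abs <- rowMeans(abs(rho[viol, , drop = FALSE]), na.rm = TRUE)
    worst <- sort(names(mean_abs)[mean_abs == max(mean_abs)])[1]
    keep <- setdiff(keep, worst)
    removed <- c(removed, worst)
  }
  structure(keep, removed = removed)
}
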