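#' Prevalence filter for a habitat's features
#'
#' Keeps features (phylotypes or ASVs) detected in at least
#' `ceiling(min_prevalence * n_samples)` of the habitat's samples, the
#' rule used to drop poorly represented species before network
#' inference.
#'
#' @param m Feature x sample matrix restricted to one habitat's samples.
#' @param min_prevalence Prevalence threshold (default 0.10).
#' @param presence_min Detection threshold.
#' @return Character vector of retained feature ids.
#' @export
prevalence_filter <- function(m, min_prevalence = 0.10, presence_min = 0) {
  if (ncol(m) < 1) stop("habitat has no samples")
  need <- ceiling(min_prevalence * ncol(m))
  pres <- rowSums(unclass(m) > presence_min)
  rownames(m)[pres >= need]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to
#' the input order (delegates to `stats::p.adjust`).
#'
#' @param pvals Numeric p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Spearman rho for all virus x asv pairs plus two-sided t-approximation p
spearman_pairs <- function(vm, em) {
  n <- ncol(vm)
  rho <- suppressWarnings(stats::cor(t(unclass(vm)), t(unclass(em)),
                                     method = "spearman"))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Virus-eukaryote co-occurrence edges within one habitat
#'
#' Spearman rank correlations (average-rank tie handling) for every
#' virus x ASV pair across the habitat's samples, with two-sided p from
#' the t approximation (or a permutation null for small n), BH-adjusted
#' across all tested pairs in the habitat. An edge is retained when
#' `rho >= rho_min` (positive-only rule) and adjusted p < `alpha`.
#' Constant features are skipped and counted in the `skipped` attribute.
#'
#' @param virus_m Virus phylotype x sample matrix (prevalence-filtered).
#' @param euk_m Eukaryote ASV x sample matrix over the same samples.
#' @param rho_min Correlation cutoff (default 0.60).
#' @param alpha FDR level on adjusted p (default 0.05).
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param seed RNG seed (permutation p only).
#' @param habitat Optional habitat label stored on each edge.
#' @return Data frame of class `edge_list`: `virus`, `asv`, `rho`, `p`,
#'   `q`, `habitat`; all tested pairs are in attribute `n_tested`.
#' @export
spearman_edges <- function(virus_m, euk_m, rho_min = 0.60, alpha = 0.05,
                           p_method = c("t", "permutation"), n_perm = 999,
                           seed = 1L, habitat = NA_character_) {
  p_method <- match.arg(p_method)
  if (!identical(colnames(virus_m), colnames(euk_m)))
    stop("virus and eukaryote matrices must share samples in the same order")
  n <- ncol(virus_m)
  if (n < 5) stop("need at least 5 samples")
  const_v <- apply(unclass(virus_m), 1, function(x) length(unique(x)) == 1)
  const_e <- apply(unclass(euk_m), 1, function(x) length(unique(x)) == 1)
  vm <- virus_m[!const_v, , drop = FALSE]
  em <- euk_m[!const_e, , drop = FALSE]
  if (nrow(vm) == 0 || nrow(em) == 0)
    stop("no non-constant features to correlate")
  sp <- spearman_pairs(vm, em)
  if (p_method == "permutation") {
    set.seed(seed)
    exceed <- matrix(0, nrow(vm), ncol = nrow(em))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      rp <- suppressWarnings(stats::cor(t(unclass(vm))[idx, , drop = FALSE],
                                        t(unclass(em)), method = "spearman"))
      exceed <- exceed + (abs(rp) >= abs(sp$rho))
    }
    sp$p <- (exceed + 1) / (n_perm + 1)
  }
  pairs <- expand.grid(virus = rownames(vm), asv = rownames(em),
                       stringsAsFactors = FALSE)
  pairs$rho <- as.vector(sp$rho)
  pairs$p <- as.vector(sp$p)
  pairs$q <- bh_adjust(pairs$p)
  keep <- pairs$rho >= rho_min & pairs$q < alpha
  edges <- pairs[keep, , drop = FALSE]
  edges$habitat <- rep(habitat, nrow(edges))
  rownames(edges) <- NULL
  class(edges) <- c("edge_list", "data.frame")
  attr(edges, "n_tested") <- nrow(pairs)
  attr(edges, "skipped") <- sum(const_v) + sum(const_e)
  attr(edges, "rho_min") <- rho_min
  attr(edges, "alpha") <- alpha
  edges
}

#' Per-habitat co-occurrence networks across a survey
#'
#' Applies the prevalence filter and [spearman_edges()] habitat by
#' habitat and pools the retained edges.
#'
#' @param virus_m Virus phylotype x sample `coverage_matrix`.
#' @param euk_m Eukaryote ASV x sample matrix (same samples).
#' @param samples A `sample_table`.
#' @param min_prevalence Prevalence threshold per habitat.
#' @param ... Passed to [spearman_edges()].
#' @return An `edge_list` over all habitats.
#' @export
cooccurrence_network <- function(virus_m, euk_m, samples,
                                 min_prevalence = 0.10, ...) {
  samples <- match_samples(virus_m, samples)
  if (!identical(colnames(virus_m), colnames(euk_m)))
    stop("virus and eukaryote matrices must share samples")
  habs <- as.character(unique(samples$habitat))
  res <- list()
  for (h in habs) {
    idx <- samples$habitat == h
    if (sum(idx) < 5) next
    vm <- virus_m[, idx, drop = FALSE]
    em <- euk_m[, idx, drop = FALSE]
    vk <- prevalence_filter(vm, min_prevalence)
    ek <- prevalence_filter(em, min_prevalence)
    if (!length(vk) || !length(ek)) next
    res[[h]] <- spearman_edges(vm[vk, , drop = FALSE], em[ek, , drop = FALSE],
                               habitat = h, ...)
  }
  if (!length(res)) {
    out <- data.frame(virus = character(0), asv = character(0),
                      rho = numeric(0), p = numeric(0), q = numeric(0),
                      habitat = character(0))
  } else {
    out <- do.call(rbind, lapply(res, as.data.frame))
  }
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  attr(out, "n_tested") <- sum(vapply(res, function(e)
    attr(e, "n_tested"), 0))
  out
}

#' Summarize a co-occurrence network
#'
#' @param edges An `edge_list`.
#' @param virus_family Optional named vector: virus id -> NCLDV family.
#' @param euk_group Optional named vector: ASV id -> eukaryote group
#'   (fungi, protozoa, algae, animals, other); unannotated nodes fall in
#'   `"other"` with a warning.
#' @return List with `edges_by_habitat`, `family_by_group`
#'   (contingency table) and `degree` (named vector over all nodes).
#' @export
network_summary <- function(edges, virus_family = NULL, euk_group = NULL) {
  by_hab <- table(edges$habitat)
  fam <- if (is.null(virus_family)) rep("unassigned", nrow(edges)) else {
    f <- unname(virus_family[edges$virus])
    f[is.na(f)] <- "unassigned"
    f
  }
  grp <- if (is.null(euk_group)) rep("other", nrow(edges)) else {
    g <- unname(euk_group[edges$asv])
    if (anyNA(g)) {
      warning(sum(is.na(g)), " ASV node(s) without group annotation; set to 'other'")
      g[is.na(g)] <- "other"
    }
    g
  }
  deg <- table(c(edges$virus, edges$asv))
  list(edges_by_habitat = by_hab,
       family_by_group = table(family = fam, group = grp),
       degree = deg)
}

#' Abundance coupling between network viruses and eukaryote groups
#'
#' For each eukaryote group, per-sample totals of network-virus
#' abundance and of the group's ASV abundance are z-scored and their
#' Pearson correlation reported.
#'
#' @param virus_m Virus matrix restricted to network phylotypes.
#' @param euk_m Eukaryote ASV matrix (same samples).
#' @param euk_group Named vector: ASV id -> group.
#' @return Data frame `group`, `r`, `p`, `n`, `note` (`r = NA` flagged
#'   for zero-variance series).
#' @export
group_abundance_correlation <- function(virus_m, euk_m, euk_group) {
  if (!identical(colnames(virus_m), colnames(euk_m)))
    stop("matrices must share samples")
  if (ncol(virus_m) < 3) stop("need at least 3 samples")
  vtot <- colSums(unclass(virus_m))
  groups <- sort(unique(unname(euk_group[rownames(euk_m)])))
  groups <- groups[!is.na(groups)]
  rows <- lapply(groups, function(g) {
    ids <- names(euk_group)[euk_group == g]
    etot <- colSums(unclass(euk_m)[rownames(euk_m) %in% ids, , drop = FALSE])
    # Pearson r is invariant to the z-scoring used for display
    s <- safe_cor(vtot, etot)
    data.frame(group = g, r = s$r, p = s$p, n = ncol(virus_m), note = s$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
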