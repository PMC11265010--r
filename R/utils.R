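#' Habitat types surveyed
#'
#' The five terrestrial habitat types covered by the survey design:
#' farmland, forest, grassland, Gobi desert and mine wasteland.
#'
#' @return Character vector of the five habitat labels.
#' @export
habitat_levels <- function() {
  c("farmland", "forest", "grassland", "gobi", "mine")
}

#' Environmental variable names
#'
#' The 14 climatic, geographic and edaphic variables recorded per sample:
#' longitude (LON), latitude (LAT), altitude (ALT), mean annual
#' precipitation (MAP), pH, electrical conductivity (EC), exchangeable
#' calcium (EX-Ca), CaCO3, cation exchange capacity (CEC), clay fraction,
#' total P, K, N and C.
#'
#' @return Character vector of the 14 variable names.
#' @export
env_variable_names <- function() {
  c("LON", "LAT", "ALT", "MAP", "pH", "EC", "EX-Ca", "CaCO3", "CEC",
    "clay", "TP", "TK", "TN", "TC")
}

#' Percentage of a total, rounded as reported
#'
#' @param n Count of interest.
#' @param total Reference total (> 0).
#' @param digits Significant digits used when reporting (default 2).
#' @return Percentage `100 * n / total` rounded to `digits` significant
#'   digits.
#' @export
percent_of <- function(n, total, digits = 2) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0)
  signif(100 * n / total, digits)
}

#' Percentage increase of a count over a baseline
#'
#' @param n_new Newly added count.
#' @param n_old Baseline count (> 0).
#' @param digits Significant digits (default 2).
#' @return Percentage increase `100 * n_new / n_old`.
#' @export
percent_increase <- function(n_new, n_old, digits = 2) {
  stopifnot(is.numeric(n_new), is.numeric(n_old), n_old > 0)
  signif(100 * n_new / n_old, digits)
}

#' Run configuration
#'
#' Bundles the thresholds and the random seed used across the pipeline so
#' that outputs can record how they were produced.
#'
#' @param identity_min Sequence identity threshold for dereplication.
#' @param overlap_min Alignment coverage threshold for dereplication.
#' @param support_min Minimum placement weight for a taxonomy call.
#' @param presence_min Abundance above which a phylotype counts as present.
#' @param prevalence_min Within-habitat prevalence filter for networks.
#' @param rho_min Spearman correlation cutoff for network edges.
#' @param fdr_alpha Benjamini-Hochberg significance level.
#' @param contig_min_len Minimum contig length (bp) for screening.
#' @param ncvog_min Minimum count of core-marker hits for screening.
#' @param n_permutations Permutations for permutation tests.
#' @param rng_seed Integer seed recorded in downstream outputs.
#' @return A list of class `soilgv_config`.
#' @export
run_config <- function(identity_min = 0.95, overlap_min = 0.90,
                       support_min = 0.5, presence_min = 0,
                       prevalence_min = 0.10, rho_min = 0.60,
                       fdr_alpha = 0.05, contig_min_len = 5000,
                       ncvog_min = 2, n_permutations = 999, rng_seed = 1L) {
  for (x in c(identity_min, overlap_min, support_min, prevalence_min,
              rho_min, fdr_alpha)) {
    if (!is.numeric(x) || x < 0 || x > 1)
      stop("thresholds on proportions must lie in [0, 1]")
  }
  stopifnot(contig_min_len > 0, ncvog_min >= 0, n_permutations >= 1)
  structure(list(identity_min = identity_min, overlap_min = overlap_min,
                 support_min = support_min, presence_min = presence_min,
                 prevalence_min = prevalence_min, rho_min = rho_min,
                 fdr_alpha = fdr_alpha, contig_min_len = contig_min_len,
                 ncvog_min = ncvog_min, n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed)),
            class = "soilgv_config")
}

#' @export
print.soilgv_config <- function(x, ...) {
  cat("soilgv run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# stamp provenance (seed/thresholds) onto a result object
stamp <- function(x, seed = NULL, ...) {
  extra <- list(...)
  if (!is.null(seed)) attr(x, "seed") <- seed
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  x
}
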