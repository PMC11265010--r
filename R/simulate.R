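#' Build a labeled synthetic reference tree for placement simulations
#'
#' Constructs a reference topology mirroring the structure a placement
#' classifier needs: six NCLDV orders containing family clades with
#' cultivated representatives (Asfarviridae, Iridoviridae,
#' Marseilleviridae, Mimiviridae, Phycodnaviridae, Poxviridae,
#' Coccolithoviridae, Mininucleoviridae, Pandoraviridae, Pithoviridae,
#' Prasinoviridae), additional proposed families without representatives,
#' and four outgroup clades (eukaryote, bacteria, archaea, phage PolBs).
#' Every branch carries a jplace edge number. The tree is synthetic: the
#' topology encodes the clade structure, not any estimated phylogeny.
#'
#' @return List of class `reference_tree`: `tree` (phylo), `edge_map`,
#'   `clade_map` and `newick` (edge-numbered string).
#' @export
make_reference_tree <- function() {
  orders <- list(
    Algavirales = list(Phycodnaviridae = 3, Coccolithoviridae = 3,
                       Prasinoviridae = 3, Algavirales_nr1 = 2),
    Asfuvirales = list(Asfarviridae = 3, Asfuvirales_nr1 = 2),
    Chitovirales = list(Poxviridae = 3),
    Imitervirales = list(Mimiviridae = 4, Imitervirales_nr1 = 2),
    Pandoravirales = list(Pandoraviridae = 3),
    Pimascovirales = list(Pithoviridae = 4, Iridoviridae = 3,
                          Marseilleviridae = 3, Mininucleoviridae = 2,
                          Pimascovirales_nr1 = 2))
  outgroups <- c(eukaryote = 4, bacteria = 4, archaea = 4, phage = 3)
  rows <- list()
  clade_str <- function(leaves) paste0("(", paste0(leaves, ":0.1", collapse = ","), "):0.1")
  ord_strs <- vapply(names(orders), function(o) {
    fams <- orders[[o]]
    fam_strs <- vapply(names(fams), function(f) {
      leaves <- paste0(f, "_", seq_len(fams[[f]]))
      rows[[length(rows) + 1]] <<- data.frame(
        leaf = leaves, group = "ncldv", order = o, family = f,
        has_rep = !grepl("_nr\\d+$", f), stringsAsFactors = FALSE)
      clade_str(leaves)
    }, "")
    if (length(fam_strs) == 1) fam_strs else
      paste0("(", paste(fam_strs, collapse = ","), "):0.1")
  }, "")
  out_strs <- vapply(names(outgroups), function(o) {
    leaves <- paste0(o, "_", seq_len(outgroups[[o]]))
    rows[[length(rows) + 1]] <<- data.frame(
      leaf = leaves, group = "outgroup", order = o, family = NA_character_,
      has_rep = NA, stringsAsFactors = FALSE)
    clade_str(leaves)
  }, "")
  nwk <- paste0("((", paste(ord_strs, collapse = ","), "):0.1,",
                paste(out_strs, collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  n_tip <- length(tree$tip.label)
  # number every branch (child-node keyed), pplacer style, in edge order
  edge_map <- data.frame(edge_num = seq_len(nrow(tree$edge)) - 1L,
                         node = tree$edge[, 2])
  cm <- clade_map(do.call(rbind, rows))
  out <- list(tree = tree, edge_map = edge_map, clade_map = cm,
              newick = edge_numbered_newick(tree, edge_map))
  class(out) <- "reference_tree"
  out
}

#' @export
print.reference_tree <- function(x, ...) {
  cat(sprintf("reference_tree: %d leaves, %d edges, %d NCLDV families, %d outgroup clades\n",
              length(x$tree$tip.label), nrow(x$edge_map),
              length(unique(x$clade_map$family[x$clade_map$group == "ncldv"])),
              length(unique(x$clade_map$order[x$clade_map$group == "outgroup"]))))
  invisible(x)
}

#' Simulate a habitat-structured soil virus community survey
#'
#' Generates a raw coverage matrix, a sample table and a ground-truth
#' record with the statistical structure the downstream analyses assume.
#' Samples come from sites nested in the five habitat types (default
#' site numbers follow the survey design: 29 farmland, 27 forest, 9
#' grassland, 4 Gobi desert and 42 mine wasteland sites, 3 samples
#' each). Phylotypes are specialists of one habitat (occupying its
#' samples with probability `p_in` and foreign samples with `p_out`) or
#' generalists (probability `p_generalist` everywhere); `n_core`
#' phylotypes occupy every sample. Abundances in occupied samples are
#' log-normal with `meanlog = mu0 + tau * log(occupied samples)`, so
#' `tau < 0` plants the abundance-occupancy tradeoff. The 14
#' environmental variables are habitat-shifted Gaussians; total C/N and
#' clay/CEC are generated collinear (Spearman rho^2 > 0.7) to exercise
#' the redundancy filter. Per-sample read counts are log-uniform.
#'
#' @param n_phylotypes Number of phylotypes (default 533).
#' @param sites_per_habitat Named integer vector of sites per habitat.
#' @param samples_per_site Samples per site (default 3).
#' @param specialist_fraction Fraction of specialist phylotypes in [0,1].
#' @param tau Occupancy-abundance tradeoff coefficient (default -0.5).
#' @param sigma Log-normal sdlog of abundances (> 0, default 1).
#' @param p_in,p_out,p_generalist Occupancy probabilities.
#' @param n_core Phylotypes forced to occupy every sample (default 0).
#' @param mu0 Baseline meanlog of abundance.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `sim_community`: `coverage` (raw
#'   `coverage_matrix`), `samples` (`sample_table`), `truth`
#'   (`sim_truth` list: `niche`, `meanlog`, `tau`, `sigma`, occupancy
#'   probabilities, `seed`, empty `pairs`).
#' @export
simulate_community <- function(n_phylotypes = 533,
                               sites_per_habitat = c(farmland = 29, forest = 27,
                                                     grassland = 9, gobi = 4,
                                                     mine = 42),
                               samples_per_site = 3,
                               specialist_fraction = 0.7,
                               tau = -0.5, sigma = 1,
                               p_in = 0.35, p_out = 0.01,
                               p_generalist = 0.15,
                               n_core = 0, mu0 = 2, seed = 1L) {
  if (specialist_fraction < 0 || specialist_fraction > 1)
    stop("specialist_fraction must lie in [0, 1]")
  stopifnot(sigma > 0, n_phylotypes >= 1, samples_per_site >= 1,
            all(sites_per_habitat >= 1), n_core <= n_phylotypes)
  bad <- setdiff(names(sites_per_habitat), habitat_levels())
  if (length(bad)) stop("unknown habitat(s): ", paste(bad, collapse = ", "))
  set.seed(seed)

  # --- sites and samples -------------------------------------------------
  hab_mean <- list( # per-habitat environmental centres
    MAP = c(farmland = 900, forest = 1200, grassland = 450, gobi = 120, mine = 800),
    ALT = c(farmland = 300, forest = 800, grassland = 1400, gobi = 1100, mine = 500),
    pH = c(farmland = 6.8, forest = 5.8, grassland = 7.4, gobi = 8.2, mine = 4.8),
    EC = c(farmland = 150, forest = 90, grassland = 180, gobi = 450, mine = 600),
    `EX-Ca` = c(farmland = 8, forest = 5, grassland = 10, gobi = 14, mine = 3),
    CaCO3 = c(farmland = 20, forest = 5, grassland = 40, gobi = 90, mine = 10),
    clay = c(farmland = 24, forest = 20, grassland = 18, gobi = 8, mine = 15),
    TP = c(farmland = 0.9, forest = 0.6, grassland = 0.5, gobi = 0.4, mine = 0.5),
    TK = c(farmland = 17, forest = 14, grassland = 18, gobi = 20, mine = 12),
    TC = c(farmland = 15, forest = 30, grassland = 20, gobi = 4, mine = 8))
  hab_sd <- c(MAP = 180, ALT = 250, pH = 0.6, EC = 80, `EX-Ca` = 2.5,
              CaCO3 = 12, clay = 5, TP = 0.2, TK = 3, TC = 6)
  site_rows <- list()
  for (h in names(sites_per_habitat)) {
    for (s in seq_len(sites_per_habitat[[h]])) {
      site_rows[[length(site_rows) + 1]] <- data.frame(
        site_id = sprintf("%s_site%02d", h, s), habitat = h,
        LON = stats::runif(1, 80, 125), LAT = stats::runif(1, 20, 50),
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  for (v in names(hab_mean))
    sites[[v]] <- stats::rnorm(nrow(sites), hab_mean[[v]][sites$habitat], hab_sd[[v]])
  sites$MAP <- pmax(sites$MAP, 10)
  sites$EC <- pmax(sites$EC, 5)
  sites$TC <- pmax(sites$TC, 0.5)
  # planted collinear pairs: TN tracks TC, CEC tracks clay
  sites$TN <- 0.09 * sites$TC + stats::rnorm(nrow(sites), 0, 0.08)
  sites$CEC <- 0.8 * sites$clay + stats::rnorm(nrow(sites), 2, 1.2)
  samp <- sites[rep(seq_len(nrow(sites)), each = samples_per_site), , drop = FALSE]
  samp$sample_id <- paste0(samp$site_id, letters[rep(seq_len(samples_per_site),
                                                     nrow(sites))])
  for (v in c("pH", "EC", "TC", "TN", "TP", "TK", "clay", "CEC", "EX-Ca", "CaCO3"))
    samp[[v]] <- samp[[v]] * exp(stats::rnorm(nrow(samp), 0, 0.05))
  samp$read_count <- round(exp(stats::runif(nrow(samp), log(2e7), log(2e8))))
  samples <- validate_sample_table(
    samp[, c("sample_id", "site_id", "habitat", "read_count",
             env_variable_names())])
  n_samples <- nrow(samples)

  # --- phylotype niches and occupancy ------------------------------------
  ids <- sprintf("pt%04d", seq_len(n_phylotypes))
  habs <- names(sites_per_habitat)
  hab_w <- sites_per_habitat / sum(sites_per_habitat)
  niche <- character(n_phylotypes)
  is_spec <- stats::runif(n_phylotypes) < specialist_fraction
  niche[is_spec] <- sample(habs, sum(is_spec), replace = TRUE, prob = hab_w)
  niche[!is_spec] <- "generalist"
  if (n_core > 0) niche[seq_len(n_core)] <- "core"
  occ <- matrix(FALSE, n_phylotypes, n_samples, dimnames = list(ids, samples$sample_id))
  hab_of <- as.character(samples$habitat)
  for (i in seq_len(n_phylotypes)) {
    occ[i, ] <- switch(
      niche[i],
      core = TRUE,
      generalist = stats::runif(n_samples) < p_generalist,
      stats::runif(n_samples) < ifelse(hab_of == niche[i], p_in, p_out))
    if (!any(occ[i, ])) { # force presence in one home-range sample
      pool <- if (niche[i] %in% habs) which(hab_of == niche[i]) else seq_len(n_samples)
      occ[i, sample(pool, 1)] <- TRUE
    }
  }

  # --- abundances with the planted tradeoff ------------------------------
  n_occ <- rowSums(occ)
  meanlog <- mu0 + tau * log(n_occ)
  cov <- matrix(0, n_phylotypes, n_samples, dimnames = dimnames(occ))
  for (i in seq_len(n_phylotypes))
    cov[i, occ[i, ]] <- stats::rlnorm(n_occ[i], meanlog[i], sigma)
  coverage <- coverage_matrix(cov, stage = "raw")

  truth <- structure(list(niche = stats::setNames(niche, ids),
                          meanlog = stats::setNames(meanlog, ids),
                          tau = tau, sigma = sigma, mu0 = mu0,
                          p_in = p_in, p_out = p_out,
                          p_generalist = p_generalist,
                          specialist_fraction = specialist_fraction,
                          pairs = data.frame(virus = character(0),
                                             asv = character(0),
                                             rho_target = numeric(0)),
                          seed = as.integer(seed)),
                     class = "sim_truth")
  structure(list(coverage = coverage, samples = samples, truth = truth),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf("sim_community: %d phylotypes x %d samples (seed %d, tau %.2f)\n",
              nrow(x$coverage), ncol(x$coverage), x$truth$seed, x$truth$tau))
  invisible(x)
}

#' Simulate a eukaryote ASV table with planted virus-host couplings
#'
#' Generates an ASV-by-sample count matrix over the samples of a
#' simulated community. `n_pairs` host ASVs are planted on the most
#' prevalent virus phylotypes: each host's abundance is a monotone
#' transform of its virus's abundance plus Gaussian-copula noise
#' calibrated so that the population Spearman correlation is
#' approximately `rho_target`. The remaining ASVs are independent
#' log-normal counts.
#'
#' @param sim A `sim_community` (or list with `coverage` and `truth`).
#' @param n_asvs Total number of ASVs (default 200).
#' @param n_pairs Number of planted virus-host pairs.
#' @param rho_target Target Spearman correlation in (0, 1).
#' @param seed Integer seed.
#' @return List with `asv` (ASV x sample count matrix) and `truth` (the
#'   community truth with the planted `pairs` filled in).
#' @export
simulate_eukaryotes <- function(sim, n_asvs = 200, n_pairs = 10,
                                rho_target = 0.7, seed = 1L) {
  if (rho_target >= 1 || rho_target <= 0)
    stop("rho_target must lie in (0, 1)")
  stopifnot(n_pairs <= n_asvs)
  cov <- sim$coverage
  n <- ncol(cov)
  set.seed(seed)
  asv_ids <- sprintf("asv%04d", seq_len(n_asvs))
  em <- matrix(0, n_asvs, n, dimnames = list(asv_ids, colnames(cov)))
  # independent background ASVs
  for (i in seq_len(n_asvs)) {
    present <- stats::runif(n) < 0.6
    em[i, present] <- round(stats::rlnorm(sum(present), 3.5, 1))
  }
  pairs <- data.frame(virus = character(0), asv = character(0),
                      rho_target = numeric(0))
  if (n_pairs > 0) {
    prev <- rowSums(unclass(cov) > 0)
    host_virus <- names(sort(prev, decreasing = TRUE))[seq_len(n_pairs)]
    rho_g <- 2 * sin(pi * rho_target / 6) # Gaussian copula scale
    for (k in seq_len(n_pairs)) {
      v <- unclass(cov)[host_virus[k], ]
      z_v <- stats::qnorm(rank(v, ties.method = "average") / (n + 1))
      z_v <- (z_v - mean(z_v)) / stats::sd(z_v)
      z_h <- rho_g * z_v + sqrt(1 - rho_g^2) * stats::rnorm(n)
      em[k, ] <- round(exp(4 + z_h))
      pairs[k, ] <- list(host_virus[k], asv_ids[k], rho_target)
    }
  }
  truth <- sim$truth
  truth$pairs <- pairs
  list(asv = em, truth = truth)
}

# categorize every numbered edge of a reference tree by the taxonomy
# call its subtree would receive
edge_categories <- function(ref) {
  sets <- node_leaf_sets(ref$tree)
  cm <- ref$clade_map
  vapply(seq_len(nrow(ref$edge_map)), function(i) {
    leaves <- sets[[ref$edge_map$node[i]]]
    rows <- cm[match(leaves, cm$leaf), , drop = FALSE]
    if (any(rows$group == "outgroup")) {
      if (all(rows$group == "outgroup") && length(unique(rows$order)) == 1)
        return(paste0("outgroup:", rows$order[1]))
      return("mixed")
    }
    cl <- classify_leaf_set(leaves, cm)
    if (identical(cl$order, "Pandoravirales")) return("pandora")
    if (identical(cl$order, "unassigned")) return("supra-order")
    if (identical(cl$family, "unassigned")) return("basal")
    "family"
  }, "")
}

#' Simulate placements of true and decoy queries on a reference tree
#'
#' True queries are placed on edges inside NCLDV family clades (or, for
#' a stated fraction, on edges basal to the family clades of an order);
#' decoys are placed inside the outgroup clades only. Likelihood weight
#' ratios are Beta-distributed; each query carries a second, lower-weight
#' candidate from the same edge pool.
#'
#' @param ref A `reference_tree` (see [make_reference_tree()]).
#' @param n_true Number of NCLDV queries.
#' @param n_decoy Number of non-NCLDV decoys.
#' @param basal_fraction Fraction of true queries placed basally.
#' @param n_pandora Additional true queries placed in the Pandoravirales
#'   clade (excluded downstream).
#' @param lwr_shape Beta shape parameters of the best weight.
#' @param seed Integer seed.
#' @return List with `placements` (a [placement_set()]) and `truth`
#'   (data frame `name`, `class` (`ncldv` or decoy clade), `planted`
#'   (`family`/`basal`/`pandora`/`outgroup`), `edge_num`).
#' @export
simulate_placements <- function(ref, n_true = 100, n_decoy = 50,
                                basal_fraction = 0, n_pandora = 0,
                                lwr_shape = c(20, 2), seed = 1L) {
  stopifnot(inherits(ref, "reference_tree"),
            basal_fraction >= 0, basal_fraction <= 1)
  if (!any(ref$clade_map$group == "outgroup"))
    stop("reference tree lacks outgroup clade labels")
  set.seed(seed)
  cat_of <- edge_categories(ref)
  pool <- split(ref$edge_map$edge_num, cat_of)
  out_pool <- unlist(pool[grepl("^outgroup:", names(pool))], use.names = FALSE)
  out_class <- sub("^outgroup:", "", rep(names(pool)[grepl("^outgroup:", names(pool))],
                                         lengths(pool[grepl("^outgroup:", names(pool))])))
  rows <- list()
  add_query <- function(name, edge_pool, class, planted) {
    e <- if (length(edge_pool) == 1) edge_pool else sample(edge_pool, 1)
    w <- stats::rbeta(1, lwr_shape[1], lwr_shape[2])
    alt <- if (length(edge_pool) > 1) sample(setdiff(edge_pool, e), 1) else e
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, edge_num = c(e, alt), like_weight_ratio = c(w, 1 - w),
      class = class, planted = planted, stringsAsFactors = FALSE)
  }
  n_basal <- stats::rbinom(1, n_true, basal_fraction)
  planted_true <- sample(c(rep("basal", n_basal), rep("family", n_true - n_basal)))
  for (i in seq_len(n_true))
    add_query(sprintf("q%04d", i), pool[[planted_true[i]]], "ncldv", planted_true[i])
  for (i in seq_len(n_pandora))
    add_query(sprintf("pv%03d", i), pool[["pandora"]], "ncldv", "pandora")
  for (i in seq_len(n_decoy)) {
    j <- sample(length(out_pool), 1)
    add_query(sprintf("d%04d", i), out_pool[j], out_class[j], "outgroup")
  }
  all_rows <- do.call(rbind, rows)
  ps <- placement_set(ref$tree, ref$edge_map,
                      all_rows[, c("name", "edge_num", "like_weight_ratio")])
  truth <- unique(all_rows[, c("name", "class", "planted")])
  truth$edge_num <- all_rows$edge_num[!duplicated(all_rows$name)]
  rownames(truth) <- NULL
  list(placements = ps, truth = truth)
}

#' Simulate a contig annotation table with known NCLDV origin
#'
#' Contig lengths are log-normal; NCLDV-origin contigs receive
#' classifier flags, core-marker (NCVOG) counts and polB flags at the
#' given rates, background contigs at near-zero rates.
#'
#' @param n_contigs Number of contigs (default 200).
#' @param p_ncldv Fraction of NCLDV-origin contigs.
#' @param len_meanlog,len_sdlog Log-normal length parameters (bp).
#' @param p_classifier,p_polb Emission probabilities for NCLDV contigs.
#' @param ncvog_rate Per-marker hit probability for NCLDV contigs (20
#'   markers).
#' @param bg_rates Named list of the background probabilities
#'   (`classifier`, `polb`, `ncvog`).
#' @param seed Integer seed.
#' @return List with `contigs` (data frame as [screen_contigs()] expects)
#'   and `truth` (logical vector: NCLDV origin).
#' @export
simulate_contigs <- function(n_contigs = 200, p_ncldv = 0.3,
                             len_meanlog = log(8000), len_sdlog = 0.8,
                             p_classifier = 0.7, p_polb = 0.3,
                             ncvog_rate = 0.2,
                             bg_rates = list(classifier = 0.02, polb = 0.002,
                                             ncvog = 0.005),
                             seed = 1L) {
  stopifnot(p_ncldv >= 0, p_ncldv <= 1, ncvog_rate >= 0, ncvog_rate <= 1)
  set.seed(seed)
  is_ncldv <- stats::runif(n_contigs) < p_ncldv
  len <- pmax(500, round(stats::rlnorm(n_contigs, len_meanlog, len_sdlog)))
  contigs <- data.frame(
    contig_id = sprintf("contig%04d", seq_len(n_contigs)),
    length = len,
    classifier_flag = stats::runif(n_contigs) <
      ifelse(is_ncldv, p_classifier, bg_rates$classifier),
    ncvog_count = stats::rbinom(n_contigs, 20,
                                ifelse(is_ncldv, ncvog_rate, bg_rates$ncvog)),
    polb_flag = stats::runif(n_contigs) <
      ifelse(is_ncldv, p_polb, bg_rates$polb),
    stringsAsFactors = FALSE)
  list(contigs = contigs,
       truth = stats::setNames(is_ncldv, contigs$contig_id))
}
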