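#' Pairwise identity and coverage between two marker sequences
#'
#' Aligns two sequences with an ends-free (terminal-gap-free) global
#' alignment under the scoring match +1, mismatch -1, gap -2, and reports
#' the identity over the aligned overlap (matches / overlap columns,
#' terminal overhangs excluded) together with the fraction of the shorter
#' sequence covered by the overlap. These are the quantities the
#' dereplication thresholds are applied to.
#'
#' @param a,b Character strings (nucleotide or amino acid, consistently).
#' @return List with `identity` and `coverage_short`, both in [0, 1].
#' @export
align_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  alpha <- unique(strsplit(paste0(a, b), "")[[1]])
  sm <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 2)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(ap)
  if (cols == 0) return(list(identity = 0, coverage_short = 0))
  matches <- Biostrings::nmatch(aln)
  short <- min(nchar(a), nchar(b))
  aligned_short <- min(nchar(gsub("-", "", ap)), nchar(gsub("-", "", as_)))
  list(identity = matches / cols, coverage_short = aligned_short / short)
}

#' Greedy incremental clustering of marker sequences into phylotypes
#'
#' CD-HIT-style dereplication: sequences are sorted by length (longest
#' first; equal lengths ordered lexicographically by id for determinism)
#' and each sequence joins the first existing cluster whose representative
#' it matches with identity > `identity_min` and coverage of the shorter
#' sequence > `overlap_min`; otherwise it founds a new cluster. Defaults
#' are the dereplication criteria used to define phylotypes (identity
#' > 95%, overlap > 90%).
#'
#' @param seqs Named character vector of sequences (names are ids).
#' @param identity_min Identity threshold in (0, 1].
#' @param overlap_min Coverage threshold in (0, 1].
#' @return List with `clusters` (named list: representative id ->
#'   member ids, in founding order) and `membership` (data frame with
#'   `id`, `representative`).
#' @export
greedy_cluster <- function(seqs, identity_min = 0.95, overlap_min = 0.90) {
  if (length(seqs) == 0) stop("no sequences to cluster")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  stopifnot(identity_min > 0, identity_min <= 1,
            overlap_min > 0, overlap_min <= 1)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  assign <- character(length(seqs))
  names(assign) <- names(seqs)
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (r in reps) {
      hit <- align_identity(seqs[[r]], seqs[[i]])
      if (hit$identity > identity_min && hit$coverage_short > overlap_min) {
        members[[r]] <- c(members[[r]], id)
        assign[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- id
      assign[id] <- id
    }
  }
  list(clusters = members,
       membership = data.frame(id = names(assign), representative = unname(assign),
                               stringsAsFactors = FALSE))
}

# leaf sets below every node of the reference tree (index = node id)
node_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# classify the leaf set subtended by one edge against the clade map
classify_leaf_set <- function(leaves, cm) {
  rows <- cm[match(leaves, cm$leaf), , drop = FALSE]
  if (anyNA(rows$group))
    stop("leaves absent from clade map: ",
         paste(leaves[is.na(rows$group)], collapse = ", "))
  if (any(rows$group == "outgroup"))
    return(list(decision = "non-NCLDV", order = NA_character_,
                family = "not-applicable"))
  orders <- unique(rows$order)
  if (length(orders) > 1)
    return(list(decision = "NCLDV", order = "unassigned", family = "unassigned"))
  fams <- unique(rows$family)
  if (length(fams) == 1 && !is.na(fams) && all(rows$has_rep))
    return(list(decision = "NCLDV", order = orders, family = fams))
  # basal to the family clades of one order, or within/basal to a family
  # without cultivated representatives
  list(decision = "NCLDV", order = orders, family = "unassigned")
}

#' Taxonomy calls from phylogenetic placements
#'
#' Converts each query's best placement (highest likelihood weight ratio)
#' into an identification and taxonomy decision: an edge strictly inside a
#' family clade with cultivated representatives gives that family; an edge
#' inside an order but basal to its family clades, or within/basal to a
#' family without cultivated representatives, gives that order with an
#' unassigned family; an edge inside an outgroup clade, or above the
#' NCLDV/outgroup split, is non-NCLDV. Queries affiliated with
#' Pandoravirales are excluded (reason `pandoravirales-removed`), as are
#' queries whose best weight falls below `support_min` (reason
#' `low-support`).
#'
#' @param ps A [placement_set()].
#' @param cm A [clade_map()] covering every leaf of the reference tree.
#' @param support_min Minimum like_weight_ratio for a retained call.
#' @return Data frame of class `taxonomy_calls`: `query`, `decision`,
#'   `order`, `family`, `excluded`, `reason`, `support`.
#' @export
classify_placements <- function(ps, cm, support_min = 0.5) {
  stopifnot(inherits(ps, "placement_set"))
  cm <- if (inherits(cm, "clade_map")) cm else clade_map(cm)
  missing_leaves <- setdiff(ps$tree$tip.label, cm$leaf)
  if (length(missing_leaves))
    stop("reference leaves not covered by clade map: ",
         paste(utils::head(missing_leaves, 5), collapse = ", "))
  sets <- node_leaf_sets(ps$tree)
  node_of <- ps$edge_map$node[match(ps$best$edge_num, ps$edge_map$edge_num)]
  out <- vector("list", nrow(ps$best))
  for (i in seq_len(nrow(ps$best))) {
    cl <- classify_leaf_set(sets[[node_of[i]]], cm)
    w <- ps$best$like_weight_ratio[i]
    excluded <- FALSE
    reason <- NA_character_
    if (w < support_min) {
      excluded <- TRUE
      reason <- "low-support"
    } else if (!is.na(cl$order) && identical(cl$order, "Pandoravirales")) {
      excluded <- TRUE
      reason <- "pandoravirales-removed"
    }
    out[[i]] <- data.frame(query = ps$best$name[i], decision = cl$decision,
                           order = cl$order, family = cl$family,
                           excluded = excluded, reason = reason,
                           support = w, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  class(calls) <- c("taxonomy_calls", "data.frame")
  calls
}

#' Benchmark taxonomy calls against known query origins
#'
#' Confusion summary for the decoy benchmark: a query counts as predicted
#' positive when it is identified as NCLDV and not excluded. The false
#' positive rate over decoys is the pipeline's headline soundness check
#' (the reference benchmark ran 612 non-NCLDV PolBs through the pipeline
#' and none were identified as NCLDV).
#'
#' @param calls A `taxonomy_calls` data frame.
#' @param truth Named character vector over all queries: `"ncldv"` or a
#'   decoy class (`"eukaryote"`, `"bacteria"`, `"archaea"`, `"phage"`).
#' @return List with `tp`, `fp`, `tn`, `fn`, `fpr` and `decoys_by_class`.
#' @export
benchmark_decoys <- function(calls, truth) {
  miss <- setdiff(calls$query, names(truth))
  if (length(miss))
    stop("queries without truth label: ", paste(utils::head(miss, 5), collapse = ", "))
  tr <- truth[calls$query]
  pos <- calls$decision == "NCLDV" & !calls$excluded
  is_ncldv <- tr == "ncldv"
  tp <- sum(pos & is_ncldv)
  fp <- sum(pos & !is_ncldv)
  tn <- sum(!pos & !is_ncldv)
  fn <- sum(!pos & is_ncldv)
  fpr <- if (fp + tn == 0) NA_real_ else fp / (fp + tn)
  list(tp = tp, fp = fp, tn = tn, fn = fn, fpr = fpr,
       decoys_by_class = table(tr[!is_ncldv]))
}
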