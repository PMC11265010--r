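#' Placement set
#'
#' Phylogenetic placements of query marker sequences onto a fixed,
#' edge-numbered reference tree (the jplace model). Each query carries
#' one or more candidate placements, each with an edge number and a
#' likelihood weight ratio; the best placement is the candidate with the
#' highest weight.
#'
#' @param tree An `ape::phylo` reference tree.
#' @param edge_map Data frame with columns `edge_num` and `node` mapping
#'   each jplace edge number to the child node of that branch.
#' @param placements Data frame with columns `name`, `edge_num`,
#'   `like_weight_ratio` (one row per candidate placement).
#' @return A list of class `placement_set` with elements `tree`,
#'   `edge_map`, `placements` and `best` (one row per query).
#' @export
placement_set <- function(tree, edge_map, placements) {
  stopifnot(inherits(tree, "phylo"),
            all(c("edge_num", "node") %in% colnames(edge_map)),
            all(c("name", "edge_num", "like_weight_ratio") %in%
                colnames(placements)))
  if (anyDuplicated(edge_map$edge_num))
    stop("duplicate edge numbers in edge map")
  bad <- setdiff(placements$edge_num, edge_map$edge_num)
  if (length(bad))
    stop("placement edge id(s) absent from tree: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!is.finite(placements$like_weight_ratio)))
    stop("non-finite like_weight_ratio")
  # best candidate per query; ties broken by first occurrence
  ord <- order(placements$name,
               -placements$like_weight_ratio,
               seq_len(nrow(placements)))
  p <- placements[ord, , drop = FALSE]
  best <- p[!duplicated(p$name), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(tree = tree, edge_map = edge_map,
                 placements = placements, best = best),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf("placement_set: %d queries, %d candidate placements, %d reference leaves\n",
              nrow(x$best), nrow(x$placements), length(x$tree$tip.label)))
  invisible(x)
}

# Rewrite an edge-numbered newick string ("...{12}...") into plain newick,
# tagging each branch's child node label with @@<edge_num> so that the
# numbers survive ape's parser; returns list(tree, edge_map).
parse_jplace_tree <- function(tree_string) {
  n_open <- lengths(regmatches(tree_string, gregexpr("\\{", tree_string)))
  n_close <- lengths(regmatches(tree_string, gregexpr("\\}", tree_string)))
  if (n_open != n_close) {
    pos <- regexpr("\\{[^}]*$", tree_string)
    stop("malformed edge braces in jplace tree near position ", pos)
  }
  tagged <- gsub("(:[0-9.eE+-]+)?\\{(\\d+)\\}", "@@\\2\\1", tree_string)
  if (grepl("\\{|\\}", tagged)) {
    pos <- regexpr("\\{|\\}", tagged)
    stop("malformed edge braces in jplace tree near position ", pos)
  }
  tree <- tryCatch(ape::read.tree(text = tagged),
                   error = function(e) stop("cannot parse jplace tree: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse jplace tree")
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label)
  hit <- regmatches(labs, regexpr("@@\\d+$", labs))
  has <- grepl("@@\\d+$", labs)
  edge_map <- data.frame(edge_num = as.integer(sub("@@", "", hit)),
                         node = which(has))
  tree$tip.label <- sub("@@\\d+$", "", tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- sub("@@\\d+$", "", tree$node.label)
    if (all(tree$node.label == "")) tree$node.label <- NULL
  }
  list(tree = tree, edge_map = edge_map)
}

#' Read a jplace placement file
#'
#' Parses the jplace (version 3) JSON dialect produced by pplacer and
#' friends: an edge-numbered newick tree (numbers in `{}` braces), a
#' `fields` vector that must contain `edge_num` and `like_weight_ratio`,
#' and a list of per-query placements.
#'
#' @param path Path to the jplace file.
#' @return A [placement_set()].
#' @export
read_jplace <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$tree) || is.null(j$fields) || is.null(j$placements))
    stop("not a jplace file: needs 'tree', 'fields', 'placements'")
  fields <- unlist(j$fields)
  for (f in c("edge_num", "like_weight_ratio"))
    if (!f %in% fields) stop("jplace 'fields' missing '", f, "'")
  i_edge <- match("edge_num", fields)
  i_lwr <- match("like_weight_ratio", fields)
  parsed <- parse_jplace_tree(j$tree)
  rows <- lapply(j$placements, function(pl) {
    nm <- if (!is.null(pl$n)) unlist(pl$n)[1] else unlist(pl$nm[[1]])[1]
    if (is.null(nm)) stop("placement without query name")
    do.call(rbind, lapply(pl$p, function(p)
      data.frame(name = nm,
                 edge_num = as.integer(p[[i_edge]]),
                 like_weight_ratio = as.numeric(p[[i_lwr]]))))
  })
  placements <- do.call(rbind, rows)
  placement_set(parsed$tree, parsed$edge_map, placements)
}

# newick writer with {edge_num} tags keyed by child node
edge_numbered_newick <- function(tree, edge_map) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- tree$edge.length
  bl_of <- numeric(n_tip + tree$Nnode)
  bl_of[tree$edge[, 2]] <- if (is.null(blen)) rep(1, nrow(tree$edge)) else blen
  tag <- character(n_tip + tree$Nnode)
  tag[edge_map$node] <- paste0("{", edge_map$edge_num, "}")
  rec <- function(node) {
    if (node <= n_tip) {
      paste0(tree$tip.label[node], ":", format(bl_of[node]), tag[node])
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, ""), collapse = ",")
      root <- node == n_tip + 1L
      paste0("(", inner, ")",
             if (root) "" else paste0(":", format(bl_of[node]), tag[node]))
    }
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Write a placement set as a jplace (version 3) file
#'
#' @param ps A [placement_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(ps, path) {
  stopifnot(inherits(ps, "placement_set"))
  pls <- lapply(split(ps$placements, ps$placements$name), function(d)
    list(p = unname(lapply(seq_len(nrow(d)), function(i)
           list(d$edge_num[i], d$like_weight_ratio[i]))),
         n = list(d$name[1])))
  obj <- list(version = 3,
              tree = edge_numbered_newick(ps$tree, ps$edge_map),
              fields = list("edge_num", "like_weight_ratio"),
              placements = unname(pls),
              metadata = list(invocation = "soilgv"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reference clade map
#'
#' Assigns every leaf of the reference tree to exactly one top-level
#' clade: either an NCLDV order/family clade or one of the outgroup
#' clades (eukaryote, bacteria, archaea, phage PolB sequences). Families
#' with cultivated representatives yield family-level taxonomy calls;
#' families with one or no cultivated representative (`has_rep = FALSE`)
#' yield order-level calls with an unassigned family.
#'
#' @param df Data frame with columns `leaf`, `group` (`"ncldv"` or
#'   `"outgroup"`), `order` (NCLDV order, or outgroup clade name),
#'   `family` (NCLDV family; `NA` for outgroups) and `has_rep` (logical;
#'   `NA` for outgroups).
#' @return `df`, validated and classed `clade_map`.
#' @export
clade_map <- function(df) {
  need <- c("leaf", "group", "order", "family", "has_rep")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clade map missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$leaf))
    stop("leaves assigned to more than one clade: ",
         paste(unique(df$leaf[duplicated(df$leaf)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("ncldv", "outgroup"))
  if (length(bad)) stop("unknown clade group(s): ", paste(bad, collapse = ", "))
  if (!any(df$group == "outgroup"))
    stop("clade map lacks outgroup clades")
  class(df) <- c("clade_map", "data.frame")
  df
}

#' Read a clade map from TSV
#'
#' @param path TSV with columns `leaf`, `group`, `order`, `family`,
#'   `has_rep`.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$has_rep <- as.logical(df$has_rep)
  clade_map(df)
}

#' Write a clade map to TSV
#'
#' @param cm A [clade_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(cm, path) {
  utils::write.table(as.data.frame(cm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
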