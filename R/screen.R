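#' Screen contigs for putative giant-virus origin
#'
#' A contig longer than `min_len` bp is accepted as a putative NCLDV
#' contig when any of three criteria fires: (1) flagged NCLDV-specific by
#' an automatic classifier, (2) carrying at least `ncvog_min` of the 20
#' ancestral core-gene markers (NCVOGs), or (3) carrying the NCLDV polB
#' gene (NCVOG0038). "Longer than" is strict (`length > min_len`).
#'
#' @param contigs Data frame with columns `contig_id`, `length`,
#'   `classifier_flag` (logical), `ncvog_count` (0..20), `polb_flag`
#'   (logical).
#' @param min_len Minimum length in bp (default 5000).
#' @param ncvog_min Marker-count criterion (default 2).
#' @return List with `accepted` (ids) and `audit` (data frame recording,
#'   per contig, which criteria fired).
#' @export
screen_contigs <- function(contigs, min_len = 5000, ncvog_min = 2) {
  need <- c("contig_id", "length", "classifier_flag", "ncvog_count", "polb_flag")
  miss <- setdiff(need, colnames(contigs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(contigs$length > 0), all(contigs$ncvog_count >= 0),
            all(contigs$ncvog_count <= 20))
  long_enough <- contigs$length > min_len
  c1 <- as.logical(contigs$classifier_flag)
  c2 <- contigs$ncvog_count >= ncvog_min
  c3 <- as.logical(contigs$polb_flag)
  accept <- long_enough & (c1 | c2 | c3)
  audit <- data.frame(contig_id = contigs$contig_id,
                      length_ok = long_enough,
                      by_classifier = long_enough & c1,
                      by_ncvog = long_enough & c2,
                      by_polb = long_enough & c3,
                      accepted = accept,
                      stringsAsFactors = FALSE)
  list(accepted = contigs$contig_id[accept], audit = audit)
}

#' Tally glycoside hydrolase (GH) annotations across genomes
#'
#' Counts GH genes per family, the number of distinct GH families, and
#' the number of genomes encoding at least one GH gene. Rows duplicated
#' on (genome, gene) are collapsed with a warning.
#'
#' @param annotations Data frame with columns `genome_id`, `gene_id`,
#'   `gh_family` (non-empty labels).
#' @return List with `genes_per_family` (table), `n_genes`, `n_families`,
#'   `n_genomes_with_gh`.
#' @export
tally_gh_families <- function(annotations) {
  need <- c("genome_id", "gene_id", "gh_family")
  miss <- setdiff(need, colnames(annotations))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(annotations) == 0)
    return(list(genes_per_family = table(character(0)), n_genes = 0L,
                n_families = 0L, n_genomes_with_gh = 0L))
  if (any(is.na(annotations$gh_family) | annotations$gh_family == ""))
    stop("GH family labels must be non-empty")
  key <- paste(annotations$genome_id, annotations$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicated (genome, gene) row(s) dropped")
    annotations <- annotations[!duplicated(key), , drop = FALSE]
  }
  list(genes_per_family = table(annotations$gh_family),
       n_genes = nrow(annotations),
       n_families = length(unique(annotations$gh_family)),
       n_genomes_with_gh = length(unique(annotations$genome_id)))
}
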