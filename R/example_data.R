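#' Worked-example survey occupancy data
#'
#' A compact presence/absence dataset reproducing the headline occupancy
#' structure of the 333-metagenome soil survey: 533 phylotypes over the
#' five habitat types, of which 381 occur in exactly one habitat (248 of
#' them only in mine wasteland, 82 of those affiliated with
#' Pithoviridae), 5 occur in all five habitats, and the remaining 147 in
#' two to four habitats. Abundances are presence indicators; the object
#' exists to exercise the occupancy summaries on the survey's reported
#' counts, not to reproduce coverage values.
#'
#' @return List with `coverage` (533 x 10 `coverage_matrix`, two samples
#'   per habitat), `samples` (`sample_table`) and `family` (named vector
#'   of family labels; `"unassigned"` where not relevant).
#' @export
occupancy_example <- function() {
  habs <- habitat_levels()
  samples <- validate_sample_table(data.frame(
    sample_id = paste0(rep(habs, each = 2), c("_a", "_b")),
    habitat = rep(habs, each = 2),
    read_count = 1e7, stringsAsFactors = FALSE))
  n_unique <- c(farmland = 60, forest = 50, grassland = 15, gobi = 8,
                mine = 248) # sums to 381
  multi <- list(two = 80, three = 47, four = 20) # the remaining 147
  n_total <- sum(n_unique) + 5 + sum(unlist(multi))
  stopifnot(n_total == 533)
  ids <- sprintf("pt%03d", seq_len(n_total))
  m <- matrix(0, n_total, nrow(samples),
              dimnames = list(ids, samples$sample_id))
  hab_of <- as.character(samples$habitat)
  i <- 0
  fam <- rep("unassigned", n_total)
  for (h in habs) {
    for (k in seq_len(n_unique[[h]])) {
      i <- i + 1
      m[i, hab_of == h] <- 1
    }
  }
  # 82 of the 248 mine-unique phylotypes are Pithoviridae
  mine_unique <- which(rowSums(m[, hab_of == "mine", drop = FALSE]) > 0 &
                         rowSums(m) == 2)
  fam[mine_unique[seq_len(82)]] <- "Pithoviridae"
  for (k in seq_len(5)) {
    i <- i + 1
    m[i, ] <- 1
  }
  spans <- rep(c(2, 3, 4), times = unlist(multi))
  for (s in spans) {
    i <- i + 1
    m[i, hab_of %in% habs[seq_len(s)]] <- 1
  }
  names(fam) <- ids
  list(coverage = coverage_matrix(m), samples = samples, family = fam)
}
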