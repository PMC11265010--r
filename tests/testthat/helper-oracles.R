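# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (direct formulas, explicit loops, full enumeration)
# and share no code with the package internals they check.

oracle_bray <- function(x, y) {
  if (sum(x + y) == 0) return(0)
  sum(abs(x - y)) / sum(x + y)
}

# average ranks from first principles
oracle_avg_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# pseudo-F from the Gower-centred inner-product matrix
oracle_pseudo_f <- function(d, groups) {
  groups <- factor(groups)
  n <- attr(stats::as.dist(d), "Size")
  D2 <- as.matrix(stats::as.dist(d))^2
  G <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, n)) -
                 outer(rep(1, n), colMeans(D2)) + mean(D2))
  H <- stats::model.matrix(~groups)
  H <- H %*% solve(crossprod(H)) %*% t(H)
  a <- nlevels(groups)
  ssa <- sum(diag(H %*% G))
  sst <- sum(diag(G))
  (ssa / (a - 1)) / ((sst - ssa) / (n - a))
}

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = k - 1L)
  out
}

oracle_permanova_exhaustive <- function(d, groups) {
  f_obs <- oracle_pseudo_f(d, groups)
  n <- attr(stats::as.dist(d), "Size")
  perms <- oracle_perms(n)
  f_perm <- vapply(perms, function(ix) {
    if (all(ix == seq_len(n))) return(NA_real_)
    oracle_pseudo_f(d, groups[ix])
  }, numeric(1))
  f_perm <- f_perm[!is.na(f_perm)]
  list(f = f_obs, p = (sum(f_perm >= f_obs) + 1) / (length(f_perm) + 1))
}

# mean accumulation curve over all sample orderings (n small)
oracle_rarefaction <- function(pres) {
  n <- ncol(pres)
  perms <- oracle_perms(n)
  acc <- matrix(0, length(perms), n)
  for (r in seq_along(perms)) {
    seen <- rep(FALSE, nrow(pres))
    for (k in seq_len(n)) {
      seen <- seen | pres[, perms[[r]][k]]
      acc[r, k] <- sum(seen)
    }
  }
  colMeans(acc)
}

# ends-free pairwise alignment (match +1, mismatch -1, gap -2), diagonal-
# preferring traceback; identity over overlap columns, coverage of shorter
oracle_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    cand <- c(S[i - 1, j - 1] + if (A[i - 1] == B[j - 1]) 1 else -1,
              S[i - 1, j] - 2, S[i, j - 1] - 2)
    P[i, j] <- which.max(cand)
    S[i, j] <- max(cand)
  }
  ends <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n + 1), m + 1))
  e <- ends[which.max(S[ends]), ]
  i <- e[1]; j <- e[2]
  matches <- 0L; cols <- 0L; ai <- 0L; bi <- 0L
  while (i > 1 && j > 1) {
    p <- P[i, j]
    cols <- cols + 1L
    if (p == 1) {
      matches <- matches + (A[i - 1] == B[j - 1])
      ai <- ai + 1L; bi <- bi + 1L; i <- i - 1; j <- j - 1
    } else if (p == 2) {
      ai <- ai + 1L; i <- i - 1
    } else {
      bi <- bi + 1L; j <- j - 1
    }
  }
  list(identity = if (cols == 0) 0 else matches / cols,
       coverage_short = (if (n <= m) ai else bi) / min(n, m))
}

oracle_greedy_cluster <- function(seqs, identity_min = 0.95, overlap_min = 0.90) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  names(assign) <- names(seqs)
  for (i in seq_along(seqs)) {
    hitrep <- NA_character_
    for (r in reps) {
      h <- oracle_align(seqs[[r]], seqs[[i]])
      if (h$identity > identity_min && h$coverage_short > overlap_min) {
        hitrep <- r
        break
      }
    }
    if (is.na(hitrep)) {
      reps <- c(reps, names(seqs)[i])
      assign[names(seqs)[i]] <- names(seqs)[i]
    } else assign[names(seqs)[i]] <- hitrep
  }
  assign
}

# random sequences and mutated families for clustering fixtures
random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_sub) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# small deterministic survey fixture reused across tests
toy_survey <- function(seed = 42, ...) {
  simulate_community(n_phylotypes = 60,
                     sites_per_habitat = c(farmland = 3, forest = 3,
                                           grassland = 2, gobi = 2, mine = 4),
                     samples_per_site = 2, seed = seed, ...)
}
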