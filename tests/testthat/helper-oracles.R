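# Independent brute-force oracles and random-fixture generators. These stay
# deliberately naive (character-by-character loops, path intersections,
# closed-form arithmetic) so they share no code with the implementation.

BASES <- c("A", "C", "G", "T")

# Random aligned matrix with optional gap/ambiguity contamination.
random_alignment_chars <- function(n_seq, n_sites, messy_prob = 0.1) {
  pool <- c(BASES, if (messy_prob > 0) c("-", "N", "?", "R", "Y", "W"))
  probs <- c(rep((1 - messy_prob) / 4, 4),
             if (messy_prob > 0) rep(messy_prob / 6, 6))
  mat <- matrix(sample(pool, n_seq * n_sites, replace = TRUE, prob = probs),
                nrow = n_seq)
  rownames(mat) <- sprintf("t%02d", seq_len(n_seq))
  mat
}

# Double-loop recount of the pairwise-deletion p-distance.
oracle_p <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- 0L; mism <- 0L
  for (i in seq_along(a)) {
    ca <- a[i]; cb <- b[i]
    if (ca %in% BASES && cb %in% BASES) {
      n <- n + 1L
      if (ca != cb) mism <- mism + 1L
    }
  }
  if (n == 0L) list(p = NA_real_, n = 0L) else list(p = mism / n, n = n)
}

# Complete-deletion oracle: drop every column containing any non-ACGT symbol
# in ANY row, then count mismatches on what is left.
oracle_p_complete_deletion <- function(mat, i, j) {
  keep <- apply(mat, 2, function(col) all(col %in% BASES))
  a <- mat[i, keep]; b <- mat[j, keep]
  if (!length(a)) return(NA_real_)
  sum(a != b) / length(a)
}

# Root-to-tip node paths of an ape tree, by walking the edge table.
tip_paths <- function(phy) {
  ntip <- length(phy$tip.label)
  parent_of <- integer(max(phy$edge))
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  lapply(seq_len(ntip), function(t) {
    path <- t
    node <- t
    root <- ntip + 1L
    while (node != root) {
      node <- parent_of[node]
      path <- c(node, path)
    }
    path
  })
}

# Path-intersection oracle for the divergence time of two tips: the MRCA is
# the last node shared by the two root-to-tip paths; its age is the sum of
# edge lengths from it down to either tip.
oracle_pair_time <- function(phy, a, b) {
  labs <- phy$tip.label
  ia <- match(a, labs); ib <- match(b, labs)
  paths <- tip_paths(phy)
  pa <- paths[[ia]]; pb <- paths[[ib]]
  shared <- pa[pa %in% pb]
  m <- shared[length(shared)]
  elen <- numeric(max(phy$edge))
  elen[phy$edge[, 2]] <- phy$edge.length
  idx <- match(m, pa)
  sum(elen[pa[(idx + 1):length(pa)]])
}

# Grid-search minimiser of the residual sum of squares for a line, as an
# independent check on the least-squares coefficients.
oracle_ols_grid <- function(x, y, through_origin = FALSE) {
  sx <- mean(x); sy <- mean(y)
  if (through_origin) {
    b0 <- sum(x * y) / sum(x^2)
    grid <- seq(b0 - 1, b0 + 1, length.out = 4001)
    ss <- vapply(grid, function(b) sum((y - b * x)^2), 0)
    list(slope = grid[which.min(ss)], intercept = 0)
  } else {
    sxx <- sum((x - sx)^2)
    b <- sum((x - sx) * (y - sy)) / sxx
    a <- sy - b * sx
    list(slope = b, intercept = a)
  }
}

# Exhaustive labelled-pair enumeration of species-pair percent ranges.
oracle_ranges <- function(pmat, sp_of, a, b, decimals = 1L) {
  tips <- rownames(pmat)
  ta <- tips[sp_of[tips] == a]
  tb <- tips[sp_of[tips] == b]
  vals <- c()
  for (x in ta) for (y in tb) {
    if (x < y || a != b) vals <- c(vals, pmat[x, y])
  }
  if (a == b) {
    vals <- c()
    for (i in seq_along(ta)) for (j in seq_along(ta)) {
      if (i < j) vals <- c(vals, pmat[ta[i], ta[j]])
    }
  }
  vals <- vals[!is.na(vals)]
  pct <- sign(vals) * floor(abs(100 * vals) * 10^decimals + 0.5) / 10^decimals
  c(min = min(pct), max = max(pct))
}

make_alignment <- function(mat) alignment(mat)
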