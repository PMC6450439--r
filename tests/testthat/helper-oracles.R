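# Independent brute-force oracles, deliberately written with plain loops
# and formulas so they share no code path with the package.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    candidates <- numeric(0)
    for (j in i:n) {
      candidates <- c(candidates, p[o[j]] * n / j)
    }
    q_sorted[i] <- min(1, min(candidates))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

oracle_global_score <- function(t) {
  total <- 0
  for (v in t) total <- total + v * v
  sqrt(total / length(t))
}

oracle_directed_score <- function(t) {
  total <- 0
  for (v in t) total <- total + sign(v) * v * v
  s <- total / length(t)
  if (s < 0) -sqrt(-s) else sqrt(s)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# naive average-linkage agglomeration over an explicit distance matrix;
# returns the sorted vector of merge heights
oracle_upgma_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  active <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        dij <- mean(d[active[[i]], active[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# PC1 scores via an explicit eigen-decomposition of the sample covariance
# of the per-gene Z-scaled matrix, oriented and Z-scaled like pathway_z
oracle_pc1 <- function(mat) {
  z <- t(apply(mat, 1, function(r) (r - mean(r)) / sd(r)))
  x <- t(z)
  x <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(x), symmetric = TRUE)
  loading <- ev$vectors[, 1]
  if (mean(loading) < 0) loading <- -loading
  scores <- as.numeric(x %*% loading)
  (scores - mean(scores)) / sd(scores)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcoxon <- function(case, reference) {
  values <- c(case, reference)
  m <- length(case)
  r <- rank(values)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(values), m)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# reference Markov clustering: dense loops, no pruning, attractor-based
# cluster extraction -- independent of mcl_cluster's implementation
oracle_mcl <- function(edges, inflation = 1.5, iters = 500, tol = 1e-10) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(genes)
  a <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$gene_a[k], genes)
    j <- match(edges$gene_b[k], genes)
    a[i, j] <- edges$combined_score[k]
    a[j, i] <- edges$combined_score[k]
  }
  for (i in seq_len(n)) a[i, i] <- max(a[i, ])
  m <- a
  for (j in seq_len(n)) m[, j] <- m[, j] / sum(m[, j])
  for (it in seq_len(iters)) {
    m2 <- (m %*% m)^inflation
    for (j in seq_len(n)) m2[, j] <- m2[, j] / sum(m2[, j])
    if (max(abs(m2 - m)) < tol) {
      m <- m2
      break
    }
    m <- m2
  }
  reach <- (m > 1e-6) | (t(m) > 1e-6)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      v <- frontier[1]
      frontier <- frontier[-1]
      for (w in which(reach[v, ])) {
        if (comp[w] == 0) {
          comp[w] <- cur
          frontier <- c(frontier, w)
        }
      }
    }
  }
  unname(lapply(split(genes, comp), sort))
}

# exact null distribution of the Mann-Whitney U statistic by the classic
# counting recurrence N(k; m, n) = N(k - n; m - 1, n) + N(k; m, n - 1)
oracle_u_distribution <- function(m, n) {
  memo <- new.env()
  count <- function(mm, nn, k) {
    if (k < 0) return(0)
    if (mm == 0 || nn == 0) return(as.numeric(k == 0))
    key <- paste(mm, nn, k)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- count(mm - 1, nn, k - nn) + count(mm, nn - 1, k)
    memo[[key]] <- val
    val
  }
  ks <- 0:(m * n)
  counts <- vapply(ks, function(k) count(m, n, k), 0)
  counts / sum(counts)
}

oracle_wilcoxon_dp <- function(case, reference) {
  m <- length(case); n <- length(reference)
  u <- sum(outer(case, reference, `>`)) + 0.5 * sum(outer(case, reference,
                                                          `==`))
  dist <- oracle_u_distribution(m, n)
  ks <- 0:(m * n)
  min(1, 2 * min(sum(dist[ks <= u]), sum(dist[ks >= u])))
}

# canonical form of a partition for comparison
partition_key <- function(clusters) {
  sets <- lapply(clusters, function(x) paste(sort(x), collapse = ","))
  paste(sort(unlist(sets)), collapse = ";")
}
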