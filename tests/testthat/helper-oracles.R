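# Independent brute-force oracles used to validate the package's
# neighborhood-metric implementations. Deliberately written from the
# defining formulas with different algorithms (subset enumeration,
# Kruskal's MST) than the implementation (analytic hypergeometric form,
# Prim's MST).

# expected rarefied richness by exhaustive enumeration of all n-subsets
bruteRarefaction <- function(abundances, n) {
  ids <- rep(seq_along(abundances), abundances)
  subs <- utils::combn(length(ids), n)
  mean(apply(subs, 2, function(ix) length(unique(ids[ix]))))
}

# Kruskal MST with union-find; returns edge list (i, j, d)
kruskalMST <- function(dmat) {
  S <- nrow(dmat)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  ord <- order(dmat[pairs], pairs[, 1], pairs[, 2])
  parent <- seq_len(S)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- NULL
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, c(i, j, dmat[i, j]))
      if (nrow(edges) == S - 1) break
    }
  }
  edges
}

bruteFEve <- function(traits, abundances) {
  traits <- as.matrix(traits)
  S <- nrow(traits)
  if (S < 3) return(NA_real_)
  w <- abundances / sum(abundances)
  dmat <- as.matrix(stats::dist(traits))
  edges <- kruskalMST(dmat)
  ew <- edges[, 3] / (w[edges[, 1]] + w[edges[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

bruteFDis <- function(traits, abundances) {
  traits <- as.matrix(traits)
  w <- abundances / sum(abundances)
  centroid <- as.numeric(t(traits) %*% w)
  mean_dist <- apply(traits, 1, function(r) sqrt(sum((r - centroid)^2)))
  sum(w * mean_dist)
}

# random neighborhood generator for oracle comparisons
randomNeighborhood <- function(n_species, n_traits = 3) {
  list(traits = matrix(rnorm(n_species * n_traits), n_species, n_traits),
       abund = sample(1:20, n_species, replace = TRUE))
}
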