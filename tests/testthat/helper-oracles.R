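# Independent naive-loop oracles for the phylogenetic community statistics.
# These deliberately share no code with the package implementations: plain
# double loops over taxon indices, computed from first principles.

naiveMPD <- function(ab, d, weighted = TRUE) {
  p <- which(ab > 0)
  if (length(p) < 2) return(NA_real_)
  num <- den <- 0
  for (i in p) for (j in p) {
    if (i == j) next
    w <- if (weighted) ab[i] * ab[j] else 1
    num <- num + w * d[i, j]
    den <- den + w
  }
  unname(num / den)
}

naiveMNTD <- function(ab, d, weighted = TRUE) {
  p <- which(ab > 0)
  if (length(p) < 2) return(NA_real_)
  num <- den <- 0
  for (i in p) {
    m <- Inf
    for (j in p) if (j != i && d[i, j] < m) m <- d[i, j]
    w <- if (weighted) ab[i] else 1
    num <- num + w * m
    den <- den + w
  }
  unname(num / den)
}

naiveBetaMNTD <- function(a, b, d, weighted = TRUE) {
  pa <- which(a > 0); pb <- which(b > 0)
  if (!length(pa) || !length(pb)) return(NA_real_)
  dirMean <- function(p1, p2, ab1) {
    num <- den <- 0
    for (i in p1) {
      m <- Inf
      for (j in p2) if (d[i, j] < m) m <- d[i, j]
      w <- if (weighted) ab1[i] else 1
      num <- num + w * m
      den <- den + w
    }
    num / den
  }
  unname((dirMean(pa, pb, a) + dirMean(pb, pa, b)) / 2)
}

# patristic distance oracle: depth(i) + depth(j) - 2 * depth(MRCA)
naivePatristic <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) d[i, j] <- depth[i] + depth[j] - 2 * depth[mrca[i, j]]
  d
}

# random rooted tree with branch lengths for property tests
randomTestTree <- function(nTips) {
  tr <- ape::rtree(nTips)
  tr$tip.label <- paste0("t", seq_len(nTips))
  tr
}

# small multinomial community matrix on a tree's taxa
randomCommunity <- function(nSamples, tree, nIndividuals = 200,
                            sdlog = 1) {
  nt <- length(tree$tip.label)
  meta <- stats::rlnorm(nt, 0, sdlog)
  meta <- meta / sum(meta)
  comm <- t(stats::rmultinom(nSamples, nIndividuals, meta))
  dimnames(comm) <- list(paste0("s", seq_len(nSamples)), tree$tip.label)
  comm
}
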