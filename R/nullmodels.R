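#' Mean pairwise phylogenetic distance of one community
#'
#' Unweighted: the mean patristic distance over all unordered pairs of
#' distinct taxa present in the sample. Abundance-weighted (the default,
#' as used for the net relatedness index): pair distances are weighted by
#' the product of the two taxa's abundances,
#' sum_(i != j) a_i a_j d_ij / sum_(i != j) a_i a_j.
#'
#' @param abund numeric abundance vector; if named, names are matched to
#'   \code{rownames(dis)}, otherwise positions are used.
#' @param dis symmetric patristic distance matrix (see
#'   [patristicDistances()]).
#' @param weighted abundance-weight the statistic (default \code{TRUE}).
#' @return the MPD, or \code{NA} when fewer than two taxa are present.
#' @export
mpd <- function(abund, dis, weighted = TRUE) {
  v <- .alignAbund(abund, dis)
  p <- which(v > 0)
  if (length(p) < 2L) return(NA_real_)
  ds <- dis[p, p, drop = FALSE]
  if (weighted) {
    f <- v[p] / sum(v[p])
    drop(f %*% ds %*% f) / (1 - sum(f * f))
  } else {
    s <- length(p)
    sum(ds) / (s * (s - 1))
  }
}

#' Mean nearest taxon distance of one community
#'
#' For each taxon present, the patristic distance to its nearest present
#' relative; averaged plainly (unweighted) or weighted by the focal
#' taxon's abundance (default, as used for the nearest taxon index).
#'
#' @inheritParams mpd
#' @return the MNTD, or \code{NA} when fewer than two taxa are present.
#' @export
mntd <- function(abund, dis, weighted = TRUE) {
  v <- .alignAbund(abund, dis)
  p <- which(v > 0)
  if (length(p) < 2L) return(NA_real_)
  ds <- dis[p, p, drop = FALSE]
  diag(ds) <- Inf
  mins <- .rowMins(ds)
  if (weighted) stats::weighted.mean(mins, v[p]) else mean(mins)
}

#' Between-community mean nearest taxon distance
#'
#' For every taxon present in sample a, the distance to its nearest taxon
#' present in sample b, and vice versa; the two directional
#' (abundance-weighted) means are averaged, making the measure symmetric.
#' Identical communities have beta-MNTD zero because each taxon's nearest
#' cross-community relative is itself.
#'
#' @param a,b abundance vectors on the same taxon set as \code{dis}.
#' @inheritParams mpd
#' @return beta-MNTD, or \code{NA} if either sample is empty.
#' @export
betaMNTD <- function(a, b, dis, weighted = TRUE) {
  a <- .alignAbund(a, dis); b <- .alignAbund(b, dis)
  pa <- which(a > 0); pb <- which(b > 0)
  if (!length(pa) || !length(pb)) return(NA_real_)
  minsA <- .rowMins(dis[pa, pb, drop = FALSE])
  minsB <- .rowMins(dis[pb, pa, drop = FALSE])
  if (weighted)
    mean(c(stats::weighted.mean(minsA, a[pa]),
           stats::weighted.mean(minsB, b[pb])))
  else mean(c(mean(minsA), mean(minsB)))
}

#' Between-community mean pairwise distance
#'
#' The comdist-style variant of phylogenetic turnover: the
#' (abundance-weighted) mean patristic distance over all cross-community
#' taxon pairs, shared taxa contributing zero-distance pairs. Provided as
#' an alternative basis for the turnover standardized effect size (see
#' \code{betaMetric} in [assemblyNullModels()]); the nearest-taxon form
#' [betaMNTD()] is the default.
#'
#' @inheritParams betaMNTD
#' @return beta-MPD, or \code{NA} if either sample is empty.
#' @export
betaMPD <- function(a, b, dis, weighted = TRUE) {
  a <- .alignAbund(a, dis); b <- .alignAbund(b, dis)
  pa <- which(a > 0); pb <- which(b > 0)
  if (!length(pa) || !length(pb)) return(NA_real_)
  ds <- dis[pa, pb, drop = FALSE]
  if (weighted) {
    fa <- a[pa] / sum(a[pa]); fb <- b[pb] / sum(b[pb])
    drop(fa %*% ds %*% fb)
  } else mean(ds)
}

#' Pairwise beta-MNTD (or beta-MPD) matrix for a pool of samples
#'
#' @param comm sample x taxon abundance matrix (rows are samples).
#' @param dis patristic distance matrix over (at least) the community's
#'   taxa; matched by name when both are named.
#' @param weighted abundance-weight the statistic.
#' @param metric \code{"bmntd"} (nearest-taxon, default) or \code{"bmpd"}.
#' @return symmetric matrix of pairwise turnover, zero diagonal.
#' @export
betaMNTDMatrix <- function(comm, dis, weighted = TRUE,
                           metric = c("bmntd", "bmpd")) {
  metric <- match.arg(metric)
  comm <- .alignComm(comm, dis)
  .betaMatrixCore(comm, dis, weighted, metric)
}

# positional core shared with the null iterations; comm columns must align
# with dis rows.
.betaMatrixCore <- function(comm, dis, weighted, metric) {
  k <- nrow(comm)
  pres <- comm > 0
  fw <- if (weighted) comm else pres * 1
  fw <- fw / rowSums(fw)
  if (metric == "bmpd") {
    dd <- fw %*% dis %*% t(fw)
    bm <- (dd + t(dd)) / 2
    diag(bm) <- 0
  } else {
    bm <- cpp_bmntd(fw, pres, unname(dis))
  }
  dimnames(bm) <- list(rownames(comm), rownames(comm))
  bm
}

#' Shuffle taxon labels of a distance matrix
#'
#' The "taxa labels" null model: taxon identifiers are permuted uniformly
#' at random across the pool's distance matrix, leaving the multiset of
#' distance values untouched. This is the randomization behind the
#' 999-iteration null distributions for NRI/NTI and beta-NTI.
#'
#' @param dis named symmetric distance matrix.
#' @param perm optional integer permutation (defaults to a uniform draw
#'   from the current RNG stream); position i receives the label formerly
#'   at position \code{perm[i]}.
#' @return the relabeled matrix, rows/columns re-sorted to the original
#'   label order.
#' @export
taxaShuffle <- function(dis, perm = NULL) {
  labs <- rownames(dis)
  if (is.null(perm)) perm <- sample.int(nrow(dis))
  out <- dis
  dimnames(out) <- list(labs[perm], labs[perm])
  out[labs, labs, drop = FALSE]
}

#' Standardized effect size of MPD or MNTD for one sample
#'
#' Computes the observed metric and its null distribution over
#' \code{nIter} taxa-shuffle randomizations, returning
#' ses = (observed - null mean) / null sd and the conventional index
#' NRI or NTI = -ses, so that index values above +2 indicate communities
#' more phylogenetically clustered than expected by chance and values
#' below -2 indicate overdispersion.
#'
#' @inheritParams mpd
#' @param metric \code{"mpd"} (yielding NRI) or \code{"mntd"} (NTI).
#' @param nIter number of randomizations (default 999).
#' @return one-row \code{data.frame} with columns \code{metric},
#'   \code{observed}, \code{null_mean}, \code{null_sd}, \code{ses},
#'   \code{index}, \code{n_iter}. A degenerate null (sd = 0) yields
#'   \code{NA} ses with a warning, never infinity.
#' @export
sesMetric <- function(abund, dis, metric = c("mpd", "mntd"),
                      weighted = TRUE, nIter = 999) {
  metric <- match.arg(metric)
  comm <- matrix(.alignAbund(abund, dis), nrow = 1,
                 dimnames = list("sample", rownames(dis)))
  res <- sesByPool(comm, dis, metric = metric, weighted = weighted,
                   nIter = nIter)
  res[, setdiff(names(res), "sample_id")]
}

#' Standardized effect sizes for a pool of samples
#'
#' As [sesMetric()], but evaluates every sample of a pool against a
#' shared permutation stream: each iteration applies one taxa shuffle of
#' the pool's distance matrix to all samples, as the weekly
#' per-compartment null pools require.
#'
#' @inheritParams betaMNTDMatrix
#' @param metric \code{"mpd"} or \code{"mntd"}.
#' @param nIter number of randomizations.
#' @return \code{data.frame} with one row per sample (columns as in
#'   [sesMetric()] plus \code{sample_id}).
#' @export
sesByPool <- function(comm, dis, metric = c("mpd", "mntd"), weighted = TRUE,
                      nIter = 999) {
  metric <- match.arg(metric)
  comm <- .alignComm(comm, dis)
  k <- nrow(comm)
  nt <- ncol(comm)
  obs <- .poolMetric(comm, dis, metric, weighted)
  nulls <- matrix(NA_real_, nIter, k)
  for (it in seq_len(nIter)) {
    perm <- sample.int(nt)
    nulls[it, ] <- .poolMetric(comm[, order(perm), drop = FALSE], dis,
                               metric, weighted)
  }
  nullMean <- colMeans(nulls)
  nullSd <- apply(nulls, 2L, stats::sd)
  ses <- ifelse(is.na(nullSd) | nullSd == 0, NA_real_,
                (obs - nullMean) / nullSd)
  if (any(!is.na(obs) & (is.na(nullSd) | nullSd == 0)))
    warning("degenerate null (sd = 0) for ", metric,
            "; ses undefined for affected sample(s)")
  data.frame(sample_id = rownames(comm), metric = metric, observed = obs,
             null_mean = nullMean, null_sd = nullSd, ses = ses,
             index = -ses, n_iter = nIter, row.names = NULL)
}

.poolMetric <- function(comm, dis, metric, weighted) {
  if (metric == "mpd") {
    f <- if (weighted) comm else (comm > 0) * 1
    f <- f / rowSums(f)
    num <- rowSums((f %*% dis) * f)
    den <- 1 - rowSums(f * f)
    out <- num / den
    out[rowSums(comm > 0) < 2L] <- NA_real_
    unname(out)
  } else {
    cpp_pool_mntd(comm, unname(dis), weighted)
  }
}

#' Beta nearest taxon index for a pool of samples
#'
#' For every unordered sample pair within the pool,
#' beta-NTI = (observed beta-MNTD - null mean) / null sd, the null being
#' \code{nIter} taxa shuffles of the pool's distance matrix. One shared
#' permutation stream serves the whole pool: each iteration evaluates all
#' pairs on the same shuffled matrix, so results are reproducible and
#' independent of pair order. Values above +2 indicate significantly more
#' phylogenetic turnover than expected (heterogeneous selection), below
#' -2 significantly less (homogeneous selection).
#'
#' @inheritParams betaMNTDMatrix
#' @param nIter number of randomizations (default 999).
#' @return list with symmetric matrices \code{beta_mntd_obs},
#'   \code{null_mean}, \code{null_sd}, \code{beta_nti}, and \code{n_iter}.
#'   Pairs with a degenerate null get \code{NA} with a warning.
#' @export
betaNTI <- function(comm, dis, weighted = TRUE, nIter = 999,
                    metric = c("bmntd", "bmpd")) {
  metric <- match.arg(metric)
  comm <- .alignComm(comm, dis)
  k <- nrow(comm)
  if (k < 2L) stop("pool must contain at least two samples")
  nt <- ncol(comm)
  lower <- which(lower.tri(matrix(0, k, k)))
  obs <- .betaMatrixCore(comm, dis, weighted, metric)
  nulls <- matrix(NA_real_, nIter, length(lower))
  for (it in seq_len(nIter)) {
    perm <- sample.int(nt)
    bm <- .betaMatrixCore(comm[, order(perm), drop = FALSE], dis,
                          weighted, metric)
    nulls[it, ] <- bm[lower]
  }
  nullMean <- colMeans(nulls)
  nullSd <- apply(nulls, 2L, stats::sd)
  sesV <- ifelse(nullSd == 0, NA_real_, (obs[lower] - nullMean) / nullSd)
  if (any(nullSd == 0))
    warning("degenerate null (sd = 0) for ", sum(nullSd == 0),
            " sample pair(s); beta-NTI undefined there")
  toMat <- function(v) {
    m <- matrix(NA_real_, k, k, dimnames = dimnames(obs))
    m[lower] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    diag(m) <- NA_real_
    m
  }
  list(beta_mntd_obs = obs, null_mean = toMat(nullMean),
       null_sd = toMat(nullSd), beta_nti = toMat(sesV), n_iter = nIter,
       metric = metric)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' 1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b)); lies in [0, 1] and is
#' invariant to rescaling both samples by a common positive constant.
#'
#' @param a,b non-negative abundance vectors on the same taxon set.
#' @return dissimilarity in [0, 1]; identical samples give 0, samples
#'   with disjoint support give 1.
#' @export
brayCurtis <- function(a, b) {
  if (length(a) != length(b)) stop("samples must share a taxon set")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  ta <- sum(a); tb <- sum(b)
  if (ta == 0 && tb == 0) stop("both samples are empty")
  1 - 2 * sum(pmin(a, b)) / (ta + tb)
}

#' Pairwise Bray-Curtis matrix
#'
#' @param comm sample x taxon abundance matrix.
#' @return symmetric dissimilarity matrix (via \code{vegan::vegdist}).
#' @export
brayCurtisMatrix <- function(comm) {
  as.matrix(vegan::vegdist(comm, method = "bray"))
}

#' Bray-Curtis-based Raup-Crick null (RC-bray)
#'
#' For every unordered sample pair in the pool, compares the observed
#' Bray-Curtis dissimilarity with \code{nIter} null realizations that
#' preserve each sample's observed richness and total abundance: each
#' null community draws its species without replacement with probability
#' proportional to occupancy across the pool (optionally occupancy times
#' mean relative abundance), then allocates its individuals to the drawn
#' species with probability proportional to pool-wide relative abundance.
#' RC = 2 * ((n_less + 0.5 * n_ties) / nIter) - 1, so +1 means the pair
#' is more dissimilar than essentially all null realizations (dispersal
#' limitation territory) and -1 less dissimilar (homogenizing dispersal).
#'
#' Because the null allocates discrete individuals, non-integer (e.g.
#' spike-normalized) tables are first rescaled so each sample totals at
#' least \code{abundanceFloor} individuals and rounded, keeping every
#' originally present taxon at count >= 1 so observed richness is
#' preserved.
#'
#' @param comm sample x taxon abundance matrix (the pool's members).
#' @param nIter number of null realizations (default 999).
#' @param speciesWeighting probability used for the species draw:
#'   \code{"occupancy"} (default) or \code{"occupancy_abundance"}.
#' @param abundanceFloor minimum per-sample total used when integerizing
#'   non-integer tables (default 1000).
#' @return list with symmetric matrices \code{rc_bray} and
#'   \code{bray_curtis_obs}, plus \code{n_iter}.
#' @export
raupCrickBray <- function(comm, nIter = 999,
                          speciesWeighting = c("occupancy",
                                               "occupancy_abundance"),
                          abundanceFloor = 1000) {
  speciesWeighting <- match.arg(speciesWeighting)
  comm <- as.matrix(comm)
  if (any(comm < 0)) stop("abundances must be non-negative")
  k <- nrow(comm)
  if (k < 2L) stop("pool must contain at least two samples")
  if (any(rowSums(comm) == 0)) stop("empty sample(s) in community matrix")
  counts <- .integerize(comm, abundanceFloor)
  occupied <- colSums(counts > 0) > 0
  if (sum(occupied) < 2L)
    stop("degenerate pool: fewer than two taxa occur across its samples")
  counts <- counts[, occupied, drop = FALSE]
  occ <- colSums(counts > 0)
  poolAb <- colSums(counts)
  relAb <- poolAb / sum(poolAb)
  sw <- if (speciesWeighting == "occupancy") occ else occ * relAb
  richness <- rowSums(counts > 0)
  totals <- rowSums(counts)
  obs <- brayCurtisMatrix(counts)
  lower <- which(lower.tri(obs))
  obsV <- obs[lower]
  eps <- 1e-10
  nt <- ncol(counts)
  nLess <- nEq <- numeric(length(lower))
  nullComm <- matrix(0L, k, nt)
  for (it in seq_len(nIter)) {
    nullComm[] <- 0L
    for (s in seq_len(k)) {
      drawn <- sample.int(nt, richness[[s]], prob = sw)
      alloc <- stats::rmultinom(1L, totals[[s]] - richness[[s]],
                                relAb[drawn])[, 1L]
      nullComm[s, drawn] <- 1L + alloc
    }
    nullV <- brayCurtisMatrix(nullComm)[lower]
    nLess <- nLess + (nullV < obsV - eps)
    nEq <- nEq + (abs(nullV - obsV) <= eps)
  }
  rcV <- 2 * ((nLess + 0.5 * nEq) / nIter) - 1
  rc <- matrix(NA_real_, k, k, dimnames = dimnames(obs))
  rc[lower] <- rcV
  rc[upper.tri(rc)] <- t(rc)[upper.tri(rc)]
  list(rc_bray = rc, bray_curtis_obs = obs, n_iter = nIter)
}

.integerize <- function(comm, floor) {
  if (all(comm == round(comm)))
    return(comm)
  t(apply(comm, 1L, function(x) {
    tot <- sum(x)
    if (tot == 0) return(x)
    scale <- max(1, floor / tot)
    y <- round(x * scale)
    y[x > 0] <- pmax(y[x > 0], 1)
    y
  }))
}

#' Split samples into null-model pools
#'
#' Null distributions are generated per pool — by default one pool per
#' compartment and week, following the weekly per-compartment design.
#'
#' @param metadata sample metadata with \code{sample_id} and the grouping
#'   columns.
#' @param groupBy grouping columns (default \code{compartment}, \code{week}).
#' @return named list of sample-ID vectors, one element per pool; each
#'   sample belongs to exactly one pool.
#' @export
makePools <- function(metadata, groupBy = c("compartment", "week")) {
  miss <- setdiff(groupBy, names(metadata))
  if (length(miss))
    stop("metadata missing grouping column(s): ", paste(miss, collapse = ", "))
  key <- interaction(metadata[groupBy], drop = TRUE, lex.order = TRUE,
                     sep = ".")
  split(as.character(metadata$sample_id), key)
}

#' Deterministic per-pool RNG sub-seed
#'
#' Derives a reproducible 32-bit seed from a master seed and a pool key,
#' so pools are independent units of work whose results do not depend on
#' execution order.
#'
#' @param seed master integer seed.
#' @param key pool identifier string (e.g. \code{"rhizosphere.4"}).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
poolSeed <- function(seed, key) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(key))) s <- (s * 131 + c) %% m
  as.integer(s + 1)
}

.alignAbund <- function(abund, dis) {
  v <- as.numeric(abund)
  if (!is.null(names(abund)) && !is.null(rownames(dis))) {
    idx <- match(rownames(dis), names(abund))
    v <- ifelse(is.na(idx), 0, as.numeric(abund)[idx])
  } else if (length(v) != nrow(dis))
    stop("abundance vector length does not match distance matrix")
  if (any(v < 0)) stop("abundances must be non-negative")
  v
}

.alignComm <- function(comm, dis) {
  comm <- as.matrix(comm)
  if (!is.null(colnames(comm)) && !is.null(rownames(dis))) {
    miss <- setdiff(colnames(comm), rownames(dis))
    if (length(miss))
      stop("taxa missing from distance matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    full <- matrix(0, nrow(comm), nrow(dis),
                   dimnames = list(rownames(comm), rownames(dis)))
    full[, colnames(comm)] <- comm
    comm <- full
  } else if (ncol(comm) != nrow(dis))
    stop("community matrix columns do not match distance matrix")
  if (any(comm < 0)) stop("abundances must be non-negative")
  if (any(rowSums(comm) == 0)) stop("empty sample(s) in community matrix")
  comm
}

# row minima via iterated pmin: fast C-level passes, no extra deps
.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  r <- m[, 1L]
  for (j in 2:ncol(m)) r <- pmin(r, m[, j])
  r
}
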