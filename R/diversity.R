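#' Pielou's evenness
#'
#' J = H' / ln(S), with H' the Shannon entropy (natural log) over taxa with
#' positive abundance and S the observed richness. Invariant to rescaling
#' the abundances. For S = 1 the index is 0/0 and \code{NaN} is returned
#' (single-taxon samples are excluded from group means rather than counted
#' as perfectly uneven).
#'
#' @param x numeric vector of non-negative abundances for one sample.
#' @return evenness in [0, 1], or \code{NaN} for a single-taxon sample.
#' @examples
#' pielouEvenness(c(8, 2)) # 0.7219
#' @export
pielouEvenness <- function(x) {
  x <- .checkAbundances(x)
  s <- sum(x > 0)
  if (s == 1L) return(NaN)
  h <- vegan::diversity(x, index = "shannon")
  as.numeric(h / log(s))
}

#' Simpson diversity
#'
#' By default the complement form 1 - sum(p_i^2) (the probability two
#' random individuals differ), matching the convention of
#' \code{vegan::diversity}; the inverse form 1 / sum(p_i^2) is available
#' via \code{variant}.
#'
#' @param x numeric vector of non-negative abundances for one sample.
#' @param variant \code{"complement"} (default) or \code{"inverse"}.
#' @return Simpson index; complement form lies in [0, 1).
#' @export
simpsonIndex <- function(x, variant = c("complement", "inverse")) {
  variant <- match.arg(variant)
  x <- .checkAbundances(x)
  idx <- if (variant == "complement") "simpson" else "invsimpson"
  as.numeric(vegan::diversity(x, index = idx))
}

#' Abundance-based coverage estimator of richness
#'
#' Classic ACE with the rare/abundant cutoff at \code{rareThreshold}
#' individuals: S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2, where
#' C_ace = 1 - F1 / N_rare is the sample coverage of the rare group and
#' gamma^2 the (truncated at zero) squared coefficient of variation of the
#' rare abundances. Defined on integer counts only; spike-normalized
#' tables are rejected. When every rare taxon is a singleton the coverage
#' estimate is zero and the bias-corrected Chao1 estimator is returned
#' instead, with a warning.
#'
#' @param x integer counts for one sample.
#' @param rareThreshold counts at or below this are "rare" (default 10).
#' @return estimated richness (>= 0).
#' @examples
#' aceRichness(c(1, 1, 2, 11)) # 7
#' @export
aceRichness <- function(x, rareThreshold = 10) {
  x <- .checkAbundances(x)
  if (any(x != round(x)))
    stop("ACE is defined on integer counts; got non-integer abundances")
  x <- x[x > 0]
  rare <- x[x <= rareThreshold]
  sAbund <- sum(x > rareThreshold)
  if (!length(rare)) return(as.numeric(sAbund))
  sRare <- length(rare)
  nRare <- sum(rare)
  f1 <- sum(rare == 1)
  cAce <- 1 - f1 / nRare
  if (cAce <= 0) {
    warning("ACE coverage is zero (all rare taxa are singletons); ",
            "falling back to bias-corrected Chao1")
    f2 <- sum(x == 2)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rareThreshold)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- if (nRare > 1)
    max(sRare / cAce * sum(i * (i - 1) * fi) / (nRare * (nRare - 1)) - 1, 0)
  else 0
  sAbund + sRare / cAce + f1 / cAce * gamma2
}

#' Per-sample alpha diversity table
#'
#' Computes richness, Pielou's evenness, Simpson diversity and (for
#' integer tables) ACE for every sample of a community experiment.
#'
#' @param x a [PhyloCommunityExperiment-class] or taxa x sample matrix.
#' @param rareThreshold passed to [aceRichness()].
#' @param simpsonVariant passed to [simpsonIndex()].
#' @return a \code{data.frame} with one row per sample and columns
#'   \code{sample_id}, \code{richness}, \code{pielou}, \code{simpson},
#'   \code{ace} (\code{NA} for non-integer tables).
#' @export
alphaDiversity <- function(x, rareThreshold = 10,
                           simpsonVariant = c("complement", "inverse")) {
  simpsonVariant <- match.arg(simpsonVariant)
  m <- if (is(x, "PhyloCommunityExperiment")) abundances(x) else as.matrix(x)
  integerTable <- all(m == round(m))
  res <- lapply(colnames(m), function(s) {
    v <- m[, s]
    data.frame(
      sample_id = s,
      richness = sum(v > 0),
      pielou = pielouEvenness(v),
      simpson = simpsonIndex(v, simpsonVariant),
      ace = if (integerTable) aceRichness(v, rareThreshold) else NA_real_)
  })
  do.call(rbind, res)
}

#' Group means with standard errors
#'
#' Summarizes a per-sample statistic into group trajectories: for every
#' combination of the grouping keys, the sample count, arithmetic mean and
#' standard error of the mean (sd with the n - 1 denominator, divided by
#' sqrt(n)). Non-finite values are dropped before summarizing and their
#' count reported; a single-member group gets \code{NA} standard error;
#' groups left empty are omitted with a warning.
#'
#' @param values numeric vector, one value per \code{sample_id}.
#' @param sample_id character vector naming each value's sample.
#' @param metadata metadata \code{data.frame} containing \code{sample_id}
#'   and the grouping columns.
#' @param groupBy grouping column names (default compartment and week).
#' @return a \code{data.frame} with the grouping columns plus \code{n},
#'   \code{mean}, \code{se} and \code{n_dropped}.
#' @examples
#' md <- data.frame(sample_id = c("a", "b", "c"),
#'                  compartment = "leaf", week = 3)
#' summarizeByGroup(c(1, 2, 3), md$sample_id, md)
#' @export
summarizeByGroup <- function(values, sample_id, metadata,
                             groupBy = c("compartment", "week")) {
  idx <- match(sample_id, metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(unique(sample_id[is.na(idx)]), collapse = ", "))
  keys <- metadata[idx, groupBy, drop = FALSE]
  key <- interaction(keys, drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    sel <- key == k
    v <- values[sel]
    dropped <- sum(!is.finite(v))
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("group '", k, "' has no finite values; omitted")
      return(NULL)
    }
    n <- length(v)
    cbind(unique(keys[sel, , drop = FALSE])[1L, , drop = FALSE],
          data.frame(n = n, mean = mean(v),
                     se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
                     n_dropped = dropped, row.names = NULL))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.checkAbundances <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) stop("abundances must be non-negative")
  if (!any(x > 0)) stop("sample has no positive abundances")
  x
}
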