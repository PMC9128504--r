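#' Assembly process categories
#'
#' The five ecological assembly processes a pairwise comparison can be
#' assigned to, in the tie-break order used by [processFractions()]
#' (deterministic categories first).
#'
#' @export
assemblyProcessLevels <- c("heterogeneous_selection", "homogeneous_selection",
                           "dispersal_limitation", "homogenizing_dispersal",
                           "drift_diversification")

#' Classify sample pairs into assembly processes
#'
#' The two-stage decision tree: a pair with beta-NTI above +2 is under
#' heterogeneous selection, below -2 under homogeneous selection
#' (deterministic turnover dominates, and RC-bray is not consulted).
#' Otherwise the pair is stochastic and RC-bray decides: above +0.95
#' dispersal limitation, below -0.95 homogenizing dispersal, and anything
#' within both bands is drift/diversification. All inequalities are
#' strict, so boundary-exact values fall to the stochastic/drift side;
#' boundary inputs are reported with a message. Non-finite inputs yield
#' \code{NA} and are tallied in the \code{"excluded"} attribute.
#'
#' @param betaNTI numeric vector of beta-NTI values.
#' @param rcBray numeric vector of RC-bray values, same length.
#' @param betaThreshold deterministic-selection threshold (default 2).
#' @param rcThreshold dispersal threshold (default 0.95).
#' @return factor with levels [assemblyProcessLevels]; attribute
#'   \code{excluded} counts pairs with non-finite input.
#' @examples
#' classifyAssembly(c(2.5, -2.5, 0.5, 0), c(0, 0.99, 0.99, 0))
#' @export
classifyAssembly <- function(betaNTI, rcBray, betaThreshold = 2,
                             rcThreshold = 0.95) {
  if (length(betaNTI) != length(rcBray))
    stop("betaNTI and rcBray must have the same length")
  ok <- is.finite(betaNTI) & is.finite(rcBray)
  out <- rep(NA_character_, length(betaNTI))
  b <- betaNTI[ok]; r <- rcBray[ok]
  out[ok] <- ifelse(b > betaThreshold, "heterogeneous_selection",
             ifelse(b < -betaThreshold, "homogeneous_selection",
             ifelse(r > rcThreshold, "dispersal_limitation",
             ifelse(r < -rcThreshold, "homogenizing_dispersal",
                    "drift_diversification"))))
  nBoundary <- sum(abs(b) == betaThreshold | abs(r) == rcThreshold)
  if (nBoundary)
    message("classifyAssembly: ", nBoundary,
            " pair(s) lie exactly on a threshold (classified stochastic)")
  res <- factor(out, levels = assemblyProcessLevels)
  attr(res, "excluded") <- sum(!ok)
  res
}

#' Per-group assembly process fractions
#'
#' Counts classified pairs per group and converts to fractions of each of
#' the five processes, reporting the dominant process (ties broken toward
#' the deterministic categories, in the order of
#' [assemblyProcessLevels]). Both samples of a pair must share the group;
#' a cross-group pair violates the pooling contract and is an error.
#' Groups whose pairs are all unclassifiable are omitted with a warning.
#'
#' @param pairs \code{data.frame} of classified pairs with a
#'   \code{process} column (factor from [classifyAssembly()]) and the
#'   grouping columns.
#' @param groupBy grouping columns (default compartment and week).
#' @param metadata optional sample metadata; when supplied (and the pairs
#'   carry \code{sample_a}/\code{sample_b}), every pair is checked to lie
#'   within one group — a cross-group pair violates the pooling contract
#'   and is an error.
#' @return \code{data.frame} with grouping columns, \code{n_pairs},
#'   \code{n_excluded}, one fraction column per process, and
#'   \code{dominant}. Fractions sum to one over classified pairs.
#' @export
processFractions <- function(pairs, groupBy = c("compartment", "week"),
                             metadata = NULL) {
  miss <- setdiff(c(groupBy, "process"), names(pairs))
  if (length(miss))
    stop("pairs missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(metadata) && all(c("sample_a", "sample_b") %in% names(pairs))) {
    ga <- metadata[match(pairs$sample_a, metadata$sample_id), groupBy,
                   drop = FALSE]
    gb <- metadata[match(pairs$sample_b, metadata$sample_id), groupBy,
                   drop = FALSE]
    cross <- rowSums(ga != gb) > 0
    if (any(cross, na.rm = TRUE))
      stop("cross-group pair(s) violate the pooling contract: ",
           paste(utils::head(paste(pairs$sample_a[cross],
                                   pairs$sample_b[cross], sep = " vs "), 3L),
                 collapse = "; "))
  }
  key <- interaction(pairs[groupBy], drop = TRUE, lex.order = TRUE,
                     sep = ".")
  out <- lapply(levels(key), function(k) {
    sel <- key == k
    pr <- pairs$process[sel]
    nExcl <- sum(is.na(pr))
    pr <- pr[!is.na(pr)]
    if (!length(pr)) {
      warning("group '", k, "' has no classifiable pairs; omitted")
      return(NULL)
    }
    counts <- table(factor(pr, levels = assemblyProcessLevels))
    frac <- as.numeric(counts) / length(pr)
    names(frac) <- assemblyProcessLevels
    dom <- assemblyProcessLevels[which.max(frac)]
    cbind(unique(pairs[sel, groupBy, drop = FALSE])[1L, , drop = FALSE],
          data.frame(n_pairs = length(pr), n_excluded = nExcl,
                     as.list(frac), dominant = dom, row.names = NULL,
                     check.names = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group mean trajectories of an index
#'
#' Convenience wrapper around [summarizeByGroup()] for per-sample indices
#' (NRI, NTI) or per-pair indices (beta-NTI, RC-bray, Bray-Curtis): each
#' value contributes once to its (compartment, week) group mean and
#' standard error. Groups whose mean magnitude crosses the significance
#' band (|mean| > \code{band}) are flagged.
#'
#' @param values numeric vector of index values.
#' @param groups \code{data.frame} of grouping columns, one row per value.
#' @param band significance band on the group mean (default 2, the
#'   two-standard-deviation null envelope); set \code{NA} to skip.
#' @return \code{data.frame} of group summaries with a logical
#'   \code{beyond_band} column.
#' @export
meanIndexTrajectory <- function(values, groups, band = 2) {
  md <- data.frame(sample_id = paste0("v", seq_along(values)), groups,
                   check.names = FALSE)
  res <- summarizeByGroup(values, md$sample_id, md, groupBy = names(groups))
  res$beyond_band <- if (is.na(band)) NA else abs(res$mean) >= band
  res
}
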