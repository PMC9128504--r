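#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

setOldClass("phylo")

#' Community experiment with an aligned phylogeny
#'
#' An S4 container coupling a taxa-by-sample abundance matrix (assay
#' \code{"counts"}), per-sample metadata (\code{colData}) and a rooted
#' phylogenetic tree with branch lengths whose tip set covers the table's
#' taxa. Rows follow the pruned tree's tip order so that distance matrices
#' and community tables are always positionally aligned.
#'
#' @slot tree a rooted \code{ape::phylo} tree with branch lengths; tip
#'   labels are a superset of \code{rownames(x)}.
#'
#' @seealso [PhyloCommunityExperiment()] for construction,
#'   [alignTableToTree()] for explicit table/tree reconciliation.
#' @exportClass PhyloCommunityExperiment
setClass("PhyloCommunityExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "phylo")
)

setValidity("PhyloCommunityExperiment", function(object) {
  msg <- character()
  a <- assay(object, withDimnames = TRUE)
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample (column) names must be present and unique")
  if (!is.numeric(a) || any(a < 0, na.rm = TRUE) || anyNA(a))
    msg <- c(msg, "abundances must be numeric, non-missing and non-negative")
  tr <- object@tree
  if (anyDuplicated(tr$tip.label) || any(!nzchar(tr$tip.label)))
    msg <- c(msg, "tree tip labels must be unique and non-empty")
  if (is.null(tr$edge.length))
    msg <- c(msg, "tree must have branch lengths")
  else if (any(tr$edge.length < 0))
    msg <- c(msg, "tree branch lengths must be non-negative")
  if (!all(rownames(object) %in% tr$tip.label))
    msg <- c(msg, "every table taxon must be a tree tip")
  if (length(msg)) msg else TRUE
})

#' Construct a PhyloCommunityExperiment
#'
#' Builds the central data object from an abundance matrix (taxa as rows,
#' samples as columns), a rooted tree and optional sample metadata. By
#' default the table and tree are reconciled first: taxa absent from the
#' tree are dropped from the table, tips absent from the table are pruned
#' from the tree, and the dropped identifiers are reported (see
#' [alignTableToTree()]). Rows are reordered to the pruned tree's tip
#' order.
#'
#' @param counts numeric matrix of non-negative abundances, taxa x samples,
#'   with row and column names.
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param sampleData a \code{data.frame} or \code{DataFrame} of per-sample
#'   metadata, one row per column of \code{counts} (matched by
#'   \code{sample_id} column or row names).
#' @param align logical; reconcile table and tree before construction.
#'   With \code{align = FALSE} the taxa must already match tree tips.
#' @return a [PhyloCommunityExperiment-class] object.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' m <- matrix(rpois(8, 5), 4, 2, dimnames = list(LETTERS[1:4], c("s1", "s2")))
#' pce <- PhyloCommunityExperiment(m, tr)
#' @export
PhyloCommunityExperiment <- function(counts, tree, sampleData = NULL,
                                     align = TRUE) {
  counts <- as.matrix(counts)
  if (align) {
    al <- alignTableToTree(counts, tree)
    counts <- al$table
    tree <- al$tree
  }
  counts <- counts[tree$tip.label[tree$tip.label %in% rownames(counts)], ,
                   drop = FALSE]
  cd <- .matchSampleData(sampleData, colnames(counts))
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd)
  new("PhyloCommunityExperiment", se, tree = tree)
}

.matchSampleData <- function(sampleData, sampleIDs) {
  if (is.null(sampleData))
    return(DataFrame(row.names = sampleIDs))
  sd <- as.data.frame(sampleData)
  key <- if ("sample_id" %in% names(sd)) as.character(sd$sample_id)
         else rownames(sd)
  idx <- match(sampleIDs, key)
  if (anyNA(idx))
    stop("metadata missing for sample(s): ",
         paste(sampleIDs[is.na(idx)], collapse = ", "))
  out <- DataFrame(sd[idx, setdiff(names(sd), "sample_id"), drop = FALSE])
  rownames(out) <- sampleIDs
  out
}

setMethod("show", "PhyloCommunityExperiment", function(object) {
  cat("PhyloCommunityExperiment:", nrow(object), "taxa x",
      ncol(object), "samples\n")
  cat("  tree:", length(object@tree$tip.label), "tips,",
      if (ape::is.rooted(object@tree)) "rooted" else "unrooted", "\n")
  cd <- colData(object)
  if (ncol(cd))
    cat("  sample data:", paste(colnames(cd), collapse = ", "), "\n")
  invisible(object)
})
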