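#' @rdname abundances
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname phyloTree
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname patristicDistances
#' @export
setGeneric("patristicDistances", function(x, ...)
  standardGeneric("patristicDistances"))

#' @rdname removeSingletons
#' @export
setGeneric("removeSingletons", function(x, ...)
  standardGeneric("removeSingletons"))

#' @rdname spikeNormalize
#' @export
setGeneric("spikeNormalize", function(x, spikeTaxon, ...)
  standardGeneric("spikeNormalize"))

#' Abundance matrix accessor
#'
#' @param x a [PhyloCommunityExperiment-class].
#' @param ... unused.
#' @return the taxa x sample abundance matrix.
#' @rdname abundances
#' @export
setMethod("abundances", "PhyloCommunityExperiment", function(x, ...)
  SummarizedExperiment::assay(x, "counts"))

#' Phylogeny accessor
#'
#' @param x a [PhyloCommunityExperiment-class].
#' @return the \code{ape::phylo} tree aligned to the table's taxa.
#' @rdname phyloTree
#' @export
setMethod("phyloTree", "PhyloCommunityExperiment", function(x) x@tree)

#' Sample metadata accessor
#'
#' @param x a [PhyloCommunityExperiment-class].
#' @return sample metadata as a base \code{data.frame} with a
#'   \code{sample_id} column.
#' @rdname sampleData
#' @export
setMethod("sampleData", "PhyloCommunityExperiment", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample_id = colnames(x), df, row.names = NULL,
             check.names = FALSE)
})
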