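#' Read a rooted Newick tree with branch lengths
#'
#' Parses a Newick file and validates it for downstream patristic-distance
#' work: tip labels must be unique and non-empty, and every edge must carry
#' a non-negative branch length. Missing branch lengths are rejected unless
#' a default is supplied, since silently defaulting corrupts distance-based
#' statistics.
#'
#' @param path path to a Newick file.
#' @param missingBranchLength \code{NA} (default) to reject trees with
#'   missing branch lengths, or a single non-negative number used to fill
#'   them in.
#' @return an \code{ape::phylo} tree.
#' @export
readNewickTree <- function(path, missingBranchLength = NA) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("failed to parse Newick in '",
                                            path, "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("failed to parse Newick in '", path, "'")
  validateTree(tree, missingBranchLength)
}

#' @rdname readNewickTree
#' @param tree an \code{ape::phylo} object to validate in place.
#' @export
validateTree <- function(tree, missingBranchLength = NA) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (any(!nzchar(tree$tip.label)))
    stop("tree has empty tip labels")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (is.na(missingBranchLength))
      stop("tree has no branch lengths (set missingBranchLength to default)")
    tree$edge.length <- rep(missingBranchLength, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.na(missingBranchLength))
      stop("tree has missing branch lengths ",
           "(set missingBranchLength to default)")
    tree$edge.length[is.na(tree$edge.length)] <- missingBranchLength
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Read an amplicon feature table
#'
#' Accepts two TSV dialects, auto-detected: a plain table with taxa as rows
#' and samples as columns (header row of sample IDs), and the TSV export of
#' a BIOM table, whose header line starts with \code{#OTU ID} and which may
#' be preceded by a \code{# Constructed from biom file} comment.
#'
#' @param path path to the feature table.
#' @return a numeric matrix, taxa x samples.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # comment lines (provenance headers, '# Constructed from biom file')
  # are dropped; a '#OTU ID' line is the BIOM-TSV dialect's header
  lines <- lines[!startsWith(lines, "#") | startsWith(lines, "#OTU ID")]
  if (!length(lines)) stop("empty feature table: ", path)
  lines[[1L]] <- sub("^#OTU ID", "taxon_id", lines[[1L]])
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- as.character(df[[1L]])
  if (anyDuplicated(taxa))
    stop("duplicate taxon IDs in feature table: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundances in feature table")
  if (anyNA(m) || any(m < 0)) stop("abundances must be non-negative numbers")
  rownames(m) <- taxa
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in feature table")
  m
}

#' Read sample metadata
#'
#' Requires columns \code{sample_id}, \code{compartment} and \code{week};
#' \code{nam_line}, \code{bbch} and \code{block} are kept when present.
#'
#' @param path path to a metadata TSV.
#' @param compartments allowed compartment labels.
#' @param weekRange inclusive allowed range of the \code{week} column
#'   (weeks after planting).
#' @return a \code{data.frame} of validated sample metadata.
#' @export
readSampleMetadata <- function(path,
                               compartments = c("leaf", "root", "rhizosphere"),
                               weekRange = c(3L, 12L)) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validateMetadata(md, compartments = compartments, weekRange = weekRange)
}

#' @rdname readSampleMetadata
#' @param metadata a metadata \code{data.frame} to validate in place.
#' @export
validateMetadata <- function(metadata,
                             compartments = c("leaf", "root", "rhizosphere"),
                             weekRange = c(3L, 12L)) {
  need <- c("sample_id", "compartment", "week")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$compartment), compartments)
  if (length(bad))
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "))
  wk <- suppressWarnings(as.integer(metadata$week))
  if (anyNA(wk)) stop("non-integer week values in metadata")
  if (any(wk < weekRange[[1L]] | wk > weekRange[[2L]]))
    stop("week values outside declared range [", weekRange[[1L]], ", ",
         weekRange[[2L]], "]")
  metadata$week <- wk
  metadata
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique tip-to-tip path, for all tip
#' pairs. Rows and columns follow the tree's tip order.
#'
#' @param x an \code{ape::phylo} tree or a [PhyloCommunityExperiment-class]
#'   (whose tree is first pruned to the table's taxa).
#' @param ... unused.
#' @return a symmetric numeric matrix with zero diagonal.
#' @rdname patristicDistances
#' @export
setMethod("patristicDistances", "phylo", function(x, ...) {
  d <- ape::cophenetic.phylo(x)
  ord <- x$tip.label
  d[ord, ord, drop = FALSE]
})

#' @rdname patristicDistances
#' @export
setMethod("patristicDistances", "PhyloCommunityExperiment", function(x, ...) {
  tr <- x@tree
  if (length(setdiff(tr$tip.label, rownames(x))))
    tr <- ape::keep.tip(tr, rownames(x))
  d <- patristicDistances(tr)
  d[rownames(x), rownames(x), drop = FALSE]
})

#' Drop dataset-wide singleton and zero-sum taxa
#'
#' Removes taxa whose summed abundance across all samples is at most one
#' read, the standard pre-filter for denoised amplicon tables. The sample
#' set is unchanged; the operation is idempotent.
#'
#' @param x a taxa x sample matrix or [PhyloCommunityExperiment-class].
#' @param ... unused.
#' @return object of the same class with filtered taxa.
#' @rdname removeSingletons
#' @export
setMethod("removeSingletons", "matrix", function(x, ...) {
  keep <- rowSums(x) > 1
  if (!any(keep))
    warning("all taxa are singletons or absent; returning zero-taxon table")
  x[keep, , drop = FALSE]
})

#' @rdname removeSingletons
#' @export
setMethod("removeSingletons", "PhyloCommunityExperiment", function(x, ...) {
  m <- removeSingletons(abundances(x))
  PhyloCommunityExperiment(m, x@tree,
                           sampleData = SummarizedExperiment::colData(x))
})

#' Normalize abundances to an internal standard spike
#'
#' Divides each sample's abundances by that sample's count of the spiked
#' internal standard taxon (for the study design, an Aliivibrio fischeri
#' spike added before DNA extraction), then removes the spike taxon from
#' the table. Every sample must contain the spike with a positive count.
#'
#' @param x a taxa x sample matrix or [PhyloCommunityExperiment-class].
#' @param spikeTaxon taxon ID of the internal standard.
#' @param ... unused.
#' @return object of the same class, spike-normalized, spike removed.
#' @rdname spikeNormalize
#' @export
setMethod("spikeNormalize", "matrix", function(x, spikeTaxon, ...) {
  if (!spikeTaxon %in% rownames(x))
    stop("spike taxon '", spikeTaxon, "' not in table")
  spike <- x[spikeTaxon, ]
  bad <- colnames(x)[spike <= 0]
  if (length(bad))
    stop("spike count is zero in sample(s): ", paste(bad, collapse = ", "))
  out <- x[setdiff(rownames(x), spikeTaxon), , drop = FALSE]
  sweep(out, 2L, spike, "/")
})

#' @rdname spikeNormalize
#' @export
setMethod("spikeNormalize", "PhyloCommunityExperiment",
          function(x, spikeTaxon, ...) {
  m <- spikeNormalize(abundances(x), spikeTaxon)
  PhyloCommunityExperiment(m, x@tree,
                           sampleData = SummarizedExperiment::colData(x))
})

#' Reconcile a feature table with a tree
#'
#' Restricts the table to taxa present as tree tips, prunes the tree to
#' taxa present in the table, and reports what was dropped on each side.
#'
#' @param table taxa x sample abundance matrix.
#' @param tree an \code{ape::phylo} tree.
#' @return list with elements \code{table}, \code{tree},
#'   \code{dropped_taxa} (in table, not tree) and \code{dropped_tips}
#'   (in tree, not table).
#' @export
alignTableToTree <- function(table, tree) {
  shared <- intersect(rownames(table), tree$tip.label)
  if (!length(shared))
    stop("no taxa shared between table and tree")
  droppedTaxa <- setdiff(rownames(table), shared)
  droppedTips <- setdiff(tree$tip.label, shared)
  if (length(droppedTaxa) || length(droppedTips))
    message("alignTableToTree: dropped ", length(droppedTaxa),
            " table taxa and ", length(droppedTips), " tree tips")
  tr <- if (length(droppedTips)) ape::keep.tip(tree, shared) else tree
  list(table = table[tr$tip.label, , drop = FALSE], tree = tr,
       dropped_taxa = droppedTaxa, dropped_tips = droppedTips)
}

#' Write a TSV with a provenance header
#'
#' All package writers emit tab-separated text prefixed with comment lines
#' recording the package version, a seed if one governs the contents, and
#' md5 hashes of any input files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed optional RNG seed recorded in the header.
#' @param inputs optional character vector of input file paths to hash.
#' @return \code{path}, invisibly.
#' @export
writeTableTSV <- function(df, path, seed = NULL, inputs = NULL) {
  hdr <- c(paste0("# PhyloAssembly ",
                  as.character(utils::packageVersion("PhyloAssembly"))))
  if (!is.null(seed)) hdr <- c(hdr, paste0("# seed: ", seed))
  for (f in inputs) if (file.exists(f))
    hdr <- c(hdr, paste0("# input md5 ", basename(f), ": ",
                         unname(tools::md5sum(f))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
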