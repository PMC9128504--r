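#' Null-model analysis of all pools
#'
#' Runs the per-pool null-model battery over a community experiment:
#' splits samples into pools (by default one per compartment and week),
#' and within each pool computes NRI/NTI standardized effect sizes,
#' pairwise beta-MNTD/beta-NTI, Bray-Curtis and RC-bray, all against
#' \code{nIter} randomizations seeded by a deterministic per-pool
#' sub-seed of \code{seed} — results are reproducible and independent of
#' pool execution order. Each pool's taxon set is the union of taxa
#' present in its member samples.
#'
#' @param x a [PhyloCommunityExperiment-class].
#' @param groupBy pooling columns in \code{sampleData(x)} (default
#'   compartment and week).
#' @param nIter randomizations per null distribution (default 999).
#' @param seed master integer seed.
#' @param weighted abundance-weight the phylogenetic metrics (default
#'   \code{TRUE}).
#' @param betaMetric \code{"bmntd"} (default) or \code{"bmpd"} basis for
#'   the turnover standardized effect size.
#' @param rcSpeciesWeighting,abundanceFloor passed to [raupCrickBray()].
#' @param betaThreshold,rcThreshold passed to [classifyAssembly()].
#' @return list with \code{ses} (per sample: NRI and NTI rows) and
#'   \code{pairs} (per within-pool sample pair: beta_mntd, beta_nti,
#'   bray_curtis, rc_bray, process), both carrying the grouping columns.
#' @export
assemblyNullModels <- function(x, groupBy = c("compartment", "week"),
                               nIter = 999, seed = 1, weighted = TRUE,
                               betaMetric = c("bmntd", "bmpd"),
                               rcSpeciesWeighting = c("occupancy",
                                                      "occupancy_abundance"),
                               abundanceFloor = 1000, betaThreshold = 2,
                               rcThreshold = 0.95) {
  betaMetric <- match.arg(betaMetric)
  rcSpeciesWeighting <- match.arg(rcSpeciesWeighting)
  md <- sampleData(x)
  pools <- makePools(md, groupBy = groupBy)
  dFull <- patristicDistances(x)
  commFull <- t(abundances(x))
  sesOut <- list(); pairOut <- list()
  for (key in names(pools)) {
    ids <- pools[[key]]
    comm <- commFull[ids, , drop = FALSE]
    comm <- comm[, colSums(comm) > 0, drop = FALSE]
    dis <- dFull[colnames(comm), colnames(comm)]
    grp <- md[match(ids[[1L]], md$sample_id), groupBy, drop = FALSE]
    set.seed(poolSeed(seed, key))
    sesMpd <- sesByPool(comm, dis, metric = "mpd", weighted = weighted,
                        nIter = nIter)
    sesMntd <- sesByPool(comm, dis, metric = "mntd", weighted = weighted,
                         nIter = nIter)
    ses <- rbind(sesMpd, sesMntd)
    sesOut[[key]] <- cbind(ses, grp[rep(1L, nrow(ses)), , drop = FALSE],
                           row.names = NULL)
    if (length(ids) < 2L) next
    bn <- betaNTI(comm, dis, weighted = weighted, nIter = nIter,
                  metric = betaMetric)
    rc <- raupCrickBray(comm, nIter = nIter,
                        speciesWeighting = rcSpeciesWeighting,
                        abundanceFloor = abundanceFloor)
    lw <- which(lower.tri(bn$beta_nti), arr.ind = TRUE)
    pr <- data.frame(
      sample_a = ids[lw[, 2L]], sample_b = ids[lw[, 1L]],
      beta_mntd = bn$beta_mntd_obs[lw],
      beta_nti = bn$beta_nti[lw],
      bray_curtis = rc$bray_curtis_obs[lw],
      rc_bray = rc$rc_bray[lw], row.names = NULL)
    pr$process <- classifyAssembly(pr$beta_nti, pr$rc_bray,
                                   betaThreshold = betaThreshold,
                                   rcThreshold = rcThreshold)
    pairOut[[key]] <- cbind(pr, grp[rep(1L, nrow(pr)), , drop = FALSE],
                            row.names = NULL)
  }
  sesAll <- do.call(rbind, sesOut)
  pairsAll <- do.call(rbind, pairOut)
  rownames(sesAll) <- rownames(pairsAll) <- NULL
  list(ses = sesAll, pairs = pairsAll)
}

#' Run the full assembly-process pipeline
#'
#' End-to-end execution: load (or simulate) the inputs, apply the
#' preprocessing filters, compute alpha diversity and its group
#' trajectories, run the per-pool null models, classify every pair and
#' aggregate process fractions, then write all outputs as TSV plus a JSON
#' run manifest. Preprocessing order is fixed: dataset-wide singleton
#' removal on raw counts, then spike normalization (samples lacking the
#' spike taxon, e.g. leaf samples, are left on the read scale), then
#' table/tree alignment. Alpha diversity (which needs integer counts for
#' ACE) is computed on the singleton-filtered counts before spike
#' scaling.
#'
#' @param config a named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{tree, table, metadata}{input file paths; or instead}
#'     \item{scenario}{list of [scenarioSpec()] arguments for a synthetic
#'       run (a \code{regime} plus optional dimensions), or}
#'     \item{study}{list of [simulateStudy()] arguments.}
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{master seed (default 1).}
#'     \item{n_iter}{null iterations (default 999; a nonstandard value is
#'       recorded in the manifest with a warning).}
#'     \item{spike_taxon}{internal standard taxon ID, if any.}
#'     \item{group_by}{pooling columns (default compartment, week).}
#'     \item{weighted, beta_metric, rc_species_weighting,
#'       abundance_floor, beta_threshold, rc_threshold, simpson_variant}{
#'       optional knobs with the documented defaults.}
#'   }
#' @return invisible list with the computed tables and the manifest; on
#'   failure a \code{FAILED} marker file is left in \code{out_dir} and
#'   the error is rethrown.
#' @export
runPipeline <- function(config) {
  cfg <- .loadConfig(config)
  outDir <- cfg$out_dir
  if (is.null(outDir)) stop("config must name an out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  tryCatch(.runPipelineInner(cfg, outDir), error = function(e) {
    writeLines(conditionMessage(e), file.path(outDir, "FAILED"))
    stop(e)
  })
}

.runPipelineInner <- function(cfg, outDir) {
  seed <- cfg$seed %||% 1L
  nIter <- cfg$n_iter %||% 999L
  groupBy <- cfg$group_by %||% c("compartment", "week")
  inputs <- character()
  if (!is.null(cfg$scenario)) {
    ds <- simulateScenario(do.call(scenarioSpec,
                                   c(cfg$scenario, list(seed = seed))))
    tree <- ds$tree; table <- ds$table; metadata <- ds$metadata
  } else if (!is.null(cfg$study)) {
    ds <- do.call(simulateStudy, c(cfg$study, list(seed = seed)))
    tree <- ds$tree; table <- ds$table; metadata <- ds$metadata
    cfg$spike_taxon <- cfg$spike_taxon %||% ds$spike_taxon
  } else {
    inputs <- unlist(cfg[c("tree", "table", "metadata")])
    tree <- readNewickTree(cfg$tree)
    table <- readFeatureTable(cfg$table)
    metadata <- readSampleMetadata(cfg$metadata)
  }
  # preprocessing: singletons -> spike -> tree alignment
  table <- removeSingletons(table)
  alpha <- alphaDiversity(table,
                          simpsonVariant = cfg$simpson_variant %||%
                            "complement")
  alphaLong <- stats::reshape(
    alpha, direction = "long", idvar = "sample_id",
    varying = c("richness", "pielou", "simpson", "ace"),
    v.names = "value", timevar = "metric",
    times = c("richness", "pielou", "simpson", "ace"))
  rownames(alphaLong) <- NULL
  alphaSummary <- do.call(rbind, lapply(
    c("richness", "pielou", "simpson", "ace"), function(mt) {
      sub <- alphaLong[alphaLong$metric == mt, ]
      s <- summarizeByGroup(sub$value, sub$sample_id, metadata,
                            groupBy = groupBy)
      cbind(metric = mt, s)
    }))
  spike <- cfg$spike_taxon
  if (!is.null(spike) && spike %in% rownames(table)) {
    hasSpike <- table[spike, ] > 0
    if (any(hasSpike)) {
      norm <- spikeNormalize(table[, hasSpike, drop = FALSE], spike)
      rest <- table[setdiff(rownames(table), spike), !hasSpike,
                    drop = FALSE]
      table <- cbind(norm, rest)[, colnames(table), drop = FALSE]
    }
  }
  pce <- PhyloCommunityExperiment(table, tree, sampleData = metadata)
  nm <- assemblyNullModels(
    pce, groupBy = groupBy, nIter = nIter, seed = seed,
    weighted = cfg$weighted %||% TRUE,
    betaMetric = cfg$beta_metric %||% "bmntd",
    rcSpeciesWeighting = cfg$rc_species_weighting %||% "occupancy",
    abundanceFloor = cfg$abundance_floor %||% 1000,
    betaThreshold = cfg$beta_threshold %||% 2,
    rcThreshold = cfg$rc_threshold %||% 0.95)
  fractions <- processFractions(nm$pairs, groupBy = groupBy)
  wt <- function(df, file) writeTableTSV(df, file.path(outDir, file),
                                         seed = seed, inputs = inputs)
  wt(alphaLong, "alpha.tsv")
  wt(alphaSummary, "alpha_summary.tsv")
  wt(nm$ses, "ses.tsv")
  wt(nm$pairs, "pairwise.tsv")
  wt(fractions, "process_fractions.tsv")
  if (nIter != 999L)
    warning("nonstandard null iteration count: ", nIter,
            " (recorded in manifest)")
  manifest <- list(
    package = "PhyloAssembly",
    version = as.character(utils::packageVersion("PhyloAssembly")),
    seed = seed, n_iter = nIter,
    nonstandard_n_iter = nIter != 999L,
    group_by = groupBy,
    n_samples = ncol(pce), n_taxa = nrow(pce),
    outputs = c("alpha.tsv", "alpha_summary.tsv", "ses.tsv",
                "pairwise.tsv", "process_fractions.tsv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(alpha = alphaLong, alpha_summary = alphaSummary,
                 ses = nm$ses, pairs = nm$pairs, fractions = fractions,
                 manifest = manifest))
}

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
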