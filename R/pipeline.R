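#' Default pipeline configuration
#'
#' Thresholds, model settings and variant matrix for [runPipeline()].
#' Defaults mirror the published procedure: STOP-STOP ORF definition,
#' RFC cutoffs 0.5/0.6/0.7/0.9, P-value threshold 0.01 with 1,000
#' randomizations, ORFs strictly longer than 30 nt, gap penalties -3/-0.1.
#'
#' @param rfcCutoffs RFC cutoffs for the cutoff-based origin calls.
#' @param alpha empirical P-value threshold.
#' @param nReps randomizations per P-value.
#' @param seed master seed; per-gene and per-node streams are derived from
#'   it, so results are independent of processing order.
#' @param orfDefinition ORF definition for RFC scoring.
#' @param minLen strict minimum ORF length, nt.
#' @param deletionBias vector of indel tie-resolution settings; each value
#'   becomes an internal-engine methodology variant.
#' @param nCategories,gammaShape discrete-gamma settings for the internal
#'   reconstruction engine.
#' @param params alignment parameters ([alignParams()]).
#' @param mostAncientLabel,genusInternalLabels ensemble classification
#'   settings ([classifyEnsemble()]); `NULL` means "use the most ancient
#'   focal-path ancestor of the tree".
#' @return a config list.
#' @export
pipelineConfig <- function(rfcCutoffs = c(0.5, 0.6, 0.7, 0.9), alpha = 0.01,
                           nReps = 1000L, seed = 1L,
                           orfDefinition = "noATG", minLen = 30L,
                           deletionBias = FALSE, nCategories = 1L,
                           gammaShape = NA_real_, params = alignParams(),
                           mostAncientLabel = NULL,
                           genusInternalLabels = NULL) {
  list(rfcCutoffs = rfcCutoffs, alpha = alpha, nReps = as.integer(nReps),
       seed = as.integer(seed), orfDefinition = orfDefinition,
       minLen = as.integer(minLen), deletionBias = deletionBias,
       nCategories = as.integer(nCategories), gammaShape = gammaShape,
       params = params, mostAncientLabel = mostAncientLabel,
       genusInternalLabels = genusInternalLabels)
}

#' Run the full origin-dating pipeline over a set of genes
#'
#' For every gene: reconstruct ancestors with the internal engine (one
#' variant per `deletionBias` setting), add any externally supplied
#' ancestral sets, score the best ancestral ORF per non-root ancestor by
#' RFC, attach empirical P-values, call a branch of origin per criterion
#' and variant, and classify the gene across variants. Gene failures are
#' isolated: a malformed gene is reported in `errors.tsv` and the rest
#' complete.
#'
#' @param genes named list; each element an [OrthologAlignment-class] or a
#'   list of arguments for [readMsa()] (`path`, `focalTaxon`, and
#'   optionally `mode`, `focalOrfSpan`, `flankLen`).
#' @param tree a [PhyloTree-class] or a path to a rooted newick file.
#' @param outDir output directory, created if needed.
#' @param config a [pipelineConfig()] list.
#' @param externalAncestors optional named list (provenance -> FASTA path
#'   or [AncestralSet-class]) of external reconstructions shared across
#'   genes is not meaningful, so entries here are per-gene:
#'   `externalAncestors[[gene]][[provenance]]`.
#' @return `outDir`, invisibly. Writes `rfc.tsv`, `pvalues.tsv`,
#'   `origins.tsv`, `ensemble.tsv`, `msa_stats.tsv`, `errors.tsv` and
#'   `provenance.json` (tool versions, seeds, thresholds).
#' @export
runPipeline <- function(genes, tree, outDir, config = pipelineConfig(),
                        externalAncestors = list()) {
  if (is.character(tree)) tree <- readTree(tree)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rfcRows <- list(); pRows <- list(); oRows <- list(); eRows <- list()
  sRows <- list(); errRows <- list()

  for (g in names(genes)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      msa <- genes[[g]]
      if (!is(msa, "OrthologAlignment"))
        msa <- do.call(readMsa, msa)
      focal <- focalTaxon(msa)
      path <- focalPathAncestors(tree, focal)
      refOrf <- focalOrfSeq(msa)
      geneSeed <- deriveSeed(config$seed, g)

      variants <- list()
      for (db in config$deletionBias) {
        model <- fitBaseFreqs(msa, gammaShape = config$gammaShape,
                              nCategories = config$nCategories)
        a <- reconstructAncestors(msa, tree, model, deletionBias = db)
        variants[[provenance(a)]] <- a
      }
      for (prov in names(externalAncestors[[g]] %||% list())) {
        ea <- externalAncestors[[g]][[prov]]
        if (is.character(ea)) ea <- readExternalAncestors(ea, tree, prov)
        variants[[provenance(ea)]] <- ea
      }

      st <- msaStats(msa)
      sRows[[g]] <- data.frame(gene = g, gaps_per_seq = st$gapsPerSeq,
                                mean_kimura = st$meanKimura)

      pvCalls <- list()
      for (prov in names(variants)) {
        a <- variants[[prov]]
        perRfc <- c(); perP <- c(); perOrf <- list()
        for (nd in path) {
          ancSeq <- ancSequences(a)[[nd]]
          if (is.null(ancSeq) || !nchar(ancSeq)) {
            perRfc[nd] <- 0; perP[nd] <- 1; perOrf[[nd]] <- NULL
          } else {
            r <- bestRfcForNode(ancSeq, refOrf, config$orfDefinition,
                                minLen = config$minLen, params = config$params)
            perRfc[nd] <- r$bestRfc
            perOrf[[nd]] <- r$bestOrf
            perP[nd] <- empiricalPvalue(ancSeq, refOrf, nReps = config$nReps,
                                        seed = deriveSeed(geneSeed, paste0(prov, "|", nd)),
                                        minLen = config$minLen,
                                        params = config$params)$pValue
          }
          bo <- perOrf[[nd]]
          rfcRows[[length(rfcRows) + 1L]] <- data.frame(
            gene = g, node = nd, provenance = prov,
            definition = config$orfDefinition, best_rfc = perRfc[nd],
            orf_start = if (is.null(bo)) NA_integer_ else bo$start,
            orf_end = if (is.null(bo)) NA_integer_ else bo$end,
            orf_len = if (is.null(bo)) NA_integer_ else bo$length)
          pRows[[length(pRows) + 1L]] <- data.frame(
            gene = g, node = nd, provenance = prov,
            observed_rfc = perRfc[nd], p_value = perP[nd],
            n_reps = config$nReps, seed = deriveSeed(geneSeed, paste0(prov, "|", nd)))
        }
        for (cut in config$rfcCutoffs) {
          cl <- assignBranchCutoff(perRfc, tree, cut, focal)
          oRows[[length(oRows) + 1L]] <- data.frame(
            gene = g, provenance = prov, criterion = "rfc_cutoff",
            threshold = cut, branch = cl$branch,
            downstream_consistency = cl$downstreamConsistency)
        }
        cl <- assignBranchPvalue(perP, tree, alpha = config$alpha, focal)
        pvCalls[[prov]] <- cl
        oRows[[length(oRows) + 1L]] <- data.frame(
          gene = g, provenance = prov, criterion = "pvalue",
          threshold = config$alpha, branch = cl$branch,
          downstream_consistency = cl$downstreamConsistency)
      }
      if (length(pvCalls) >= 2L) {
        mal <- config$mostAncientLabel %||% path[1L]
        ens <- classifyEnsemble(pvCalls, mal,
                                config$genusInternalLabels %||% mal)
        eRows[[g]] <- data.frame(gene = g, category = ens$category,
                                  n_agreeing = ens$nAgreeing,
                                  n_variants = length(pvCalls))
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res))
      errRows[[g]] <- data.frame(gene = g, error = res)
    message(sprintf("[orfancestry] gene %s: %s (%.2fs)", g,
                    if (isTRUE(res)) "ok" else "FAILED",
                    proc.time()[["elapsed"]] - t0))
  }

  writeTsv <- function(rows, file, empty) {
    df <- if (length(rows)) do.call(rbind, rows) else empty
    utils::write.table(df, file.path(outDir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeTsv(rfcRows, "rfc.tsv", data.frame(gene = character(0)))
  writeTsv(pRows, "pvalues.tsv", data.frame(gene = character(0)))
  writeTsv(oRows, "origins.tsv", data.frame(gene = character(0)))
  writeTsv(eRows, "ensemble.tsv", data.frame(gene = character(0)))
  writeTsv(sRows, "msa_stats.tsv", data.frame(gene = character(0)))
  writeTsv(errRows, "errors.tsv", data.frame(gene = character(0), error = character(0)))
  prov <- list(package = "orfancestry",
               version = as.character(utils::packageVersion("orfancestry")),
               r_version = R.version.string,
               seed = config$seed, alpha = config$alpha, nReps = config$nReps,
               rfcCutoffs = config$rfcCutoffs,
               orfDefinition = config$orfDefinition, minLen = config$minLen,
               alignParams = unclass(config$params))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
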