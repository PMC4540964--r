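#' @import methods
#' @importFrom stats optimize pchisq phyper p.adjust rnorm runif setNames
#'   quantile sd ecdf IQR AIC logLik
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head modifyList
NULL

setOldClass("phylo")

#' PWMatrix: a position weight matrix
#'
#' Column-stochastic base-probability model of a transcription factor binding
#' motif. Probabilities are derived from counts with a pseudocount added to
#' every cell, so all entries are strictly positive. Information content is
#' reported in bits, \eqn{\sum_j (2 + \sum_b p_{bj} \log_2 p_{bj})}.
#'
#' @slot id motif identifier.
#' @slot name optional motif name (e.g. the factor).
#' @slot profile 4 x L numeric matrix of base probabilities, rows A,C,G,T.
#' @slot ic information content in bits.
#' @slot pseudocount pseudocount per cell used when normalising counts.
#' @exportClass PWMatrix
setClass("PWMatrix",
  representation(id = "character", name = "character", profile = "matrix",
                 ic = "numeric", pseudocount = "numeric"))

setValidity("PWMatrix", function(object) {
  p <- object@profile
  if (!is.numeric(p) || nrow(p) != 4L)
    return("profile must be a numeric 4 x L matrix (rows A,C,G,T)")
  if (ncol(p) < 1L)
    return("motif length must be >= 1")
  if (any(p <= 0))
    return("all probabilities must be > 0 after pseudocounting")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("each position's probabilities must sum to 1 (tol 1e-9)")
  TRUE
})

#' RegimePainting: branch-to-regime assignment on a rooted tree
#'
#' Assigns every branch of a rooted phylogeny to a selective regime, either
#' \code{"base"} or \code{"shift"}. Houses the evolutionary scenarios used for
#' Hansen-model fitting: BM and M0 paint every branch \code{"base"}; a
#' branch-shift model paints the clade spanned by \code{shiftTips} (plus its
#' stem branch) \code{"shift"}. A painting built with
#' \code{allowComplement = TRUE} instead shifts everything outside the
#' complement clade, in which case the root regime is \code{"shift"}.
#'
#' @slot model model identifier (BM, M0, M1..M10 or user-defined).
#' @slot tree the \code{phylo} tree the painting refers to.
#' @slot regimes character vector, one entry per edge of \code{tree} in edge
#'   order, each \code{"base"} or \code{"shift"}.
#' @slot rootRegime regime at the root node.
#' @slot shiftTips tip labels defining the shifted clade (empty for BM/M0).
#' @slot spansRoot TRUE when the shift regime was painted as a complement and
#'   therefore contains the root.
#' @exportClass RegimePainting
setClass("RegimePainting",
  representation(model = "character", tree = "phylo", regimes = "character",
                 rootRegime = "character", shiftTips = "character",
                 spansRoot = "logical"))

setValidity("RegimePainting", function(object) {
  tr <- object@tree
  if (length(object@regimes) != nrow(tr$edge))
    return("one regime per branch required")
  if (!all(object@regimes %in% c("base", "shift")))
    return("regimes must be 'base' or 'shift'")
  if (!object@rootRegime %in% c("base", "shift"))
    return("rootRegime must be 'base' or 'shift'")
  if (length(object@shiftTips) == 0L && any(object@regimes == "shift"))
    return("shift branches present but no shiftTips recorded")
  if (!all(object@shiftTips %in% tr$tip.label))
    return("shiftTips must be tip labels of the tree")
  TRUE
})

#' ClusterScore: homotypic-cluster score of one region in one species
#'
#' The log2 likelihood ratio of the best-scoring subsegment under the
#' homotypic-cluster HMM relative to the background-only model, floored at 0
#' (the empty cluster scores 0), together with the best-cluster interval and
#' the motif hits of its highest-probability parse.
#'
#' @slot region region identifier.
#' @slot species species label.
#' @slot score log2 likelihood ratio, >= 0.
#' @slot interval integer length-2, 0-based half-open best-cluster interval
#'   relative to the region (c(0,0) when the best cluster is empty).
#' @slot hits data.frame with columns \code{start} (0-based), \code{strand}
#'   (\code{"+"}/\code{"-"}) and \code{logOdds} (log2 per-site odds) for the
#'   Viterbi parse of the best cluster.
#' @exportClass ClusterScore
setClass("ClusterScore",
  representation(region = "character", species = "character",
                 score = "numeric", interval = "integer",
                 hits = "data.frame"))

setValidity("ClusterScore", function(object) {
  if (length(object@score) != 1L || !is.finite(object@score))
    return("score must be a single finite number")
  if (object@score < 0)
    return("score is floored at 0")
  if (length(object@interval) != 2L || object@interval[1] > object@interval[2])
    return("interval must be 0-based half-open with start <= end")
  TRUE
})

#' ScoreMatrix: region x species trait table
#'
#' One row per region, one column per species; entries are CRM scores (log2
#' units) or any other quantitative trait such as normalised chromatin signal.
#' Missing orthologs are \code{NA}, never 0.
#'
#' @slot values numeric matrix with region rownames and species colnames.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(values = "matrix"))

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("region rownames and species colnames are required")
  if (anyDuplicated(rownames(v))) return("duplicate region identifiers")
  if (anyDuplicated(colnames(v))) return("duplicate species labels")
  TRUE
})

#' ModelFit: a fitted trait-evolution model
#'
#' Maximum-likelihood fit of BM, single-optimum OU (M0) or a branch-shift
#' Hansen model to one trait vector. The parameter count is 2 for BM
#' (\code{x0}, \code{sigmaSq}), 3 for M0 (\code{alpha}, \code{sigmaSq},
#' \code{theta}) and 4 for a branch-shift model (\code{alpha}, \code{sigmaSq},
#' \code{theta} base and shift); the root state is pinned to the root regime's
#' optimum. \code{AIC == 2k - 2 logLik} always holds exactly.
#'
#' @slot model model identifier.
#' @slot params named list: \code{alpha}, \code{sigmaSq}, \code{theta} (named
#'   by regime), \code{x0}.
#' @slot logLik maximised log-likelihood (natural log).
#' @slot k number of free parameters.
#' @slot AIC Akaike information criterion.
#' @slot nTips number of tips with data used in the fit.
#' @slot degenerate TRUE when the residual variance was floored (constant
#'   trait).
#' @slot untestable TRUE when the model could not be assessed on this trait
#'   (e.g. every shifted tip missing); such fits carry NA likelihoods.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(model = "character", params = "list", logLik = "numeric",
                 k = "numeric", AIC = "numeric", nTips = "integer",
                 degenerate = "logical", untestable = "logical"))

setValidity("ModelFit", function(object) {
  if (object@untestable) return(TRUE)
  if (!is.finite(object@logLik)) return("non-finite log-likelihood")
  if (abs(object@AIC - (2 * object@k - 2 * object@logLik)) > 1e-8)
    return("AIC must equal 2k - 2 logLik")
  TRUE
})

#' BootstrapResult: parametric-bootstrap model comparison
#'
#' Distributions of the model-choice statistic
#' \eqn{\delta = 2(\log L_a - \log L_b)} under data simulated from each of the
#' two fitted models, the observed \eqn{\delta}, its quantile in each
#' distribution, and the overlap of the two distributions (the greater the
#' overlap, the lower the power to tell the models apart).
#'
#' @slot modelA,modelB the compared model identifiers.
#' @slot deltaNull delta values from data simulated under fitted model a.
#' @slot deltaAlt delta values from data simulated under fitted model b.
#' @slot observedDelta delta on the observed trait.
#' @slot overlap overlap fraction in [0,1] (1 - total-variation distance
#'   estimated from pooled Freedman-Diaconis histograms).
#' @slot quantileNull,quantileAlt quantile of the observed delta in each
#'   distribution.
#' @slot nFailed number of bootstrap refits that failed and were skipped.
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(modelA = "character", modelB = "character",
                 deltaNull = "numeric", deltaAlt = "numeric",
                 observedDelta = "numeric", overlap = "numeric",
                 quantileNull = "numeric", quantileAlt = "numeric",
                 nFailed = "integer"))

setValidity("BootstrapResult", function(object) {
  if (object@overlap < 0 || object@overlap > 1)
    return("overlap must lie in [0,1]")
  TRUE
})

#' SyntheticPanel: simulated ortholog sequence panel with ground truth
#'
#' Per-species sequence sets for a shared list of regions, with motif clusters
#' planted in (gain), deleted from (loss), or shared/absent across (conserved)
#' a designated clade, plus the generating parameters and per-region truth
#' labels. Species backgrounds are independent i.i.d. draws; sequence
#' evolution along the tree is deliberately not modelled.
#'
#' @slot tree the phylogeny whose tips index the species.
#' @slot pwm the planted \linkS4class{PWMatrix}.
#' @slot sequences named list, species -> \code{DNAStringSet} named by region.
#' @slot truth data.frame with columns \code{region}, \code{label}
#'   (conserved/gain/loss), \code{clade}.
#' @slot params generator parameters including the seed.
#' @exportClass SyntheticPanel
setClass("SyntheticPanel",
  representation(tree = "phylo", pwm = "PWMatrix", sequences = "list",
                 truth = "data.frame", params = "list"))

setMethod("show", "PWMatrix", function(object) {
  cat("PWMatrix", object@id,
      if (length(object@name) && nzchar(object@name)) paste0("(", object@name, ")") else "",
      "\n  length:", ncol(object@profile), "bp",
      " information content:", format(object@ic, digits = 4), "bits\n")
})

setMethod("show", "RegimePainting", function(object) {
  cat("RegimePainting", object@model, "on", length(object@tree$tip.label),
      "tips:", sum(object@regimes == "shift"), "shift /",
      sum(object@regimes == "base"), "base branches")
  if (length(object@shiftTips))
    cat("; shifted clade {", paste(object@shiftTips, collapse = ", "), "}")
  cat("\n")
})

setMethod("show", "ClusterScore", function(object) {
  cat("ClusterScore", object@region, "/", object@species, ":",
      format(object@score, digits = 4), "(log2),",
      nrow(object@hits), "sites in [", object@interval[1], ",",
      object@interval[2], ")\n")
})

setMethod("show", "ScoreMatrix", function(object) {
  v <- object@values
  cat("ScoreMatrix:", nrow(v), "regions x", ncol(v), "species,",
      sum(is.na(v)), "missing\n")
})

setMethod("show", "ModelFit", function(object) {
  if (object@untestable) {
    cat("ModelFit", object@model, "(untestable on this trait)\n")
    return(invisible(NULL))
  }
  cat("ModelFit", object@model, ": logLik =", format(object@logLik, digits = 6),
      ", k =", object@k, ", AIC =", format(object@AIC, digits = 6), "\n")
  p <- object@params
  if (!is.null(p$alpha))
    cat("  alpha =", format(p$alpha, digits = 4),
        " sigmaSq =", format(p$sigmaSq, digits = 4),
        " theta =", paste(names(p$theta), format(p$theta, digits = 4),
                          sep = "=", collapse = " "), "\n")
  else
    cat("  x0 =", format(p$x0, digits = 4),
        " sigmaSq =", format(p$sigmaSq, digits = 4), "\n")
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult", object@modelA, "vs", object@modelB, ":",
      length(object@deltaNull), "+", length(object@deltaAlt), "replicates\n",
      " observed delta =", format(object@observedDelta, digits = 5),
      " overlap =", format(object@overlap, digits = 4),
      " null quantile =", format(object@quantileNull, digits = 4), "\n")
})

setMethod("show", "SyntheticPanel", function(object) {
  cat("SyntheticPanel:", nrow(object@truth), "regions x",
      length(object@sequences), "species; labels:",
      paste(names(table(object@truth$label)), table(object@truth$label),
            sep = "=", collapse = " "), "\n")
})
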