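#' Simulate a trait on a painted tree
#'
#' Pre-order recursion from the root: along a branch of length \eqn{t} in
#' regime \eqn{b}, \eqn{X_{child} \sim N(\theta_b + (X_{parent} - \theta_b)
#' e^{-\alpha t},\; \sigma^2 (1 - e^{-2\alpha t})/(2\alpha))}; under BM,
#' \eqn{X_{child} \sim N(X_{parent}, \sigma^2 t)}. The root starts at
#' \code{x0} (default: the root regime's optimum under OU, 0 under BM) with
#' zero variance. An identical seed gives an identical trait.
#'
#' @param tree a validated \code{phylo}.
#' @param painting a \linkS4class{RegimePainting}; its \code{model} slot
#'   selects BM vs OU simulation.
#' @param params named list: for OU \code{alpha}, \code{sigmaSq},
#'   \code{theta} (single value or named by regime), optional \code{x0};
#'   for BM \code{sigmaSq} and optional \code{x0}.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return named numeric vector over the tips.
#' @export
simulateTrait <- function(tree, painting, params, seed = NULL) {
  stopifnot(is(painting, "RegimePainting"))
  validatePhylo(tree)
  if (!is.null(seed)) set.seed(seed)
  bm <- painting@model == "BM"
  sigmaSq <- params$sigmaSq
  if (is.null(sigmaSq) || sigmaSq <= 0) stop("params$sigmaSq must be > 0")
  if (!bm) {
    alpha <- params$alpha
    if (is.null(alpha) || alpha < 0) stop("params$alpha must be >= 0")
    if (alpha == 0) stop("alpha = 0 is the BM limit; use a BM painting")
    regimeNames <- unique(c("base", painting@regimes))
    th <- params$theta
    th <- if (length(th) == 1L && is.null(names(th)))
      stats::setNames(rep(th, length(regimeNames)), regimeNames)
    else th[regimeNames]
    if (anyNA(th)) stop("params$theta must cover every regime")
    x0 <- if (!is.null(params$x0)) params$x0 else th[[painting@rootRegime]]
  } else {
    x0 <- if (!is.null(params$x0)) params$x0 else 0
  }
  n <- length(tree$tip.label)
  nNode <- n + tree$Nnode
  val <- rep(NA_real_, nNode)
  val[n + 1L] <- x0
  ## pre-order: ape cladewise edge order guarantees parents precede children
  ord <- ape::reorder.phylo(tree, "cladewise")
  idx <- match(apply(ord$edge, 1, paste, collapse = "-"),
               apply(tree$edge, 1, paste, collapse = "-"))
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1]; child <- ord$edge[r, 2]
    t <- ord$edge.length[r]
    if (bm) {
      val[child] <- stats::rnorm(1, val[par], sqrt(sigmaSq * t))
    } else {
      reg <- painting@regimes[idx[r]]
      w <- exp(-alpha * t)
      v <- sigmaSq * (-expm1(-2 * alpha * t)) / (2 * alpha)
      val[child] <- stats::rnorm(1, th[[reg]] + (val[par] - th[[reg]]) * w,
                                 sqrt(v))
    }
  }
  stats::setNames(val[seq_len(n)], tree$tip.label)
}

## delta = 2 (logLik a - logLik b) on one trait, refitting both models.
.deltaOn <- function(tree, trait, paintingA, paintingB) {
  fa <- fitModel(tree, paintingA, trait)
  fb <- fitModel(tree, paintingB, trait)
  if (fa@untestable || fb@untestable) return(NA_real_)
  2 * (logLik(fa) - logLik(fb))
}

## Simulation parameters of a fitted model, as simulateTrait expects.
.fitToSimParams <- function(fit) {
  p <- fitParams(fit)
  if (fit@model == "BM") list(sigmaSq = p$sigmaSq, x0 = p$x0)
  else list(alpha = p$alpha, sigmaSq = p$sigmaSq, theta = p$theta,
            x0 = p$x0)
}

#' Parametric-bootstrap power analysis (phylogenetic Monte Carlo)
#'
#' Fits models a and b to the observed trait; simulates \code{nBoot} data
#' sets under each fitted model and refits BOTH models on every set,
#' yielding the null (\code{a}-simulated) and alternative
#' (\code{b}-simulated) distributions of
#' \eqn{\delta = 2(\log L_a - \log L_b)}. The observed \eqn{\delta}'s
#' position in the null distribution measures significance; the overlap of
#' the two distributions measures power (the greater the overlap, the lower
#' the power). Overlap is 1 minus the total-variation distance estimated
#' from pooled Freedman-Diaconis histograms. Failed refits are skipped and
#' counted, never silently replaced.
#'
#' @param tree a validated \code{phylo}.
#' @param trait named numeric trait vector.
#' @param paintingA,paintingB the two compared paintings.
#' @param nBoot bootstrap replicates per model (default 1000; reduce for
#'   desk-scale runs).
#' @param seed integer seed (mandatory for reproducibility).
#' @return a \linkS4class{BootstrapResult}.
#' @export
pmcPower <- function(tree, trait, paintingA, paintingB, nBoot = 1000,
                     seed) {
  stopifnot(nBoot >= 1)
  fa <- fitModel(tree, paintingA, trait)
  fb <- fitModel(tree, paintingB, trait)
  if (fa@untestable || fb@untestable)
    stop("both models must be fittable on the observed trait")
  observed <- 2 * (logLik(fa) - logLik(fb))
  set.seed(seed)
  simBatch <- function(genPainting, genParams) {
    out <- numeric(0); failed <- 0L
    for (i in seq_len(nBoot)) {
      tr <- simulateTrait(tree, genPainting, genParams, seed = NULL)
      d <- tryCatch(.deltaOn(tree, tr, paintingA, paintingB),
                    error = function(e) NA_real_)
      if (is.na(d)) failed <- failed + 1L else out <- c(out, d)
    }
    list(delta = out, failed = failed)
  }
  nullB <- simBatch(paintingA, .fitToSimParams(fa))
  altB <- simBatch(paintingB, .fitToSimParams(fb))
  pooled <- c(nullB$delta, altB$delta)
  overlap <- if (length(unique(pooled)) < 2L) 1 else {
    brk <- .fdBreaks(pooled)
    hN <- graphics::hist(nullB$delta, breaks = brk, plot = FALSE)$counts
    hA <- graphics::hist(altB$delta, breaks = brk, plot = FALSE)$counts
    1 - 0.5 * sum(abs(hN / sum(hN) - hA / sum(hA)))
  }
  new("BootstrapResult", modelA = paintingA@model, modelB = paintingB@model,
      deltaNull = nullB$delta, deltaAlt = altB$delta,
      observedDelta = observed, overlap = overlap,
      quantileNull = stats::ecdf(nullB$delta)(observed),
      quantileAlt = stats::ecdf(altB$delta)(observed),
      nFailed = nullB$failed + altB$failed)
}

## Freedman-Diaconis break points covering the pooled range.
.fdBreaks <- function(x) {
  iqr <- stats::IQR(x)
  h <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else
    diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  if (h <= 0) h <- 1
  nb <- max(1L, ceiling(diff(range(x)) / h))
  seq(min(x) - h / 2, max(x) + h / 2, length.out = nb + 2L)
}

#' Write a parametric-bootstrap report
#'
#' A TSV of the two delta distributions plus a plain-text summary, and
#' optionally the pooled histogram as tab-delimited bins.
#'
#' @param result a \linkS4class{BootstrapResult}.
#' @param prefix output path prefix; writes \code{<prefix>_delta.tsv},
#'   \code{<prefix>_report.txt} and (if \code{histogram}) \code{
#'   <prefix>_hist.tsv}.
#' @param histogram also export binned counts (default TRUE).
#' @return character vector of written paths, invisibly.
#' @export
writePmcReport <- function(result, prefix, histogram = TRUE) {
  d <- deltaDistributions(result)
  df <- rbind(data.frame(model = result@modelA, delta = d$null),
              data.frame(model = result@modelB, delta = d$alt))
  p1 <- paste0(prefix, "_delta.tsv")
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(prefix, "_report.txt")
  writeLines(c(
    sprintf("model a: %s   model b: %s", result@modelA, result@modelB),
    sprintf("replicates: %d + %d (failed refits skipped: %d)",
            length(d$null), length(d$alt), result@nFailed),
    sprintf("observed delta = 2(logLa - logLb): %.6g", observedDelta(result)),
    sprintf("quantile of observed delta in a-null: %.4g", result@quantileNull),
    sprintf("quantile of observed delta in b-alt:  %.4g", result@quantileAlt),
    sprintf("distribution overlap (1 - TV): %.4g", overlapFraction(result)),
    "interpretation: the greater the overlap the lower the power."), p2)
  paths <- c(p1, p2)
  if (histogram) {
    brk <- .fdBreaks(c(d$null, d$alt))
    hN <- graphics::hist(d$null, breaks = brk, plot = FALSE)
    hA <- graphics::hist(d$alt, breaks = brk, plot = FALSE)
    p3 <- paste0(prefix, "_hist.tsv")
    utils::write.table(
      data.frame(binStart = utils::head(brk, -1), binEnd = brk[-1],
                 countNull = hN$counts, countAlt = hA$counts),
      p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
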