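#' Likelihood-ratio test between nested evolutionary models
#'
#' \eqn{LR = 2(\log L_{alt} - \log L_{null})}, clipped at 0, compared with a
#' chi-squared distribution with 1 degree of freedom (the branch-shift model
#' adds exactly one optimum to M0; the root state is pinned to the root
#' regime's optimum so no hidden parameter changes).
#'
#' @param fitNull the null (M0) fit: a \linkS4class{ModelFit} or a bare
#'   log-likelihood.
#' @param fitAlt the alternative (branch-shift) fit, likewise.
#' @param df degrees of freedom (default 1).
#' @return list with \code{LR} and \code{p}.
#' @examples
#' lrTest(0, 28.99 / 2)  # LR = 28.99
#' @export
lrTest <- function(fitNull, fitAlt, df = 1) {
  llN <- if (is(fitNull, "ModelFit")) logLik(fitNull) else as.numeric(fitNull)
  llA <- if (is(fitAlt, "ModelFit")) logLik(fitAlt) else as.numeric(fitAlt)
  if (is(fitNull, "ModelFit") && is(fitAlt, "ModelFit")) {
    kN <- fitNull@k; kA <- fitAlt@k
    if (kA <= kN)
      stop("models are not nested (alternative has no extra parameter); ",
           "use akaikeWeights() for non-nested comparisons")
  }
  if (llA < llN - 1e-6)
    warning("alternative log-likelihood below the null beyond tolerance; ",
            "optimizer artefact, LR clipped at 0")
  LR <- max(0, 2 * (llA - llN))
  list(LR = LR, p = stats::pchisq(LR, df = df, lower.tail = FALSE))
}

#' Akaike weights over a compared model set
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_r \exp(-\Delta_r/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}, computed in the shifted form so that
#' arbitrarily large AIC differences cannot overflow. Weights sum to 1.
#'
#' @param aics numeric vector (>= 2 finite AIC values), optionally named.
#' @return numeric vector of weights in [0,1], same names.
#' @examples
#' akaikeWeights(c(M10 = 100, M0 = 102))
#' @export
akaikeWeights <- function(aics) {
  aics <- unlist(aics)
  if (length(aics) < 2L) stop("need at least 2 AIC values")
  if (any(!is.finite(aics))) stop("non-finite AIC in the compared set")
  d <- aics - min(aics)
  w <- exp(-0.5 * d)
  w / sum(w)
}

#' Direction of a fitted branch shift
#'
#' \code{"gain"} when the shifted clade's optimum exceeds the background
#' optimum, \code{"loss"} when below, \code{"indeterminate"} when the two
#' estimates are equal to within 1e-9.
#'
#' @param fit a branch-shift \linkS4class{ModelFit} (must carry theta_base
#'   and theta_shift).
#' @return \code{"gain"}, \code{"loss"} or \code{"indeterminate"}.
#' @export
classifyDirection <- function(fit) {
  th <- fitParams(fit)$theta
  if (is.null(th) || !all(c("base", "shift") %in% names(th)))
    stop("fit does not carry base and shift optima")
  d <- th[["shift"]] - th[["base"]]
  if (abs(d) < 1e-9) "indeterminate" else if (d > 0) "gain" else "loss"
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, applied across the
#' number of regions and number of models tested. Thin wrapper over
#' \code{p.adjust} with input validation.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call lineage-specific divergence for one region
#'
#' Compares fitted models by Akaike weight. In \code{pairwise} mode (the
#' default, and the most robust in practice) each branch-shift model Mx is
#' weighed against M0 alone: the region is divergent under Mx iff
#' wAIC(Mx) > wAIC(M0), i.e. > 0.5 of the pair. \code{triple} mode weighs
#' {BM, M0, Mx} and \code{all} mode the full model set at once; both are
#' more stringent, the winner being the argmax weight. Ties are broken
#' toward the model with fewer parameters. The LR test against M0 and the
#' shift direction are reported alongside.
#'
#' @param fits named list of \linkS4class{ModelFit} including \code{"M0"}
#'   (as returned by \code{\link{fitRegion}}).
#' @param mode \code{"pairwise"}, \code{"triple"} or \code{"all"}.
#' @param region region identifier carried into the output.
#' @return data.frame with one row per branch-shift model: model, wAIC,
#'   wAIC_M0, LR, p, direction, divergent.
#' @export
callDivergence <- function(fits, mode = c("pairwise", "triple", "all"),
                           region = "region") {
  mode <- match.arg(mode)
  if (!"M0" %in% names(fits)) stop("fits must include the M0 null model")
  ok <- !vapply(fits, isUntestable, logical(1))
  fits <- fits[ok]
  shiftModels <- names(fits)[vapply(fits, function(f)
    !is.null(fitParams(f)$theta) &&
      "shift" %in% names(fitParams(f)$theta), logical(1))]
  if (!length(shiftModels))
    return(data.frame(region = character(0), model = character(0),
                      wAIC = numeric(0), wAIC_M0 = numeric(0),
                      LR = numeric(0), p = numeric(0),
                      direction = character(0), divergent = logical(0)))
  rows <- lapply(shiftModels, function(m) {
    cmp <- switch(mode,
      pairwise = c(m, "M0"),
      triple = intersect(c("BM", "M0", m), names(fits)),
      all = names(fits))
    w <- akaikeWeights(vapply(fits[cmp], AIC, numeric(1)))
    ## tie toward fewer parameters: subtract an infinitesimal rank penalty
    ks <- vapply(fits[cmp], function(f) f@k, numeric(1))
    winner <- cmp[order(-w, ks)][1]
    lr <- lrTest(fits$M0, fits[[m]])
    divergent <- if (mode == "pairwise") winner == m else winner == m
    data.frame(region = region, model = m,
               wAIC = unname(w[m]), wAIC_M0 = unname(w["M0"]),
               LR = lr$LR, p = lr$p,
               direction = classifyDirection(fits[[m]]),
               divergent = divergent)
  })
  do.call(rbind, rows)
}

#' Build a divergence-call table over many regions (one PWM / trait table)
#'
#' Runs \code{\link{fitRegion}} + \code{\link{callDivergence}} on every row
#' of a trait table and stacks the calls; optionally BH-adjusts the LR
#' p-values across regions x models and applies the minimum-score filter
#' (retain calls only where the region's maximum tip trait reaches a
#' threshold, as in focussed case studies).
#'
#' @param traits a \linkS4class{ScoreMatrix} or bare region x species
#'   matrix.
#' @param tree the phylogeny.
#' @param paintings named list of paintings (default
#'   \code{builtinRegimes(tree)}).
#' @param mode comparison mode, see \code{\link{callDivergence}}.
#' @param minScore optional minimum max-tip score filter (default off).
#' @param adjust add a BH-adjusted p column across all calls (default TRUE).
#' @param pwm PWM identifier carried into the table.
#' @return data.frame of divergence calls (columns as
#'   \code{\link{callDivergence}} plus \code{pwm} and \code{p_adj}).
#' @export
divergenceTable <- function(traits, tree, paintings = builtinRegimes(tree),
                            mode = "pairwise", minScore = NULL,
                            adjust = TRUE, pwm = "pwm") {
  v <- if (is(traits, "ScoreMatrix")) scoreValues(traits) else traits
  calls <- list()
  for (rg in rownames(v)) {
    trait <- v[rg, ]
    if (sum(!is.na(trait)) < 3L) next
    if (!is.null(minScore) && max(trait, na.rm = TRUE) < minScore) next
    fits <- fitRegion(tree, trait, paintings)
    calls[[rg]] <- callDivergence(fits, mode = mode, region = rg)
  }
  if (!length(calls))
    return(data.frame(pwm = character(0), region = character(0),
                      model = character(0), wAIC = numeric(0),
                      wAIC_M0 = numeric(0), LR = numeric(0), p = numeric(0),
                      direction = character(0), divergent = logical(0),
                      p_adj = numeric(0)))
  df <- do.call(rbind, calls)
  df <- cbind(pwm = pwm, df)
  if (adjust) df$p_adj <- bhAdjust(df$p)
  rownames(df) <- NULL
  df
}

#' Write a divergence database directory
#'
#' One calls TSV per PWM plus per-(model, direction) region-id lists under
#' \code{<dir>/<pwm>/<model>_<direction>.txt}, mirroring a downloadable
#' divergence-table layout.
#'
#' @param calls data.frame of calls (stacked \code{\link{divergenceTable}}
#'   output over PWMs).
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeDivergenceDb <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pw in unique(calls$pwm)) {
    sub <- calls[calls$pwm == pw, ]
    pdir <- file.path(dir, pw)
    if (!dir.exists(pdir)) dir.create(pdir)
    utils::write.table(sub, file.path(pdir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    div <- sub[sub$divergent, ]
    for (m in unique(div$model)) for (d in unique(div$direction)) {
      ids <- div$region[div$model == m & div$direction == d]
      if (length(ids))
        writeLines(ids, file.path(pdir, paste0(m, "_", d, ".txt")))
    }
  }
  invisible(dir)
}

#' Read a divergence database directory back into a calls table
#'
#' @param dir directory written by \code{\link{writeDivergenceDb}}.
#' @return stacked calls data.frame.
#' @export
readDivergenceDb <- function(dir) {
  files <- list.files(dir, pattern = "^calls\\.tsv$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no calls.tsv found under ", dir)
  do.call(rbind, lapply(files, function(f)
    utils::read.delim(f, stringsAsFactors = FALSE)))
}
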