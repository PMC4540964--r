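## Trait-evolution likelihoods on a painted tree.
##
## All models are Gaussian: a trait vector at the tips is multivariate normal
## with mean and covariance determined by the process.
##
##  BM:     dX = sigma dB(t).  E[X_i] = x0;  V_ij = sigma^2 * t_ij, with t_ij
##          the root-to-MRCA path length of tips i, j.
##  Hansen: dX = alpha (theta_b - X) dt + sigma dB(t), with the optimum
##          theta_b depending on the branch's regime.  The process starts at
##          the root with value x0 and zero variance, so
##            E[X_i]  = x0 e^{-alpha s_i}
##                    + sum_{branches b on the root->i path}
##                      theta_{regime(b)} (e^{-alpha (s_i - tEnd_b)}
##                                       - e^{-alpha (s_i - tStart_b)})
##            V_ij    = sigma^2/(2 alpha) e^{-alpha (s_i + s_j - 2 t_ij)}
##                      (1 - e^{-2 alpha t_ij})
##          where s_i is the root-to-tip depth.  x0 is pinned to the root
##          regime's theta, which keeps the parameter count at 3 for M0 and 4
##          for a branch-shift model (so the M0-vs-Mx LR has df = 1).
##
## ML fitting profiles the likelihood over alpha: at fixed alpha the tip
## means are linear in the theta vector through the exponential weight
## matrix, so theta is solved by generalized least squares and sigma^2 in
## closed form from the weighted residuals; alpha is then maximised by a
## deterministic log-spaced grid plus 1-D refinement.

## Geometry shared by every likelihood evaluation on one tree: tip depths,
## MRCA depth matrix, and the per-tip path incidence over edges.
.treeGeometry <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  s <- depth[seq_len(n)]
  mr <- ape::mrca(tree)
  T <- matrix(depth[mr], n, n, dimnames = list(tree$tip.label,
                                               tree$tip.label))
  E <- nrow(tree$edge)
  P <- matrix(0, n, E)
  for (e in seq_len(E)) {
    child <- tree$edge[e, 2]
    tipsBelow <- if (child <= n) child else {
      dn <- .descendantNodes(tree, child)
      dn[dn <= n]
    }
    P[tipsBelow, e] <- 1
  }
  list(n = n, s = stats::setNames(s, tree$tip.label), T = T, P = P,
       tStart = depth[tree$edge[, 1]], tEnd = depth[tree$edge[, 2]],
       height = max(s), tips = tree$tip.label)
}

## Hansen design at fixed alpha: W (n x regimes) mean weights and V0, the
## unit-sigma^2 covariance. Regime columns follow `regimeNames`.
.hansenDesign <- function(geom, edgeRegime, rootRegime, alpha, regimeNames) {
  eTerm <- exp(alpha * geom$tEnd) - exp(alpha * geom$tStart)
  damp <- exp(-alpha * geom$s)
  W <- matrix(0, geom$n, length(regimeNames),
              dimnames = list(geom$tips, regimeNames))
  for (r in regimeNames) {
    sel <- edgeRegime == r
    W[, r] <- if (any(sel))
      damp * as.vector(geom$P[, sel, drop = FALSE] %*% eTerm[sel]) else 0
  }
  W[, rootRegime] <- W[, rootRegime] + damp
  S1 <- outer(geom$s, geom$s, "+")
  V0 <- exp(-alpha * (S1 - 2 * geom$T)) * (-expm1(-2 * alpha * geom$T)) /
        (2 * alpha)
  list(W = W, V0 = V0)
}

.cholSolve <- function(V0, label = "covariance") {
  L <- tryCatch(chol(V0), error = function(e)
    stop("singular ", label, " matrix (duplicate or zero-length tips?); ",
         "consider jittering branch lengths"))
  L
}

#' Brownian-motion log-likelihood of a trait on a tree
#'
#' Multivariate normal log-density with mean \code{x0} at every tip and
#' covariance \eqn{\sigma^2 t_{ij}} (shared root-to-MRCA path length).
#'
#' @param tree a validated \code{phylo}.
#' @param trait named numeric vector, names = tip labels (subset allowed;
#'   the tree is pruned to the named tips).
#' @param x0 root state (trait units).
#' @param sigmaSq diffusion intensity, trait^2 per unit time; > 0.
#' @return log-likelihood (natural log).
#' @export
bmLoglik <- function(tree, trait, x0, sigmaSq) {
  if (sigmaSq <= 0) stop("sigmaSq must be > 0")
  pt <- .pruneToTrait(tree, trait)
  geom <- .treeGeometry(pt$tree)
  V <- sigmaSq * geom$T
  L <- .cholSolve(V)
  r <- pt$x - x0
  z <- forwardsolve(t(L), r)
  -0.5 * (geom$n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

#' Hansen (branch-shift OU) log-likelihood
#'
#' Multivariate normal log-density under the branch-shift
#' Ornstein-Uhlenbeck process; see the package vignette for the tip mean and
#' covariance construction. The process starts at the root at \code{x0}
#' (default: the root regime's optimum) with zero variance. As
#' \eqn{\alpha \to 0} this converges to the BM likelihood at matched
#' \code{sigmaSq} and \code{x0}.
#'
#' @param tree a validated \code{phylo}.
#' @param painting a \linkS4class{RegimePainting} on \code{tree}.
#' @param trait named numeric vector over (a subset of) the tips.
#' @param alpha selection strength (1/time); must be > 0 (use
#'   \code{\link{bmLoglik}} for the drift limit).
#' @param sigmaSq diffusion intensity; > 0.
#' @param theta optimum per regime: single value, or named vector with
#'   entries \code{base} and \code{shift}.
#' @param x0 root state; default \code{theta[rootRegime(painting)]}.
#' @return log-likelihood (natural log).
#' @export
hansenLoglik <- function(tree, painting, trait, alpha, sigmaSq, theta,
                         x0 = NULL) {
  if (alpha <= 0)
    stop("alpha must be > 0; for the alpha = 0 drift limit use bmLoglik()")
  if (sigmaSq <= 0) stop("sigmaSq must be > 0")
  stopifnot(is(painting, "RegimePainting"))
  pt <- .pruneToTrait(tree, trait)
  pp <- if (identical(sort(pt$tree$tip.label), sort(tree$tip.label)))
    painting else repaint(painting, pt$tree)
  if (is.null(pp)) stop("painting untestable on the pruned tree")
  regimeNames <- unique(c("base", pp@regimes))
  th <- if (length(theta) == 1L && is.null(names(theta)))
    stats::setNames(rep(theta, length(regimeNames)), regimeNames)
  else {
    if (!all(regimeNames %in% names(theta)))
      stop("theta must name every regime: ",
           paste(regimeNames, collapse = ", "))
    theta[regimeNames]
  }
  if (is.null(x0)) x0 <- th[[pp@rootRegime]]
  geom <- .treeGeometry(pp@tree)
  d <- .hansenDesign(geom, pp@regimes, pp@rootRegime, alpha, regimeNames)
  mu <- as.vector(d$W %*% th)
  ## replace the root-regime column's root contribution when x0 is custom
  if (x0 != th[[pp@rootRegime]])
    mu <- mu + exp(-alpha * geom$s) * (x0 - th[[pp@rootRegime]])
  V <- sigmaSq * d$V0
  L <- .cholSolve(V)
  z <- forwardsolve(t(L), pt$x[geom$tips] - mu)
  -0.5 * (geom$n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

## Drop NA trait entries and prune the tree to the remaining tips. Plain
## likelihood evaluation works from 2 tips; model fitting requires >= 3.
.pruneToTrait <- function(tree, trait, minTips = 2L) {
  validatePhylo(tree)
  x <- trait[!is.na(trait)]
  if (is.null(names(x)) || !all(names(x) %in% tree$tip.label))
    stop("trait must be named by tip labels present in the tree")
  if (any(!is.finite(x))) stop("trait values must be finite")
  if (length(x) < minTips)
    stop("need trait values for at least ", minTips, " tips")
  tr <- if (length(x) == length(tree$tip.label)) tree
        else ape::keep.tip(tree, names(x))
  list(tree = tr, x = x[tr$tip.label])
}

## Profile log-likelihood machinery at fixed alpha on prepared geometry.
## Returns loglik, GLS theta-hat, sigma^2-hat and the degeneracy flag.
.profileAt <- function(alpha, geom, edgeRegime, rootRegime, regimeNames, x) {
  d <- .hansenDesign(geom, edgeRegime, rootRegime, alpha, regimeNames)
  L <- .cholSolve(d$V0)
  Wt <- forwardsolve(t(L), d$W)
  xt <- forwardsolve(t(L), x)
  XtX <- crossprod(Wt)
  theta <- tryCatch(as.vector(solve(XtX, crossprod(Wt, xt))),
                    error = function(e) NULL)
  if (is.null(theta)) {
    ## alpha -> 0 collapses the regime columns (theta_shift unidentifiable):
    ## the supremum is the equal-optima solution, whose design is the row
    ## sum of W (exactly 1 by telescoping)
    ot <- forwardsolve(t(L), rep(1, geom$n))
    t0 <- sum(ot * xt) / sum(ot^2)
    theta <- rep(t0, length(regimeNames))
  }
  resid <- xt - Wt %*% theta
  q <- sum(resid^2)
  n <- geom$n
  s2 <- q / n
  degenerate <- FALSE
  if (s2 < 1e-12) { s2 <- 1e-12; degenerate <- TRUE }
  ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + q / s2)
  list(loglik = ll, theta = stats::setNames(theta, regimeNames),
       sigmaSq = s2, degenerate = degenerate)
}

#' Maximum-likelihood fit of one evolutionary model
#'
#' Fits BM, the single-optimum OU model (M0) or a branch-shift Hansen model
#' to one trait vector. Missing species are pruned and the painting
#' re-derived on the induced subtree; when every shifted tip is missing the
#' model is returned as untestable (a distinct state, not a failure). A
#' constant trait is fitted with the residual variance floored at 1e-12 and
#' flagged degenerate.
#'
#' @param tree a validated \code{phylo}.
#' @param painting a \linkS4class{RegimePainting} (its \code{model} slot
#'   decides BM vs OU fitting).
#' @param trait named numeric trait vector.
#' @param alphaBounds search bounds for alpha; default
#'   \code{c(1e-8, 100/treeHeight)}.
#' @param alphaExtra extra alpha candidates injected into the profile search
#'   (used by \code{\link{fitRegion}} to guarantee the nesting inequality
#'   max logLik(Mx) >= max logLik(M0)).
#' @return a \linkS4class{ModelFit}.
#' @export
fitModel <- function(tree, painting, trait, alphaBounds = NULL,
                     alphaExtra = numeric(0)) {
  stopifnot(is(painting, "RegimePainting"))
  pt <- .pruneToTrait(tree, trait, minTips = 3L)
  if (painting@model == "BM") return(.fitBM(pt))
  pp <- if (identical(sort(pt$tree$tip.label),
                      sort(painting@tree$tip.label)))
    painting else repaint(painting, pt$tree)
  if (is.null(pp))
    return(new("ModelFit", model = painting@model, params = list(),
               logLik = NA_real_, k = NA_real_, AIC = NA_real_,
               nTips = length(pt$x), degenerate = FALSE, untestable = TRUE))
  geom <- .treeGeometry(pp@tree)
  regimeNames <- unique(c("base", pp@regimes))
  if (is.null(alphaBounds)) alphaBounds <- c(1e-8, 100 / geom$height)
  x <- pt$x[geom$tips]
  prof <- function(a) .profileAt(a, geom, pp@regimes, pp@rootRegime,
                                 regimeNames, x)$loglik
  cand <- sort(c(
    exp(seq(log(alphaBounds[1]), log(alphaBounds[2]), length.out = 9)),
    pmin(pmax(alphaExtra, alphaBounds[1]), alphaBounds[2])))
  cand <- cand[c(TRUE, diff(log(cand)) > 1e-10)]  # drop log-scale dupes
  vals <- vapply(cand, prof, numeric(1))
  iBest <- which.max(vals)
  lo <- if (iBest > 1L) cand[iBest - 1L] else cand[1L]
  hi <- if (iBest < length(cand)) cand[iBest + 1L] else cand[length(cand)]
  aHat <- cand[iBest]; llHat <- vals[iBest]
  if (log(hi) - log(lo) > 1e-9) {
    opt <- stats::optimize(function(la) prof(exp(la)),
                           interval = log(c(lo, hi)), maximum = TRUE,
                           tol = 1e-8)
    if (opt$objective > llHat) { aHat <- exp(opt$maximum); llHat <- opt$objective }
  }
  ## boundary handling: if the profile at a bound matches (or beats) the
  ## interior maximum within convergence tolerance, alpha is effectively
  ## unidentified up to that bound — report it via alphaAtBound
  llLo <- vals[1]; llHi <- vals[length(vals)]
  if (llLo >= llHat) { aHat <- alphaBounds[1]; llHat <- llLo }
  if (llHi > llHat) { aHat <- alphaBounds[2]; llHat <- llHi }
  atBound <- aHat <= alphaBounds[1] * (1 + 1e-9) ||
             aHat >= alphaBounds[2] / (1 + 1e-9) ||
             llLo >= llHat - 1e-6 || llHi >= llHat - 1e-6
  best <- .profileAt(aHat, geom, pp@regimes, pp@rootRegime, regimeNames, x)
  k <- 2 + length(regimeNames)          # alpha, sigma^2, theta per regime
  ll <- best$loglik
  new("ModelFit", model = painting@model,
      params = list(alpha = aHat, sigmaSq = best$sigmaSq,
                    theta = best$theta, x0 = best$theta[[pp@rootRegime]],
                    rootRegime = pp@rootRegime, alphaBounds = alphaBounds,
                    alphaAtBound = atBound),
      logLik = ll, k = k, AIC = 2 * k - 2 * ll,
      nTips = geom$n, degenerate = best$degenerate, untestable = FALSE)
}

## BM closed-form ML: GLS intercept + residual quadratic form.
.fitBM <- function(pt) {
  geom <- .treeGeometry(pt$tree)
  L <- .cholSolve(geom$T, "BM covariance")
  one <- rep(1, geom$n)
  ot <- forwardsolve(t(L), one)
  xt <- forwardsolve(t(L), pt$x[geom$tips])
  x0 <- sum(ot * xt) / sum(ot^2)
  q <- sum((xt - x0 * ot)^2)
  s2 <- q / geom$n
  degenerate <- FALSE
  if (s2 < 1e-12) { s2 <- 1e-12; degenerate <- TRUE }
  ll <- -0.5 * (geom$n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + q / s2)
  new("ModelFit", model = "BM",
      params = list(x0 = x0, sigmaSq = s2),
      logLik = ll, k = 2, AIC = 4 - 2 * ll, nTips = geom$n,
      degenerate = degenerate, untestable = FALSE)
}

#' Fit a set of evolutionary models to one region's trait
#'
#' Fits every painting in \code{paintings} to the trait. M0's estimated
#' alpha is injected as an extra profile candidate into every branch-shift
#' fit, which enforces the nesting property
#' \code{logLik(Mx) >= logLik(M0) - tol} (Mx contains M0 at equal optima).
#'
#' @param tree a validated \code{phylo}.
#' @param trait named numeric trait vector.
#' @param paintings named list of \linkS4class{RegimePainting} objects
#'   (default \code{builtinRegimes(tree)}).
#' @return named list of \linkS4class{ModelFit} objects.
#' @export
fitRegion <- function(tree, trait, paintings = builtinRegimes(tree)) {
  stopifnot(length(paintings) > 0)
  if (is.null(names(paintings)))
    names(paintings) <- vapply(paintings, modelId, character(1))
  fits <- list()
  a0 <- numeric(0)
  if ("M0" %in% names(paintings)) {
    fits$M0 <- fitModel(tree, paintings$M0, trait)
    a0 <- fits$M0@params$alpha
  }
  for (m in setdiff(names(paintings), "M0"))
    fits[[m]] <- fitModel(tree, paintings[[m]], trait, alphaExtra = a0)
  fits[names(paintings)]
}

#' Write model fits as a TSV report
#'
#' One row per (region, model): alpha, sigma^2, theta_base, theta_shift,
#' logLik, k, AIC. Log-likelihoods are written at full precision.
#'
#' @param fits named list (region -> named list of \linkS4class{ModelFit}),
#'   or a single region's fit list.
#' @param file output path.
#' @return the data.frame written, invisibly.
#' @export
writeFitTable <- function(fits, file) {
  if (length(fits) && is(fits[[1]], "ModelFit")) fits <- list(region = fits)
  rows <- list()
  for (rg in names(fits)) for (m in names(fits[[rg]])) {
    f <- fits[[rg]][[m]]
    p <- f@params
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, model = f@model,
      alpha = if (!is.null(p$alpha)) p$alpha else NA_real_,
      sigmaSq = if (!is.null(p$sigmaSq)) p$sigmaSq else NA_real_,
      theta_base = if (!is.null(p$theta)) unname(p$theta["base"]) else
        if (!is.null(p$x0)) p$x0 else NA_real_,
      theta_shift = if (!is.null(p$theta) && "shift" %in% names(p$theta))
        unname(p$theta["shift"]) else NA_real_,
      logLik = f@logLik, k = f@k, AIC = f@AIC,
      untestable = f@untestable, degenerate = f@degenerate)
  }
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, trim = TRUE), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}
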