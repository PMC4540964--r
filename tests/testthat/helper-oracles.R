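## Independent oracles used across the suite. Each re-derives the target
## quantity by a route the package itself never takes: exhaustive
## enumeration for the cluster score and the hypergeometric tail, a
## recursive moment construction plus dense solve() for the Hansen
## likelihood.

## ---- cluster-score oracle: exhaustive parse enumeration ------------------

oracleEncode <- function(seq) match(strsplit(toupper(seq), "")[[1]],
                                    c("A", "C", "G", "T"))

## strand-symmetrised background, same convention as the scorer
oracleBackground <- function(x) {
  nA <- sum(x == 1); nC <- sum(x == 2); nG <- sum(x == 3); nT <- sum(x == 4)
  tot <- nA + nC + nG + nT + 4
  at <- (nA + nT + 2) / (2 * tot); cg <- (nC + nG + 2) / (2 * tot)
  c(at, cg, cg, at)
}

## odds ratio of a site starting at p (1-based), either strand
oracleOdds <- function(x, prof, q, p, strand) {
  w <- ncol(prof)
  s <- x[p:(p + w - 1)]
  if (strand == "-") {
    rc <- rev(5 - s)
    prod(prof[cbind(rc, seq_len(w))]) / prod(q[s])
  } else {
    prod(prof[cbind(s, seq_len(w))]) / prod(q[s])
  }
}

## sum over every legal placement set of motif instances within [a, b]
oracleSegmentRatio <- function(x, prof, q, tau, a, b) {
  w <- ncol(prof)
  len <- b - a + 1
  total <- 0
  rec <- function(from, nSites, prod) {
    total <<- total + prod * (1 - tau)^(len - w * nSites)
    if (from > b - w + 1) return(invisible(NULL))
    for (p in from:(b - w + 1)) {
      for (st in c("+", "-")) {
        o <- oracleOdds(x, prof, q, p, st)
        rec(p + w, nSites + 1, prod * (tau / 2) * o)
      }
    }
  }
  rec(a, 0, 1)
  total
}

## max over all subsegments, log2, floored at 0 — the CRM score definition
oracleCrmScore <- function(seq, pwm, expectedGap = 35) {
  x <- oracleEncode(seq)
  prof <- crmEvol::motifProfile(pwm)
  q <- oracleBackground(x)
  tau <- 1 / (1 + expectedGap)
  n <- length(x)
  best <- 1
  for (a in seq_len(n)) for (b in a:n)
    best <- max(best, oracleSegmentRatio(x, prof, q, tau, a, b))
  log2(best)
}

## ---- Hansen likelihood oracle: recursive moments + dense MVN -------------

oracleHansenLoglik <- function(tree, painting, trait, alpha, sigmaSq,
                               theta, x0 = NULL) {
  n <- length(tree$tip.label)
  reg <- painting@regimes
  th <- if (length(theta) == 1 && is.null(names(theta)))
    setNames(rep(theta, 2), c("base", "shift")) else theta
  if (is.null(x0)) x0 <- th[[painting@rootRegime]]
  nNode <- n + tree$Nnode
  Ev <- rep(NA_real_, nNode); Vv <- rep(NA_real_, nNode)
  Ev[n + 1] <- x0; Vv[n + 1] <- 0
  ord <- ape::reorder.phylo(tree, "cladewise")
  idx <- match(apply(ord$edge, 1, paste, collapse = "-"),
               apply(tree$edge, 1, paste, collapse = "-"))
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1]; ch <- ord$edge[r, 2]; t <- ord$edge.length[r]
    o <- th[[reg[idx[r]]]]
    Ev[ch] <- o + (Ev[par] - o) * exp(-alpha * t)
    Vv[ch] <- Vv[par] * exp(-2 * alpha * t) +
      sigmaSq * (1 - exp(-2 * alpha * t)) / (2 * alpha)
  }
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = FALSE)
  V <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- if (i == j) i else mr[i, j]
    V[i, j] <- Vv[m] * exp(-alpha * (depth[i] - depth[m])) *
      exp(-alpha * (depth[j] - depth[m]))
  }
  x <- trait[tree$tip.label]
  r <- x - Ev[seq_len(n)]
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
          drop(r %*% solve(V, r)))
}

## ---- hypergeometric upper tail: direct combinatorial sum -----------------

oracleHyper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## ---- shared fixtures -----------------------------------------------------

tinyConsensusPwm <- function(counts = 60, len = 3, bases = c(1, 2, 3)) {
  m <- matrix(1, 4, len)
  for (j in seq_len(len)) m[bases[j], j] <- counts
  crmEvol::pwMatrix(m, id = "cons")
}

randomPwm <- function(len, strength = 20) {
  m <- matrix(stats::rexp(4 * len), 4, len)
  j <- sample(4, len, replace = TRUE)
  m[cbind(j, seq_len(len))] <- m[cbind(j, seq_len(len))] + strength
  crmEvol::pwMatrix(m, id = "rand")
}

randomSeqStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

## random rooted tree with a random monophyletic shift clade
randomPaintedTree <- function(nTips) {
  tr <- ape::rtree(nTips, rooted = TRUE)
  tr$edge.length <- tr$edge.length + 0.1
  internal <- (nTips + 2):(nTips + tr$Nnode)
  node <- if (length(internal)) sample(c(seq_len(nTips), internal), 1)
          else sample(seq_len(nTips), 1)
  tips <- if (node <= nTips) tr$tip.label[node]
          else ape::extract.clade(tr, node)$tip.label
  if (length(tips) == nTips) tips <- tips[1]
  list(tree = tr, painting = crmEvol::paintClade(tr, tips, "Mx"))
}

fiveTipTree <- function()
  crmEvol::parseNewick(
    "((A:0.3,B:0.3):0.4,((C:0.2,D:0.2):0.3,E:0.5):0.2);")
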