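## Homotypic-cluster scoring.
##
## Model: a candidate cluster segment is parsed into motif occurrences (either
## strand) and background bases. At each step the cluster model emits a
## background base with probability (1 - tau) or starts a motif occurrence
## with probability tau (strands equiprobable); tau = 1/(1 + expectedGap)
## makes inter-site gap lengths geometric with the requested mean. The score
## of a segment is log2 of the forward-algorithm sum over ALL parses divided
## by the background-only likelihood of the same segment (background emission
## probabilities cancel, so only per-site odds ratios and the tau weights
## remain). The region's CRM score is the maximum over all subsegments,
## floored at 0: the empty cluster scores 0 and single strong matches count
## as one-site clusters.

.BASES <- c("A", "C", "G", "T")

.encodeSeq <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c(.BASES, "N"))
  if (anyNA(x))
    stop("sequence contains characters outside {A,C,G,T,N}")
  x  # 1..4 bases, 5 = N
}

## Strand-symmetrised 0th-order background from the region itself (+1
## pseudocount per base pair class) so that score(seq) == score(revcomp).
.regionBackground <- function(x) {
  nA <- sum(x == 1L); nC <- sum(x == 2L); nG <- sum(x == 3L); nT <- sum(x == 4L)
  tot <- nA + nC + nG + nT + 4
  at <- (nA + nT + 2) / (2 * tot)
  cg <- (nC + nG + 2) / (2 * tot)
  c(A = at, C = cg, G = cg, T = at)
}

## Per-end-position site odds ratios (numerator PWM emission over background)
## for both strands; positions covering N contribute factor 1. Returns a
## vector over site END positions (NA-free; 0 where the site does not fit).
.siteOdds <- function(x, profile, q) {
  w <- ncol(profile)
  n <- length(x)
  if (n < w) return(numeric(0))
  loF <- rbind(log(profile / q), rep(0, w))          # 5th row: N -> ratio 1
  comp <- c(4L, 3L, 2L, 1L, 5L)
  profRC <- profile[comp[1:4], rev(seq_len(w)), drop = FALSE]
  rownames(profRC) <- .BASES
  loR <- rbind(log(profRC / q), rep(0, w))
  accF <- numeric(n - w + 1L)
  accR <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    b <- x[seq.int(j, n - w + j)]
    accF <- accF + loF[cbind(b, j)]
    accR <- accR + loR[cbind(b, j)]
  }
  ends <- seq.int(w, n)
  odds <- numeric(n)
  odds[ends] <- exp(accF) + exp(accR)   # strands pooled with weight 1/2 later
  odds
}

#' Homotypic-cluster CRM score of a sequence
#'
#' Scores a nucleotide sequence against one PWM with the forward-algorithm
#' cluster HMM: the reported score is the log2 likelihood ratio (cluster
#' model vs background-only) of the best-scoring subsegment, floored at 0.
#' The forward sum aggregates over every legal placement of motif instances
#' on both strands with a geometric prior on inter-site gaps, so clusters of
#' several weak sites and single strong matches both score. An exact
#' all-starts recursion is used, making the maximisation over subsegments
#' (and the floor at 0) exact rather than heuristic.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @param pwm a \linkS4class{PWMatrix}.
#' @param expectedGap expected background gap between neighbouring sites of a
#'   cluster, in bp (geometric prior; default 35).
#' @param background optional length-4 background base probabilities (A,C,G,T);
#'   default: strand-symmetrised frequencies of the scored region itself.
#' @param region,species labels stored in the result.
#' @return a \linkS4class{ClusterScore}.
#' @examples
#' pwm <- pwMatrix(matrix(c(40, 0, 0, 0,  0, 40, 0, 0,  0, 0, 40, 0), 4, 3),
#'                 id = "ACG")
#' clusterScore(crmScore("TTACGTTTTACGTT", pwm))
#' @export
crmScore <- function(seq, pwm, expectedGap = 35, background = NULL,
                     region = "region", species = "") {
  stopifnot(is(pwm, "PWMatrix"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty nucleotide string")
  if (expectedGap <= 0) stop("expectedGap must be positive")
  x <- .encodeSeq(seq)
  n <- length(x)
  w <- ncol(pwm@profile)
  q <- if (is.null(background)) .regionBackground(x) else {
    stopifnot(length(background) == 4L, all(background > 0))
    stats::setNames(background / sum(background), .BASES)
  }
  tau <- 1 / (1 + expectedGap)
  empty <- new("ClusterScore", region = region, species = species,
               score = 0, interval = c(0L, 0L),
               hits = data.frame(start = integer(0), strand = character(0),
                                 logOdds = numeric(0)))
  if (n < w) return(empty)

  odds <- .siteOdds(x, pwm@profile, q)
  fwd <- .forwardAllStarts(odds, n, w, tau)
  if (fwd$logBest <= 0) return(empty)
  hits <- .viterbiHits(x, pwm@profile, q, fwd$bestA, fwd$bestB, w, tau)
  new("ClusterScore", region = region, species = species,
      score = fwd$logBest / log(2),
      interval = c(fwd$bestA - 1L, fwd$bestB),
      hits = hits)
}

## Exact forward recursion over all segment starts. F_b[a] is the parse-sum
## ratio of segment [a..b]; stored with F_b[b+1] = 1 (empty segment) and 0
## beyond, so the vector recursion
##   F_b = (1-tau) F_{b-1} + (tau/2) odds[b] F_{b-w}
## is correct for every start simultaneously. Values are kept on a common
## log2 offset that is renormalised when they grow large, so arbitrarily
## strong clusters cannot overflow. Returns the best natural-log ratio and
## its segment.
.forwardAllStarts <- function(odds, n, w, tau) {
  ring <- vector("list", w + 1L)
  f0 <- numeric(n + 1L); f0[1L] <- 1
  ring[[1L]] <- f0
  scaleLog <- 0                       # natural-log offset of stored values
  bestLog <- -Inf; bestA <- 0L; bestB <- 0L
  oneMinusTau <- 1 - tau
  halfTau <- tau / 2
  for (b in seq_len(n)) {
    prev <- ring[[((b - 1L) %% (w + 1L)) + 1L]]
    cur <- oneMinusTau * prev
    if (b >= w && odds[b] > 0) {
      back <- ring[[((b - w) %% (w + 1L)) + 1L]]
      cur <- cur + (halfTau * odds[b]) * back
    }
    cur[b + 1L] <- exp(-scaleLog)     # empty segment, true value 1
    if (b + 2L <= n + 1L) cur[(b + 2L):(n + 1L)] <- 0
    m <- max(cur[seq_len(b)])
    if (m > 0 && log(m) + scaleLog > bestLog) {
      bestLog <- log(m) + scaleLog
      bestA <- which.max(cur[seq_len(b)])
      bestB <- b
    }
    if (m > 1e250) {                  # renormalise the whole ring
      for (j in seq_along(ring))
        if (!is.null(ring[[j]])) ring[[j]] <- ring[[j]] / m
      cur <- cur / m
      scaleLog <- scaleLog + log(m)
    }
    ring[[(b %% (w + 1L)) + 1L]] <- cur
  }
  list(logBest = bestLog, bestA = bestA, bestB = bestB)
}

## Max-product (Viterbi) parse of the best segment, to annotate site
## positions and strands; the score itself always comes from the forward sum.
.viterbiHits <- function(x, profile, q, a, b, w, tau) {
  emptyHits <- data.frame(start = integer(0), strand = character(0),
                          logOdds = numeric(0))
  if (a < 1L || b < a) return(emptyHits)
  seg <- x[a:b]
  m <- length(seg)
  loF <- rbind(log(profile / q), rep(0, w))
  comp <- c(4L, 3L, 2L, 1L, 5L)
  profRC <- profile[comp[1:4], rev(seq_len(w)), drop = FALSE]
  loR <- rbind(log(profRC / q), rep(0, w))
  best <- c(0, rep(-Inf, m))          # best[i+1] = best log-ratio of seg[1..i]
  from <- integer(m); kind <- character(m)
  lo1 <- log(1 - tau); loS <- log(tau / 2)
  for (i in seq_len(m)) {
    bg <- best[i] + lo1
    best[i + 1L] <- bg; from[i] <- i - 1L; kind[i] <- "bg"
    if (i >= w) {
      pos <- seg[(i - w + 1L):i]
      sF <- sum(loF[cbind(pos, seq_len(w))])
      sR <- sum(loR[cbind(pos, seq_len(w))])
      candF <- best[i - w + 1L] + loS + sF
      candR <- best[i - w + 1L] + loS + sR
      if (candF >= best[i + 1L]) { best[i + 1L] <- candF; from[i] <- i - w; kind[i] <- "+" }
      if (candR > best[i + 1L]) { best[i + 1L] <- candR; from[i] <- i - w; kind[i] <- "-" }
    }
  }
  hits <- emptyHits
  i <- m
  while (i >= 1L) {
    if (kind[i] != "bg") {
      pos <- seg[(i - w + 1L):i]
      lo <- if (kind[i] == "+") sum(loF[cbind(pos, seq_len(w))])
            else sum(loR[cbind(pos, seq_len(w))])
      hits <- rbind(data.frame(start = a + i - w - 1L, strand = kind[i],
                               logOdds = lo / log(2)), hits)
    }
    i <- from[i]
  }
  hits
}

#' Score an ortholog panel against one PWM
#'
#' Applies \code{\link{crmScore}} to every (region, species) sequence of a
#' panel and assembles the region x species \linkS4class{ScoreMatrix}.
#' Regions absent from a species are recorded as missing (\code{NA}), never
#' as 0.
#'
#' @param panel named list: species -> \code{DNAStringSet} (or character
#'   vector) whose names are region identifiers.
#' @param pwm a \linkS4class{PWMatrix}.
#' @param expectedGap,background passed to \code{\link{crmScore}}.
#' @return a \linkS4class{ScoreMatrix}.
#' @export
scoreOrthologs <- function(panel, pwm, expectedGap = 35, background = NULL) {
  stopifnot(is.list(panel), length(panel) > 0,
            !is.null(names(panel)), all(nzchar(names(panel))))
  seqs <- lapply(panel, function(s) {
    v <- as.character(s)
    if (is.null(names(v)) && !is.null(names(s))) names(v) <- names(s)
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop("every sequence needs a region identifier")
    v
  })
  for (sp in names(seqs))
    if (anyDuplicated(names(seqs[[sp]])))
      stop("duplicate region id in species '", sp, "': ",
           names(seqs[[sp]])[duplicated(names(seqs[[sp]]))][1])
  regionsAll <- unique(unlist(lapply(seqs, names), use.names = FALSE))
  m <- matrix(NA_real_, nrow = length(regionsAll), ncol = length(seqs),
              dimnames = list(regionsAll, names(seqs)))
  for (sp in names(seqs)) {
    v <- seqs[[sp]]
    for (r in names(v))
      m[r, sp] <- clusterScore(crmScore(v[[r]], pwm,
                                        expectedGap = expectedGap,
                                        background = background,
                                        region = r, species = sp))
  }
  new("ScoreMatrix", values = m)
}

#' Read per-species FASTA files into an ortholog panel
#'
#' Record ids of the form \code{region|species} are trimmed to the region
#' part; otherwise the full id is the region identifier.
#'
#' @param files named character vector: species label -> FASTA path.
#' @return named list species -> \code{DNAStringSet}, ready for
#'   \code{\link{scoreOrthologs}}.
#' @export
readFastaPanel <- function(files) {
  stopifnot(!is.null(names(files)), all(nzchar(names(files))))
  out <- lapply(files, function(f) {
    s <- Biostrings::readDNAStringSet(f)
    names(s) <- sub("\\|.*$", "", sub("\\s.*$", "", names(s)))
    s
  })
  names(out) <- names(files)
  out
}

#' Write an ortholog panel as per-species FASTA files
#'
#' @param panel named list species -> \code{DNAStringSet}.
#' @param dir output directory (created if needed); one
#'   \code{<species>.fa} per species, record ids \code{region|species}.
#' @return character vector of written paths, invisibly.
#' @export
writeFastaPanel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sp in names(panel)) {
    s <- Biostrings::DNAStringSet(as.character(panel[[sp]]))
    names(s) <- paste0(names(panel[[sp]]), "|", sp)
    p <- file.path(dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(s, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read/write a region x species score (trait) table
#'
#' TSV with header \code{region<TAB>species...}; \code{NA} marks missing
#' orthologs.
#'
#' @param file path.
#' @return \code{readScoreMatrix}: a \linkS4class{ScoreMatrix}.
#' @export
readScoreMatrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "region")
    stop("malformed trait table (expected first column 'region'): ", file)
  if (anyDuplicated(df$region))
    stop("duplicate region id at line ",
         which(duplicated(df$region))[1] + 1L, " of ", file)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))) &
                 !is.na(df[, -1, drop = FALSE]), arr.ind = TRUE)
    stop("non-numeric trait value at line ",
         if (length(bad)) bad[1, 1] + 1L else "?", " of ", file)
  }
  rownames(m) <- df$region
  new("ScoreMatrix", values = m)
}

#' @rdname readScoreMatrix
#' @param x a \linkS4class{ScoreMatrix} (or bare matrix with dimnames).
#' @export
writeScoreMatrix <- function(x, file) {
  v <- if (is(x, "ScoreMatrix")) scoreValues(x) else x
  df <- data.frame(region = rownames(v), v, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
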