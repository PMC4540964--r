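#' Hypergeometric upper-tail overlap test
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(population \code{N},
#' successes \code{K}, sample \code{n}), computed in log space so that
#' overlaps far in the tail (p below 1e-300) remain finite. \code{k = 0}
#' gives p = 1 (the whole support).
#'
#' @param N population size (e.g. all regulatory regions in the universe).
#' @param K successes in the population (regions predicted divergent for a
#'   PWM/model/direction).
#' @param n sample size (experimentally divergent regions).
#' @param k observed successes in the sample (the overlap).
#' @return the upper-tail p-value in (0, 1].
#' @examples
#' hypergeomTest(136353, 12928, 42, 24)  # ~1.74e-14
#' @export
hypergeomTest <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("N, K, n, k must be integers")
  if (k < 0 || k > min(n, K) || K > N || n > N)
    stop("bounds violated: need 0 <= k <= min(n, K) <= N and n <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

.newEnrichmentRow <- function(pwm, model, direction, N, n, K, k, p) {
  data.frame(pwm = pwm, model = model, direction = direction,
             N = N, n = n, K = K, k = k, p = p)
}

#' Overlap test between two region sets
#'
#' Single hypergeometric test with sample \code{a}, population successes
#' \code{b}, overlap \code{|a \eqn{\cap} b|}, in a universe of \code{N}
#' regions.
#'
#' @param setA,setB character vectors of region identifiers (within the
#'   universe).
#' @param N universe size (>= the size of the union).
#' @param labels optional length-2 labels carried into the output row.
#' @return one-row data.frame with N, n, K, k and p.
#' @examples
#' overlapTest(paste0("r", 1:42), paste0("r", 30:60), N = 500)
#' @export
overlapTest <- function(setA, setB, N, labels = c("setA", "setB")) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setA) > N || length(setB) > N)
    stop("sets larger than the universe")
  k <- length(intersect(setA, setB))
  p <- hypergeomTest(N, length(setB), length(setA), k)
  .newEnrichmentRow(labels[2], labels[1], "overlap", N,
                    length(setA), length(setB), k, p)
}

#' Divergent-motif discovery by hypergeometric enrichment
#'
#' Compares an input set of experimentally divergent regions (from
#' cross-species ChIP-Seq, STARR-Seq or FAIRE-Seq) against every set of
#' predicted divergent regions in a divergence-call table, one test per
#' (PWM, model, direction) with at least one predicted region. P-values are
#' Bonferroni-corrected over all performed tests and results ranked by
#' adjusted then raw p. Direction matching is deliberately not enforced: a
#' gain input may legitimately enrich for losses in the out-group lineage.
#'
#' @param inputRegions character vector of region ids (must lie within the
#'   universe).
#' @param calls divergence-call table (\code{\link{divergenceTable}} /
#'   \code{\link{readDivergenceDb}} output): columns pwm, region, model,
#'   direction, divergent.
#' @param universe character vector of all region ids in the population, or
#'   a single integer N (then membership of the input cannot be checked).
#' @return data.frame of ranked enrichment rows: pwm, model, direction,
#'   N, n, K, k, p, p_adj, rank.
#' @export
discoverMotifs <- function(inputRegions, calls, universe) {
  inputRegions <- unique(as.character(inputRegions))
  if (!length(inputRegions)) stop("empty input region set")
  if (is.character(universe)) {
    universe <- unique(universe)
    N <- length(universe)
    outside <- setdiff(inputRegions, universe)
    if (length(outside))
      stop("input region(s) outside the universe: ",
           paste(utils::head(outside, 5), collapse = ", "),
           if (length(outside) > 5) " ...")
  } else {
    N <- as.integer(universe)
    if (is.na(N) || N < length(inputRegions))
      stop("universe must be an id vector or an integer >= |input|")
  }
  div <- calls[calls$divergent, , drop = FALSE]
  groups <- unique(div[, c("pwm", "model", "direction")])
  if (!nrow(groups)) stop("no predicted divergent sets in the call table")
  n <- length(inputRegions)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    ids <- unique(div$region[div$pwm == g$pwm & div$model == g$model &
                             div$direction == g$direction])
    k <- length(intersect(inputRegions, ids))
    .newEnrichmentRow(g$pwm, g$model, g$direction, N, n, length(ids), k,
                      hypergeomTest(N, length(ids), n, k))
  })
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_adj <- pmin(1, res$p * m)
  res <- res[order(res$p_adj, res$p), , drop = FALSE]
  ## competition ranking: sets with identical overlap statistics (e.g. a
  ## clade model and its sub-clade model capturing the same regions) share
  ## the top rank
  res$rank <- rank(res$p, ties.method = "min")
  rownames(res) <- NULL
  res
}

#' Named presets for defining experimentally divergent input sets
#'
#' Helpers implementing the conventional cutoffs for upstream data: ChIP
#' fold-change > 2 between lineages, and STARR-Seq activity with p <= 0.001
#' and >= 3-fold enrichment. Both take a data.frame and return the region
#' ids passing the preset.
#'
#' @param df data.frame with a \code{region} column plus, for
#'   \code{chipFoldPreset}, \code{foldChange}; for \code{starrPreset},
#'   \code{p} and \code{fold}.
#' @param foldCut,pCut preset thresholds (defaults 2; and 0.001 with 3).
#' @return character vector of region ids.
#' @export
chipFoldPreset <- function(df, foldCut = 2) {
  stopifnot(all(c("region", "foldChange") %in% names(df)))
  unique(df$region[df$foldChange > foldCut])
}

#' @rdname chipFoldPreset
#' @export
starrPreset <- function(df, pCut = 0.001, foldCut = 3) {
  stopifnot(all(c("region", "p", "fold") %in% names(df)))
  unique(df$region[df$p <= pCut & df$fold >= foldCut])
}

#' Read a region set from BED or one-id-per-line text
#'
#' BED rows (>= 3 tab-separated columns) become \code{chrom:start-end} ids
#' unless a 4th name column is present; plain files are read as one id per
#' line.
#'
#' @param file path.
#' @return character vector of region ids.
#' @export
readRegionSet <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t")
  if (all(lengths(parts) >= 3) &&
      !anyNA(suppressWarnings(as.integer(vapply(parts, `[`, "", 2))))) {
    vapply(parts, function(p)
      if (length(p) >= 4 && nzchar(p[4])) p[4]
      else paste0(p[1], ":", p[2], "-", p[3]), character(1))
  } else trimws(lines)
}
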