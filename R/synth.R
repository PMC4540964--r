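## Synthetic data: every stage of the pipeline is testable without
## downloads. Trait datasets exercise the evolutionary models directly;
## sequence panels exercise scoring + fitting end to end. Sequence evolution
## along the tree is deliberately NOT modelled: species backgrounds are
## independent i.i.d. draws with motif sites planted per scenario — a
## non-phylogenetic sequence null that is sufficient to exercise the scorer
## and the OU machinery (see the vignette for what this does and does not
## show about real data).

#' Simulate a trait dataset with ground-truth labels
#'
#' Each region's trait is simulated independently under the given painting
#' and parameters via \code{\link{simulateTrait}}; the truth label of every
#' region is the generating model. Pure function of (parameters, seed).
#'
#' @param tree a validated \code{phylo}.
#' @param painting the generating \linkS4class{RegimePainting}.
#' @param params simulation parameters, see \code{\link{simulateTrait}}.
#' @param nRegions number of regions (>= 1).
#' @param seed integer seed.
#' @param prefix region id prefix.
#' @return list with \code{traits} (a \linkS4class{ScoreMatrix}) and
#'   \code{truth} (data.frame region, model).
#' @export
genTraitDataset <- function(tree, painting, params, nRegions, seed,
                            prefix = "region") {
  stopifnot(nRegions >= 1)
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(nRegions))
  m <- t(vapply(ids, function(i)
    simulateTrait(tree, painting, params, seed = NULL),
    numeric(length(tree$tip.label))))
  rownames(m) <- ids
  list(traits = new("ScoreMatrix", values = m),
       truth = data.frame(region = ids, model = painting@model))
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T")

.randomSeq <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

## Plant `sites` (character vector) into `seq` at clustered positions inside
## a window of `windowLen` bp; returns the modified sequence. Non-overlapping
## placement by spacing the sites evenly with jitter.
.plantSites <- function(seq, sites, windowLen) {
  n <- nchar(seq)
  w <- nchar(sites[1])
  need <- length(sites) * w
  windowLen <- min(max(windowLen, need), n)
  if (need > n) stop("impossible packing: sites exceed the region length")
  winStart <- sample.int(n - windowLen + 1L, 1L)
  slack <- windowLen - need
  gaps <- if (length(sites) > 0) {
    cuts <- sort(sample.int(slack + 1L, length(sites), replace = TRUE) - 1L)
    diff(c(0L, cuts))
  } else integer(0)
  pos <- winStart
  out <- strsplit(seq, "")[[1]]
  for (i in seq_along(sites)) {
    pos <- pos + gaps[i]
    out[pos:(pos + w - 1L)] <- strsplit(sites[i], "")[[1]]
    pos <- pos + w
  }
  paste(out, collapse = "")
}

#' Generate an ortholog sequence panel with planted or deleted clusters
#'
#' Background sequence is drawn i.i.d. from the stated composition,
#' independently per species. \code{"gain"} regions receive \code{nSites}
#' PWM-sampled sites at clustered positions only in the clade species;
#' \code{"loss"} regions receive sites in every species except the clade;
#' \code{"conserved"} regions receive sites everywhere or nowhere (50/50).
#' Sites are clustered within a window of 3x the scorer's expected gap to
#' guarantee single-cluster structure.
#'
#' @param tree a validated \code{phylo} (tips = species).
#' @param pwm the \linkS4class{PWMatrix} whose sites are planted.
#' @param scenario list: \code{cladeTips} (character), \code{direction}
#'   ("gain", "loss" or "conserved"), \code{nSites} (default 3),
#'   \code{regionLength} (default 600), \code{nRegions} (default 10),
#'   \code{composition} (A,C,G,T probabilities; default uniform; pass
#'   \code{c(.3,.2,.2,.3)} for an AT-rich background), \code{expectedGap}
#'   (default 35), \code{dropout} (per-cell missing-ortholog rate, default
#'   0).
#' @param seed integer seed.
#' @param prefix region id prefix.
#' @return a \linkS4class{SyntheticPanel}.
#' @export
genSequencePanel <- function(tree, pwm, scenario, seed, prefix = "region") {
  validatePhylo(tree)
  sc <- utils::modifyList(
    list(cladeTips = character(0), direction = "gain", nSites = 3L,
         regionLength = 600L, nRegions = 10L,
         composition = c(A = .25, C = .25, G = .25, T = .25),
         expectedGap = 35, dropout = 0), scenario)
  stopifnot(sc$direction %in% c("gain", "loss", "conserved"))
  if (sc$direction != "conserved" && !length(sc$cladeTips))
    stop("gain/loss scenarios need cladeTips")
  if (!all(sc$cladeTips %in% tree$tip.label))
    stop("unknown clade tip(s)")
  w <- ncol(motifProfile(pwm))
  if (sc$regionLength < sc$nSites * w)
    stop("impossible packing: regionLength < nSites * motif length")
  comp <- stats::setNames(sc$composition / sum(sc$composition),
                          c("A", "C", "G", "T"))
  set.seed(seed)
  species <- tree$tip.label
  ids <- sprintf("%s%04d", prefix, seq_len(sc$nRegions))
  windowLen <- ceiling(3 * sc$expectedGap) + sc$nSites * w
  seqs <- lapply(species, function(s) character(sc$nRegions))
  names(seqs) <- species
  truthLab <- character(sc$nRegions)
  for (i in seq_len(sc$nRegions)) {
    planted <- switch(sc$direction,
      gain = sc$cladeTips,
      loss = setdiff(species, sc$cladeTips),
      conserved = if (stats::runif(1) < 0.5) species else character(0))
    truthLab[i] <- sc$direction
    for (s in species) {
      bg <- .randomSeq(sc$regionLength, comp)
      if (s %in% planted && sc$nSites > 0)
        bg <- .plantSites(bg, samplePwmSite(pwm, sc$nSites), windowLen)
      seqs[[s]][i] <- bg
    }
  }
  for (s in species) {
    keep <- stats::runif(sc$nRegions) >= sc$dropout
    ss <- Biostrings::DNAStringSet(seqs[[s]][keep])
    names(ss) <- ids[keep]
    seqs[[s]] <- ss
  }
  new("SyntheticPanel", tree = tree, pwm = pwm, sequences = seqs,
      truth = data.frame(region = ids, label = truthLab,
                         clade = paste(sc$cladeTips, collapse = ",")),
      params = c(sc, list(seed = seed)))
}

#' Assemble a divergent-motif discovery benchmark
#'
#' Combines the regions of one or more synthetic panels with background
#' region identifiers into a universe, and builds the experimental input
#' set from the true gain/loss regions plus configurable label noise
#' (\code{noise} = fraction of the input drawn uniformly from the universe
#' instead of from the truth).
#'
#' @param panels list of \linkS4class{SyntheticPanel} objects.
#' @param nBackground number of additional background-only region ids.
#' @param noise label-noise fraction in [0, 1].
#' @param seed integer seed.
#' @return list with \code{universe} (ids), \code{input} (ids) and
#'   \code{truth} (data.frame pwm, model tips, direction per panel).
#' @export
genEnrichmentBenchmark <- function(panels, nBackground, noise = 0, seed) {
  stopifnot(length(panels) >= 1, noise >= 0, noise <= 1)
  set.seed(seed)
  panelRegions <- unlist(lapply(panels, function(p) panelTruth(p)$region))
  if (anyDuplicated(panelRegions))
    stop("panels must use distinct region id prefixes")
  bg <- if (nBackground > 0) sprintf("bg%05d", seq_len(nBackground))
        else character(0)
  universe <- c(panelRegions, bg)
  trueDiv <- unlist(lapply(panels, function(p) {
    t <- panelTruth(p)
    t$region[t$label %in% c("gain", "loss")]
  }))
  nIn <- length(trueDiv)
  nNoise <- round(noise * nIn)
  input <- c(sample(trueDiv, nIn - nNoise),
             sample(universe, nNoise))
  input <- unique(input)
  truth <- do.call(rbind, lapply(panels, function(p) {
    t <- panelTruth(p)
    lab <- setdiff(unique(t$label), "conserved")
    if (!length(lab)) return(NULL)
    data.frame(pwm = p@pwm@id, clade = t$clade[1], direction = lab)
  }))
  list(universe = universe, input = input, truth = truth)
}
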