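#' Parse a newick string into a rooted phylogeny
#'
#' Thin validating wrapper around \code{ape::read.tree}: the returned tree is
#' guaranteed rooted, with strictly positive branch lengths on every non-root
#' branch and unique tip labels. These are the invariants every downstream
#' model fit relies on, so violations are errors here, not later surprises.
#'
#' @param text a newick string (branch lengths mandatory).
#' @return an \code{ape} \code{phylo} object.
#' @examples
#' tr <- parseNewick("(A:1,(B:0.5,C:0.5):0.5);")
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr))
    stop("malformed newick string (unbalanced parentheses or truncated): ",
         substr(text, 1, 60))
  validatePhylo(tr)
  tr
}

#' Read a rooted phylogeny from a newick file
#'
#' @param file path to a newick file.
#' @return an \code{ape} \code{phylo} object (validated).
#' @export
readNewick <- function(file) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "")
  parseNewick(txt)
}

#' Write a phylogeny to a newick file
#'
#' @param tree a \code{phylo} object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeNewick <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Validate the tree invariants assumed by the evolutionary models
#'
#' Checks: exactly one root, branch lengths present and strictly positive,
#' unique tip labels, every non-root node reachable from the root.
#'
#' @param tree a \code{phylo} object.
#' @return \code{tree}, invisibly; errors describe the offending element.
#' @export
validatePhylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("branch lengths are missing; the models need a time axis")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length at edge ",
         which(!is.finite(tree$edge.length))[1])
  if (any(tree$edge.length <= 0)) {
    bad <- which(tree$edge.length <= 0)[1]
    child <- tree$edge[bad, 2]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child]
           else paste0("node", child)
    stop("non-positive branch length on the branch to '", lab, "'")
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  n <- length(tree$tip.label)
  root <- n + 1L
  nNode <- n + tree$Nnode
  parents <- unique(tree$edge[, 1])
  children <- tree$edge[, 2]
  if (length(setdiff(seq_len(nNode)[-root], children)))
    stop("node(s) unreachable from the root")
  if (anyDuplicated(children))
    stop("a node has more than one parent; not a rooted tree")
  invisible(tree)
}

## Per-edge stable identifiers: tip label for terminal branches, "node<k>"
## for internal ones (the child node of the edge).
paintingBranchIds <- function(painting) {
  branchIds(painting@tree)
}

branchIds <- function(tree) {
  child <- tree$edge[, 2]
  n <- length(tree$tip.label)
  ifelse(child <= n, tree$tip.label[child], paste0("node", child))
}

## Node set of the clade rooted at `node` (including `node` itself).
.descendantNodes <- function(tree, node) {
  out <- node
  stack <- node
  edge <- tree$edge
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- edge[edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}

#' Paint a branch-shift selective regime onto a tree
#'
#' Labels the branches inside the clade spanned by \code{shiftTips}, plus the
#' clade's stem branch, as \code{"shift"}; all remaining branches are
#' \code{"base"}. The stem is included because the optimum changes on the
#' lineage leading to the clade. \code{shiftTips} must be monophyletic; with
#' \code{allowComplement = TRUE}, a tip set whose \emph{complement} is a clade
#' is painted by exclusion (everything outside the complement clade shifts,
#' and the root then lies in the shift regime).
#'
#' @param tree a validated \code{phylo} object.
#' @param shiftTips non-empty character vector of tip labels.
#' @param model model identifier stored in the painting (e.g. "M10").
#' @param allowComplement allow a root-spanning painting when the complement
#'   of \code{shiftTips} is monophyletic (default FALSE: error instead).
#' @return a \linkS4class{RegimePainting}.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' paintClade(tr, c("A", "B"), "Mab")
#' @export
paintClade <- function(tree, shiftTips, model = "shift",
                       allowComplement = FALSE) {
  validatePhylo(tree)
  shiftTips <- unique(as.character(shiftTips))
  if (length(shiftTips) == 0L) stop("shiftTips must be non-empty")
  unknown <- setdiff(shiftTips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  root <- n + 1L

  cladeNodes <- function(tips) {
    idx <- match(tips, tree$tip.label)
    if (length(idx) == 1L) return(list(mrca = idx, nodes = idx, tips = tips))
    mrca <- ape::getMRCA(tree, tips)
    nodes <- .descendantNodes(tree, mrca)
    list(mrca = mrca, nodes = nodes,
         tips = tree$tip.label[nodes[nodes <= n]])
  }

  cl <- cladeNodes(shiftTips)
  reg <- rep("base", nrow(tree$edge))
  if (setequal(cl$tips, shiftTips)) {
    inClade <- tree$edge[, 2] %in% cl$nodes  # includes the stem (child==mrca)
    reg[inClade] <- "shift"
    rootReg <- if (cl$mrca == root) "shift" else "base"
    spans <- cl$mrca == root
  } else if (allowComplement &&
             length(setdiff(tree$tip.label, shiftTips)) > 0L) {
    comp <- setdiff(tree$tip.label, shiftTips)
    ccl <- cladeNodes(comp)
    if (!setequal(ccl$tips, comp) || ccl$mrca == root)
      stop("tips {", paste(shiftTips, collapse = ", "),
           "} are not monophyletic (nor is their complement)")
    inComp <- tree$edge[, 2] %in% ccl$nodes
    reg[!inComp] <- "shift"
    rootReg <- "shift"
    spans <- TRUE
  } else {
    stop("tips {", paste(shiftTips, collapse = ", "),
         "} are not monophyletic in the tree")
  }
  new("RegimePainting", model = model, tree = tree, regimes = reg,
      rootRegime = rootReg, shiftTips = shiftTips, spansRoot = spans)
}

#' Single-regime paintings (BM and M0)
#'
#' Every branch is \code{"base"}: BM (neutral drift) and M0 (one global
#' optimum) differ in the fitted process, not the painting.
#'
#' @param tree a validated \code{phylo} object.
#' @param model "BM" or "M0".
#' @return a \linkS4class{RegimePainting}.
#' @export
paintUniform <- function(tree, model = c("M0", "BM")) {
  model <- match.arg(model)
  validatePhylo(tree)
  new("RegimePainting", model = model, tree = tree,
      regimes = rep("base", nrow(tree$edge)), rootRegime = "base",
      shiftTips = character(0), spansRoot = FALSE)
}

#' Canonical 12-species Drosophila tip names and aliases
#'
#' Maps common spellings (full binomials, UCSC-style abbreviations) to the
#' canonical short labels used by \code{\link{builtinRegimes}}.
#'
#' @return named character vector: alias -> canonical label.
#' @export
drosophilaAliases <- function() {
  canon <- c(Dmel = "melanogaster", Dsim = "simulans", Dsec = "sechellia",
             Dyak = "yakuba", Dere = "erecta", Dana = "ananassae",
             Dpse = "pseudoobscura", Dper = "persimilis", Dwil = "willistoni",
             Dmoj = "mojavensis", Dvir = "virilis", Dgri = "grimshawi")
  out <- character(0)
  for (i in seq_along(canon)) {
    short <- names(canon)[i]; sp <- canon[[i]]
    ali <- c(short, tolower(short),
             paste0("D. ", sp), paste0("Drosophila ", sp), sp,
             paste0("d", sp),
             paste0("dro", toupper(substr(sp, 1, 1)), substr(sp, 2, 3)))
    out[ali] <- short
  }
  out
}

#' Reference 12-species Drosophila phylogeny
#'
#' Ultrametric topology of the 12 sequenced Drosophila genomes with branch
#' lengths in relative time units (tree height 1, roughly 60 My). The
#' literature source of this framework never fixes a chronogram, so these
#' lengths are a documented convention: replace them with any user tree via
#' \code{\link{readNewick}} for real analyses.
#'
#' @return a \code{phylo} object with tips Dmel, Dsim, Dsec, Dyak, Dere,
#'   Dana, Dpse, Dper, Dwil, Dmoj, Dvir, Dgri.
#' @export
drosophilaTree <- function() {
  txt <- paste0(
    "((((((Dmel:0.0833,(Dsim:0.0333,Dsec:0.0333):0.05):0.1334,",
    "(Dyak:0.1667,Dere:0.1667):0.05):0.2,Dana:0.4167):0.1666,",
    "(Dpse:0.0333,Dper:0.0333):0.55):0.0834,Dwil:0.6667):0.3333,",
    "((Dmoj:0.5,Dvir:0.5):0.1667,Dgri:0.6667):0.3333);")
  parseNewick(txt)
}

## Resolve the 12 canonical Drosophila labels among a tree's tips (through
## the alias table); errors list absentees.
.resolveDrosTips <- function(tree, aliases = drosophilaAliases()) {
  canon <- unique(aliases)
  hit <- aliases[match(tree$tip.label, names(aliases))]
  found <- stats::setNames(tree$tip.label, hit)[!is.na(hit)]
  missing <- setdiff(canon, names(found))
  if (length(missing))
    stop("tree is missing required species: ",
         paste(missing, collapse = ", "))
  found  # canonical -> actual tip label
}

#' The built-in evolutionary scenarios for the 12 Drosophila species
#'
#' Returns the twelve paintings used throughout: BM (drift), M0 (one global
#' optimum) and the ten branch-shift scenarios M1-M10 — M1 melanogaster
#' subgroup; M2 melanogaster group; M3 D.moj+D.vir+D.gri; M4 D.moj+D.vir;
#' M5 obscura group; M6 D.wil+D.moj+D.vir+D.gri; M7 D.sec; M8 D.mel;
#' M9 D.pse; M10 D.vir. Tip names are matched through an alias table, so
#' full binomials or UCSC abbreviations work unchanged. M6's tip set is not
#' a clade on this topology (D. willistoni is Sophophora); it is painted by
#' complement, so its shift regime spans the root.
#'
#' @param tree a tree containing the 12 species (default the packaged
#'   reference topology).
#' @param aliases alias table, see \code{\link{drosophilaAliases}}.
#' @return named list of 12 \linkS4class{RegimePainting} objects.
#' @export
builtinRegimes <- function(tree = drosophilaTree(),
                           aliases = drosophilaAliases()) {
  tip <- .resolveDrosTips(tree, aliases)
  clades <- list(
    M1 = c("Dmel", "Dsim", "Dsec", "Dyak", "Dere"),
    M2 = c("Dmel", "Dsim", "Dsec", "Dyak", "Dere", "Dana"),
    M3 = c("Dmoj", "Dvir", "Dgri"),
    M4 = c("Dmoj", "Dvir"),
    M5 = c("Dpse", "Dper"),
    M6 = c("Dwil", "Dmoj", "Dvir", "Dgri"),
    M7 = "Dsec",
    M8 = "Dmel",
    M9 = "Dpse",
    M10 = "Dvir")
  out <- list(BM = paintUniform(tree, "BM"), M0 = paintUniform(tree, "M0"))
  for (m in names(clades))
    out[[m]] <- paintClade(tree, unname(tip[clades[[m]]]), model = m,
                           allowComplement = m == "M6")
  out
}

#' Serialize a regime painting as a two-column TSV
#'
#' Columns \code{branch_id} (tip label, or \code{node<k>} for internal
#' branches) and \code{regime}.
#'
#' @param painting a \linkS4class{RegimePainting}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeRegimeTable <- function(painting, file) {
  df <- data.frame(branch_id = paintingBranchIds(painting),
                   regime = painting@regimes)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a regime painting from a two-column TSV
#'
#' @param file TSV written by \code{\link{writeRegimeTable}} (or compatible).
#' @param tree the tree the painting refers to.
#' @param model model identifier to store.
#' @return a \linkS4class{RegimePainting}.
#' @export
readRegimeTable <- function(file, tree, model = "custom") {
  validatePhylo(tree)
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("branch_id", "regime") %in% names(df)))
    stop("expected columns branch_id and regime")
  ids <- branchIds(tree)
  m <- match(ids, df$branch_id)
  if (anyNA(m))
    stop("painting is missing branch(es): ",
         paste(ids[is.na(m)], collapse = ", "))
  reg <- df$regime[m]
  if (!all(reg %in% c("base", "shift")))
    stop("regimes must be 'base' or 'shift'")
  n <- length(tree$tip.label)
  stips <- tree$tip.label[tree$edge[reg == "shift", 2][
    tree$edge[reg == "shift", 2] <= n]]
  ## root regime: regime of the branches incident to the root if they agree
  ## and shift, else base; a painting whose shift set touches the root on
  ## both sides spans it.
  rootKids <- tree$edge[, 1] == (n + 1L)
  rootReg <- if (all(reg[rootKids] == "shift")) "shift" else "base"
  new("RegimePainting", model = model, tree = tree, regimes = reg,
      rootRegime = rootReg, shiftTips = stips,
      spansRoot = rootReg == "shift")
}

#' Re-derive a painting on a (possibly pruned) tree
#'
#' Used when tips are dropped for missing trait data: the painting is rebuilt
#' from its stored shifted tip set on the new tree. Returns NULL when no
#' shifted tip survives (the model is untestable on the pruned data).
#'
#' @param painting a \linkS4class{RegimePainting}.
#' @param tree the new tree (tips a subset of the painting's tree).
#' @return a \linkS4class{RegimePainting} on \code{tree}, or NULL.
#' @export
repaint <- function(painting, tree) {
  if (length(painting@shiftTips) == 0L)
    return(paintUniform(tree, if (painting@model %in% c("BM", "M0"))
                               painting@model else "M0"))
  keep <- intersect(painting@shiftTips, tree$tip.label)
  if (length(keep) == 0L) return(NULL)
  if (length(keep) == length(tree$tip.label)) return(NULL)
  paintClade(tree, keep, model = painting@model,
             allowComplement = painting@spansRoot)
}
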