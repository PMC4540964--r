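#' Build a position weight matrix from counts
#'
#' Adds \code{pseudocount} to every cell of a 4 x L count matrix (rows
#' A,C,G,T) and normalises each column to probabilities. Information content
#' is \eqn{\sum_j (2 + \sum_b p_{bj} \log_2 p_{bj})} bits. The default
#' pseudocount of 0.375 per cell follows the Cluster-Buster convention.
#'
#' @param counts numeric 4 x L matrix (or L x 4, auto-transposed) of base
#'   counts; probabilities are accepted and treated as counts.
#' @param id motif identifier.
#' @param name optional human-readable name.
#' @param pseudocount weight added to every cell before normalisation.
#' @return a \linkS4class{PWMatrix}.
#' @examples
#' pwMatrix(matrix(c(8, 2, 0, 0), 4, 3), id = "toy")
#' @export
pwMatrix <- function(counts, id = "pwm", name = "", pseudocount = 0.375) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L && ncol(counts) == 4L) counts <- t(counts)
  if (nrow(counts) != 4L)
    stop("a PWM needs 4 base rows (A,C,G,T); got ", nrow(counts))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("non-numeric cell in PWM '", id, "'")
  if (any(counts < 0))
    stop("negative count in PWM '", id, "'")
  if (any(colSums(counts) == 0) && pseudocount <= 0)
    stop("position with all-zero counts in PWM '", id,
         "' and no pseudocount to rescue it")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  p <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  if (any(p <= 0))
    stop("zero probability after pseudocounting in PWM '", id,
         "'; increase the pseudocount")
  rownames(p) <- c("A", "C", "G", "T")
  ic <- sum(2 + colSums(p * log2(p)))
  new("PWMatrix", id = as.character(id), name = as.character(name),
      profile = p, ic = ic, pseudocount = pseudocount)
}

#' Read a JASPAR-style PWM file
#'
#' Parses plain-text motif collections in the common JASPAR layouts: a
#' \code{>ID name} header followed by four base rows, either annotated
#' (\code{A [ 1 2 3 ]}) or bare whitespace-separated numbers. Orientation
#' (4 rows of length L vs L rows of 4 columns) is autodetected for bare
#' blocks. Counts are pseudocounted and normalised by \code{\link{pwMatrix}};
#' probability matrices (columns summing to 1) are first rescaled to counts
#' from 100 observations so the pseudocount acts on a comparable scale.
#'
#' @param file path to the matrix file.
#' @param pseudocount per-cell pseudocount, see \code{\link{pwMatrix}}.
#' @return a named list of \linkS4class{PWMatrix} objects.
#' @export
readJaspar <- function(file, pseudocount = 0.375) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PWM file: ", file)
  hdr <- grep("^>", lines)
  if (!length(hdr)) { hdr <- 0L; lines <- c(">pwm1", lines); hdr <- 1L }
  starts <- grep("^>", lines)
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i] + 1L
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    if (to < from) stop("PWM block without rows at line ", starts[i])
    head <- strsplit(trimws(sub("^>", "", lines[starts[i]])), "\\s+")[[1]]
    id <- head[1]
    nm <- if (length(head) > 1) paste(head[-1], collapse = " ") else ""
    block <- lines[from:to]
    mat <- .parsePwmBlock(block, id)
    ## probability matrices (columns summing to 1) are rescaled to counts
    ## from 100 observations so the pseudocount acts on a sensible scale
    if (all(abs(colSums(mat) - 1) < 1e-3)) mat <- mat * 100
    out[[id]] <- pwMatrix(mat, id = id, name = nm,
                          pseudocount = pseudocount)
  }
  out
}

.parsePwmBlock <- function(block, id) {
  annotated <- grepl("^[ACGTacgt]\\s*[\\[|]?", block) &
               grepl("[0-9]", block) & grepl("^[ACGTacgt][^0-9]", block)
  rows <- lapply(block, function(ln) {
    base <- NA_character_
    if (grepl("^\\s*[ACGTacgt][^0-9.]", ln)) {
      base <- toupper(substr(trimws(ln), 1, 1))
      ln <- sub("^\\s*[ACGTacgt]", "", ln)
    }
    ln <- gsub("[\\[\\]|]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(vals))
      stop("non-numeric cell in PWM '", id, "': ", trimws(ln))
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, function(r) r$base, character(1))
  vals <- lapply(rows, function(r) r$vals)
  if (!anyNA(bases) && setequal(bases, c("A", "C", "G", "T"))) {
    L <- unique(lengths(vals))
    if (length(L) != 1L)
      stop("ragged rows in PWM '", id, "'")
    m <- do.call(rbind, vals[match(c("A", "C", "G", "T"), bases)])
  } else {
    L <- unique(lengths(vals))
    if (length(L) != 1L) stop("ragged rows in PWM '", id, "'")
    m <- do.call(rbind, vals)
    if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
    if (nrow(m) != 4L)
      stop("cannot orient PWM '", id, "': need 4 base rows or columns")
  }
  m
}

#' Write PWMs in JASPAR-style text
#'
#' @param pwms list of \linkS4class{PWMatrix} (probabilities are written).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeJaspar <- function(pwms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p@id, if (nzchar(p@name)) paste0(" ", p@name)), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ",
                        paste(format(p@profile[b, ], digits = 6),
                              collapse = " "), " ]"), con)
  }
  invisible(file)
}

#' Sample a site from a PWM
#'
#' Draws one sequence of the motif's length with per-position probabilities
#' given by the profile. Used by the synthetic-panel generator.
#'
#' @param pwm a \linkS4class{PWMatrix}.
#' @param n number of sites to draw.
#' @return character vector of \code{n} sites.
#' @export
samplePwmSite <- function(pwm, n = 1L) {
  p <- pwm@profile
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(ncol(p)), function(j)
      sample(rownames(p), 1L, prob = p[, j]), character(1)), collapse = "")
  }, character(1))
}
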