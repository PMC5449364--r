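#' Position weight matrix libraries
#'
#' A PWM library is a list of motifs, each a list with \code{id}, a 4 x width
#' probability \code{matrix} (rows A, C, G, T; every column sums to 1 after
#' pseudocount normalisation), a \code{background} composition and the
#' \code{pseudocount} used. Count matrices are accepted and normalised.
#'
#' @param motifs list of lists with \code{id} and \code{matrix} (counts or
#'   probabilities, rows A/C/G/T)
#' @param background base composition, defaults to uniform
#' @param pseudocount added to every cell before column normalisation
#' @return a \code{pwm_library} object
#' @export
pwm_library <- function(motifs, background = c(A = .25, C = .25, G = .25, T = .25),
                        pseudocount = 1e-3) {
  if (abs(sum(background) - 1) > 1e-9) stop_config("background must sum to 1")
  lib <- lapply(motifs, function(m) {
    mat <- as.matrix(m$matrix)
    if (ncol(mat) == 0) stop_config("zero-width PWM: ", m$id)
    if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(mat < 0)) stop_config("negative PWM entries: ", m$id)
    mat <- sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
    stopifnot(all(abs(colSums(mat) - 1) < 1e-9))
    list(id = m$id, matrix = mat, background = background,
         pseudocount = pseudocount)
  })
  names(lib) <- vapply(lib, `[[`, character(1), "id")
  if (anyDuplicated(names(lib))) stop_config("duplicate motif ids")
  structure(lib, class = "pwm_library")
}

#' @export
print.pwm_library <- function(x, ...) {
  cat("pwm_library:", length(x), "motif(s); widths",
      paste(vapply(x, function(m) ncol(m$matrix), integer(1)), collapse = ","), "\n")
  invisible(x)
}

#' Read a JASPAR-style PWM text file
#'
#' Parses the common 4-line JASPAR layout: a \code{>id} header followed by
#' rows \code{A [ ... ]} through \code{T [ ... ]} (brackets optional).
#'
#' @param path file to read
#' @inheritParams pwm_library
#' @return a \code{pwm_library}
#' @export
read_jaspar <- function(path, background = c(A = .25, C = .25, G = .25, T = .25),
                        pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_structural("no motif headers in ", path)
  motifs <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4) stop_structural("motif block must have 4 base rows")
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = parts[1], values = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop_structural("motif rows must be labelled A/C/G/T")
    mat <- do.call(rbind, lapply(rows, `[[`, "values"))
    rownames(mat) <- bases
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    list(id = id, matrix = mat[c("A", "C", "G", "T"), , drop = FALSE])
  })
  pwm_library(motifs, background = background, pseudocount = pseudocount)
}

#' Write a PWM library in JASPAR-style text
#' @param lib a \code{pwm_library}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_jaspar <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in lib) {
    writeLines(paste0(">", m$id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$matrix[b, ], digits = 6), collapse = " ")), con)
  }
  invisible(path)
}

#' Consensus sequence of a motif (highest-probability base per column)
#' @param motif one element of a \code{pwm_library}
#' @return character string
#' @export
pwm_consensus <- function(motif) {
  paste(rownames(motif$matrix)[apply(motif$matrix, 2, which.max)], collapse = "")
}
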