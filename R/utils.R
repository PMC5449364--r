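# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state afterwards
#'
#' All simulators route their randomness through this so that a fixed seed and
#' configuration yield byte-identical outputs without clobbering the caller's
#' RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round() in R is round-half-even; census percentages use the conventional
# round-half-up at one decimal (134/329 -> 40.7).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("lectinomics_config_error", "error")))
}

stop_structural <- function(...) {
  stop(errorCondition(paste0(...), class = c("lectinomics_structural_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement on plain character codes; N maps to N.
comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(comp_base[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
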