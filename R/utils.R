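# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded generators are reproducible without clobbering the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# C-locale stable ordering of peak/interval tables by (chrom, start, end).
order_genomic <- function(chrom, start, end = integer(length(start))) {
  order(chrom, start, end, method = "radix")
}

stop_line <- function(line, fmt, ...) {
  stop(sprintf("line %d: %s", line, sprintf(fmt, ...)), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# number of bins covering a chromosome
n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))
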