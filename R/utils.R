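# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not
#' disturb the caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
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
  code
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    stopf("counts must be a non-empty genes x libraries matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene rownames and library colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  invisible(counts)
}

# Overlap of gene intervals with event intervals on the same chromosome.
# `policy` is "any" (any positive overlap) or "within" (gene fully inside).
interval_overlaps <- function(gene_start, gene_end, ev_start, ev_end,
                              policy = c("any", "within")) {
  policy <- match.arg(policy)
  if (policy == "any") gene_start <= ev_end & gene_end >= ev_start
  else gene_start >= ev_start & gene_end <= ev_end
}
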