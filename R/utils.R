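#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a reproducible per-stage seed from one global seed. Offsets keep
# stages independent; modulus keeps the result a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, split = 211L, sva = 307L, de = 401L,
    cdc = 503L, dc = 601L, preservation = 701L, classify = 811L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# WGCNA-style module colour palette, assigned by descending module size.
module_palette <- function(n) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "black", "red",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue"
  )
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("module", seq_len(n - length(base)) + length(base)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("expression must be a numeric probe x sample matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stopf("duplicate probe ids in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stopf("duplicate sample ids in expression matrix")
  if (!all(is.finite(expr)))
    stopf("expression matrix contains non-finite values")
  invisible(expr)
}

# Spearman correlation of the columns of x (samples in rows).
spearman_cor <- function(x) {
  r <- apply(x, 2, rank)
  sds <- apply(r, 2, stats::sd)
  if (any(sds == 0)) {
    # constant columns have undefined rank correlation; define it as 0
    warning("constant gene(s): their correlations are set to 0")
    ok <- sds > 0
    out <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
    if (sum(ok) >= 2) out[ok, ok] <- stats::cor(r[, ok, drop = FALSE])
    diag(out) <- 1
    return(out)
  }
  stats::cor(r)
}
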