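#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft sd var rnorm runif quantile median predict qnorm qf
#'   pf prcomp rbinom coef optim
#' @importFrom utils head tail modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based derivation of child seeds from a master seed; keeps every
# derived seed inside the 32-bit signed-integer range R requires.
derive_seed <- function(master_seed, counter) {
  s <- (as.double(master_seed) * 48271 + as.double(counter) * 16807 + 12345)
  as.integer(s %% 2147483647)
}

# Row-wise softmax of a score matrix, numerically stabilised.
softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Least-squares solve of A %*% W = B via the normal equations with a small
# ridge jitter on the Gram matrix to survive rank deficiency.
pinv_solve <- function(A, B, jitter = 1e-8) {
  G <- crossprod(A)
  diag(G) <- diag(G) + jitter * mean(diag(G))
  solve(G, crossprod(A, B))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Full-precision numeric formatting so CSV round-trips are bit-identical.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
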