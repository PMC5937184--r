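# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic operations route
# their randomness through this so identical seeds give identical output
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single non-missing number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# Classed error constructor so callers can distinguish configuration errors,
# screening flags, etc. from generic failures.
ba_stop <- function(msg, class = "behavarch_error", call. = FALSE) {
  stop(structure(
    class = c(class, "behavarch_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    ba_stop(sprintf("`%s` must be a single probability in [0, 1]", name),
            class = "behavarch_config_error")
  }
}

# All permutations of seq_len(n) as an n! x n integer matrix (n <= 8).
all_permutations <- function(n) {
  if (n > 8L) ba_stop("refusing to enumerate permutations for n > 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Midrank-based Spearman correlation on pairwise-complete observations,
# computed as the Pearson correlation of midranks (so perfectly concordant
# or discordant vectors give exactly +/-1). Returns NA when fewer than 3
# complete pairs or a constant vector.
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  r <- stats::cor(rank(x), rank(y))
  # perfectly (anti)concordant ranks are exactly +/-1; undo sqrt round-off
  if (1 - abs(r) < 1e-12) r <- sign(r)
  r
}
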