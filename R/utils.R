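# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic, platform-independent derivation of a child seed from a
# parent seed and a stream of integer labels. All arithmetic stays below
# 2^53 so it is exact in doubles; the result lies in [1, 2^31 - 20].
derive_seed <- function(seed, ...) {
  labels <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (v in labels) {
    h <- (h * 69069 + abs(v) + 1) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

check_triple <- function(x, name) {
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3 || !is.numeric(x) || any(!is.finite(x)) || any(x < 1) ||
      any(x != floor(x))) {
    stopf("'%s' must be a positive integer triple", name)
  }
  as.integer(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (length(da) != length(db) || any(da != db)) {
    stopf("%s must have identical shapes (got %s vs %s)", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  invisible(TRUE)
}
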