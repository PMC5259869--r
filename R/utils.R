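# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Logging: messages can be silenced globally via options(comodule.verbose = FALSE).
co_log <- function(fmt, ...) {
  if (isTRUE(getOption("comodule.verbose", TRUE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

is_binary01 <- function(m) all(m == 0 | m == 1)

# scale rows of a matrix to unit Euclidean norm; all-zero rows are left at zero
row_unit_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, , drop = FALSE] -> mm
  m[nz, ] <- mm / nrm[nz]
  m
}

pair_key <- function(gene, mirna) paste(gene, mirna, sep = "\r")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
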