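# Internal helpers: seeded evaluation, stable link functions, base encoding.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so that
#' seeded simulators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a parent seed and a stream index, staying < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

# Numerically stable softplus link with sharpness beta: log(1 + exp(beta*x))/beta.
softplus <- function(x, beta = 1) {
  z <- beta * x
  out <- log1p(exp(pmin(z, 30))) / beta
  big <- z > 30
  if (any(big)) out[big] <- x[big]
  out
}

# Inverse softplus: the pre-link score whose softplus equals rate r > 0.
inv_softplus <- function(r, beta = 1) {
  stopifnot(all(r > 0))
  z <- beta * r
  ifelse(z > 30, r, log(expm1(z)) / beta)
}

# Encode an upper-case ACGTN string as integers 1..4 (N -> NA).
seq_to_int <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  match(chars, BASES)
}

int_to_seq <- function(ints) {
  chars <- ifelse(is.na(ints), "N", BASES[ints])
  paste(chars, collapse = "")
}

# Reverse complement on the integer encoding (NA stays NA).
rc_int <- function(ints) rev(5L - ints)

rc_seq <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
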