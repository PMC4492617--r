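# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls stay side-effect free.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal draws by inverse-CDF so they are cheap and seed-stable.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' @importFrom stats pnorm
soft_threshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}

# binomial log-likelihood for probabilities p and outcome y in {0,1}
binomial_loglik <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

check_binary_outcome <- function(y, arg = "outcome") {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary 0/1 vector with no missing values", arg),
         call. = FALSE)
  }
  y
}

# error signalled when a logistic fit diverges (complete/quasi-complete separation)
separation_error <- function(msg) {
  stop(structure(
    class = c("srp_separation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
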