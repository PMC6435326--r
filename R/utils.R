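# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All simulators go through this so that no
# generator touches global random state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("seed must be a single finite number")
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(msg, class = "gt_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "gt_error")))
}

stop_degenerate <- function(msg) {
  stop_invalid(msg, class = "gt_degenerate_input")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# A discrete distribution over positive integers, given as a probability
# vector over 1:length(p). Returns a sampler closure.
discrete_sampler <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) || any(p < 0) ||
      sum(p) <= 0) {
    stop_invalid("a discrete distribution must be a non-negative probability vector")
  }
  p <- p / sum(p)
  function(n) sample.int(length(p), n, replace = TRUE, prob = p)
}
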