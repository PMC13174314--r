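# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route their seed through this
#' helper so that a call never perturbs the caller's RNG stream.
#'
#' @param seed integer seed (kept below 2^31 by the caller).
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-stream seed from a global seed with a fixed offset so adding a
# generator never changes another generator's draws.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

stop_regenmac <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

# Rank-based AUC of `x` for separating `positive` (logical) observations:
# the Mann-Whitney U statistic scaled to [0, 1] with midranks for ties.
rank_auc <- function(x, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Two-sided Wilcoxon rank-sum test used by rank_markers and
# differential_ligands. Exact distribution when both groups are small and
# untied (the field-standard convention); otherwise the normal approximation
# with tie and continuity corrections.
rank_sum_test <- function(x_in, x_out, exact_max_n = 50L) {
  n1 <- length(x_in)
  n2 <- length(x_out)
  r <- rank(c(x_in, x_out))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= exact_max_n && n2 <= exact_max_n) {
    if (u > n1 * n2 / 2) {
      p <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- stats::pwilcox(u, n1, n2)
    }
    p <- min(1, 2 * p)
  } else {
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- z - sign(z) * 0.5  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z / sqrt(sigma2))))
    }
  }
  list(statistic = u, p = p)
}

# Dirichlet draws (rows = draws), via normalized gamma variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
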