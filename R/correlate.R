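# Correlation between pocket availability (binding propensity) and
# equilibrium binding, with exact permutation inference: at the sample
# sizes of a ligand panel (n ~ 4-8) asymptotic p-values are invalid, so
# all n! pairings are enumerated.

# All permutations of 1..n as an (n! x n) matrix, in lexicographic order.
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out[row + seq_len(nrow(sub)), 1] <- first
    out[row + seq_len(nrow(sub)), -1] <- matrix(rest[sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

#' Correlate binding propensity with equilibrium binding
#'
#' Pearson and Spearman correlations with one-sided (positive
#' association) permutation p-values.  For `n <= exact_max` (default 8)
#' all `n!` pairings are enumerated, giving exact p-values with floor
#' `1/n!`; larger panels use seeded Monte-Carlo permutation.
#'
#' @param propensities named numeric vector of per-ligand binding
#'   propensities (fractions).
#' @param binding_values named numeric vector of per-ligand equilibrium
#'   binding (RU); names must match `propensities`.
#' @param exact_max largest n for exhaustive enumeration (default 8).
#' @param n_mc Monte-Carlo permutations when `n > exact_max`.
#' @param seed seed for the Monte-Carlo branch.
#' @return List of class `correlation_result`: `n`, `pearson_r`,
#'   `spearman_rho`, `p_pearson`, `p_spearman`, `exact` (logical),
#'   `p_floor` (smallest achievable p), `method`.
#' @export
correlate <- function(propensities, binding_values, exact_max = 8,
                      n_mc = 20000, seed = 1) {
  n <- length(propensities)
  if (n < 3L) stop("correlation needs at least 3 paired values")
  if (length(binding_values) != n) stop("input lengths differ")
  if (!is.null(names(propensities)) && !is.null(names(binding_values))) {
    if (!setequal(names(propensities), names(binding_values))) {
      stop("ligand labels do not match between the two vectors")
    }
    binding_values <- binding_values[names(propensities)]
  }
  x <- as.numeric(propensities); y <- as.numeric(binding_values)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: at least one vector is constant")
  }
  r_obs <- cor(x, y, method = "pearson")
  rho_obs <- cor(x, y, method = "spearman")
  eps <- 1e-12
  if (n <= exact_max) {
    perms <- .all_permutations(n)
    r_perm <- apply(perms, 1, function(p) cor(x, y[p], method = "pearson"))
    rho_perm <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
    p_r <- mean(r_perm >= r_obs - eps)
    p_rho <- mean(rho_perm >= rho_obs - eps)
    exact <- TRUE
    p_floor <- 1 / factorial(n)
  } else {
    set.seed(seed)
    r_perm <- rho_perm <- numeric(n_mc)
    for (b in seq_len(n_mc)) {
      yp <- sample(y)
      r_perm[b] <- cor(x, yp, method = "pearson")
      rho_perm[b] <- cor(x, yp, method = "spearman")
    }
    # add-one Monte-Carlo estimator (includes the observed pairing)
    p_r <- (1 + sum(r_perm >= r_obs - eps)) / (n_mc + 1)
    p_rho <- (1 + sum(rho_perm >= rho_obs - eps)) / (n_mc + 1)
    exact <- FALSE
    p_floor <- 1 / (n_mc + 1)
  }
  structure(list(n = n, pearson_r = r_obs, spearman_rho = rho_obs,
                 p_pearson = p_r, p_spearman = p_rho, exact = exact,
                 p_floor = p_floor,
                 method = if (exact) "exact permutation (all n! pairings)"
                          else sprintf("Monte-Carlo permutation (%d draws)",
                                       n_mc)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> n = %d: Pearson r = %.3f (p = %.4f), Spearman rho = %.3f (p = %.4f)\n",
              x$n, x$pearson_r, x$p_pearson, x$spearman_rho, x$p_spearman))
  cat(sprintf("  %s; smallest achievable one-sided p = %.4g\n",
              x$method, x$p_floor))
  invisible(x)
}
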