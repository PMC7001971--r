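#' Two-sample permutation test
#'
#' Tests whether two samples share a common distribution by permuting the
#' group labels. When the pooled sample has fewer than `exact_limit`
#' observations, all `choose(n_a + n_b, n_a)` label assignments are
#' enumerated and the p-value is the exact fraction of assignments whose
#' statistic is at least as extreme as the observed one. Otherwise a Monte
#' Carlo approximation with `n_perm` random assignments is used, with the
#' add-one correction p = (b + 1) / (n_perm + 1) so that p is never zero.
#'
#' @param a,b Numeric samples (finite, non-empty).
#' @param statistic `"mean"` (difference of group means, default) or
#'   `"median"` (difference of group medians).
#' @param n_perm Number of Monte Carlo permutations (default 1,000,000).
#' @param exact_limit Pooled sample sizes below this are enumerated
#'   exactly (default 10).
#' @param seed Optional seed making the Monte Carlo draw reproducible; the
#'   caller's random state is left untouched.
#' @return A list of class `permutation_result`: `p_value`,
#'   `observed_statistic`, `n_permutations_used`, `method` (`"exact"` or
#'   `"approximate"`), `seed`. The test is two-sided.
#' @examples
#' permutation_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
permutation_test <- function(a, b, statistic = c("mean", "median"),
                             n_perm = 1e6, exact_limit = 10, seed = NULL) {
  statistic <- match.arg(statistic)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must contain only finite values")
  pooled <- c(a, b)
  n_a <- length(a)
  n <- length(pooled)
  stat_fun <- if (statistic == "mean") {
    function(idx_a) mean(pooled[idx_a]) - mean(pooled[-idx_a])
  } else {
    function(idx_a) stats::median(pooled[idx_a]) - stats::median(pooled[-idx_a])
  }
  obs <- stat_fun(seq_len(n_a))
  tol <- 1e-12 * max(1, abs(obs))

  if (n < exact_limit) {
    assignments <- utils::combn(n, n_a)
    perm <- apply(assignments, 2, stat_fun)
    k <- sum(abs(perm) >= abs(obs) - tol)
    return(structure(list(p_value = k / ncol(assignments),
                          observed_statistic = obs,
                          n_permutations_used = ncol(assignments),
                          method = "exact", seed = seed),
                     class = "permutation_result"))
  }

  draw <- function() {
    n_perm <- as.integer(n_perm)
    extreme <- 0L
    chunk <- 20000L
    done <- 0L
    if (statistic == "mean") {
      # difference of means depends only on the group-a sum
      n_b <- n - n_a
      total <- sum(pooled)
      thresh <- abs(obs) - tol
      while (done < n_perm) {
        m <- min(chunk, n_perm - done)
        s_a <- vapply(seq_len(m),
                      function(i) sum(pooled[sample.int(n, n_a)]), 0.0)
        d <- s_a / n_a - (total - s_a) / n_b
        extreme <- extreme + sum(abs(d) >= thresh)
        done <- done + m
      }
    } else {
      while (done < n_perm) {
        m <- min(chunk, n_perm - done)
        d <- vapply(seq_len(m),
                    function(i) stat_fun(sample.int(n, n_a)), 0.0)
        extreme <- extreme + sum(abs(d) >= abs(obs) - tol)
        done <- done + m
      }
    }
    (extreme + 1) / (n_perm + 1)
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(p_value = p, observed_statistic = obs,
                 n_permutations_used = as.integer(n_perm),
                 method = "approximate", seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s, p = %.4g (stat = %.4g, %s perms)\n",
              x$method, x$p_value, x$observed_statistic,
              format(x$n_permutations_used, big.mark = ",")))
  invisible(x)
}
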