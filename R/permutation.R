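# Two-sample permutation test on the absolute difference of means, with a
# Monte-Carlo backend (add-one smoothed p) and an exact enumeration backend,
# plus a type-I-error / power simulation harness.

.check_groups <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("groups contain non-finite values", call. = FALSE)
  if (length(a) + length(b) < 3)
    stop("combined sample size must be at least 3", call. = FALSE)
}

.perm_result <- function(observed, p, n_iter, backend, seed = NULL) {
  structure(list(observed_stat = observed, p_value = p,
                 n_iterations = n_iter, backend = backend, seed = seed),
            class = "permutation_result")
}

#' Exact two-sample permutation test
#'
#' Enumerates every split of the pooled sample that preserves the group
#' sizes and computes the two-sided statistic `|mean(a) - mean(b)|` for
#' each. The p-value is the fraction of splits whose statistic is at least
#' the observed one (ties count, so the identity split guarantees
#' `p >= 1/n_splits`).
#'
#' @param a,b Numeric group samples.
#' @param max_splits Enumeration cap; exceeding it raises an error directing
#'   the caller to the Monte-Carlo backend.
#' @return A `permutation_result` with `backend = "exact"`.
#' @export
exact_permutation_test <- function(a, b, max_splits = 2e5) {
  .check_groups(a, b)
  z <- c(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  n_splits <- choose(n, na)
  if (n_splits > max_splits)
    stop(sprintf(paste0("%.0f distinct splits exceed the enumeration cap ",
                        "(%g); use the Monte-Carlo backend"),
                 n_splits, max_splits), call. = FALSE)
  obs <- abs(mean(a) - mean(b))
  S <- sum(z)
  idx <- utils::combn(n, na)
  sa <- colSums(matrix(z[idx], nrow = na))
  stats <- abs(sa / na - (S - sa) / nb)
  p <- sum(stats >= obs - 1e-12) / n_splits
  .perm_result(obs, p, as.integer(n_splits), "exact")
}

#' Two-sample permutation test
#'
#' Tests the null hypothesis that the two groups come from the same
#' distribution using the two-sided statistic `|mean(a) - mean(b)|`. When
#' the number of distinct splits is small (at most `exact_threshold`) the
#' test switches to exact enumeration; otherwise it samples label
#' permutations with replacement and reports the add-one smoothed p-value
#' `(b + 1) / (m + 1)`, where `b` counts permuted statistics at least as
#' large as the observed one. The smoothed estimator is never
#' anti-conservative and never reports exactly 0: at 20,000 iterations the
#' smallest reportable p is 1/20001.
#'
#' @param a,b Numeric group samples (non-empty, finite, combined size >= 3).
#' @param n_iterations Monte-Carlo iterations (default 20000).
#' @param seed Optional integer seed; the ambient RNG state is restored
#'   afterwards. `NULL` draws from the ambient stream.
#' @param exact_threshold Switch to exact enumeration when the number of
#'   distinct splits is at most this (default 10000).
#' @return A `permutation_result`: `observed_stat`, `p_value`,
#'   `n_iterations`, `backend` (`"monte_carlo"` or `"exact"`), `seed`.
#' @export
permutation_test <- function(a, b, n_iterations = 20000, seed = NULL,
                             exact_threshold = 10000) {
  .check_groups(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  if (choose(n, na) <= exact_threshold)
    return(exact_permutation_test(a, b))
  # sort the pooled sample and always resample the smaller group size: the
  # null distribution depends only on the pooled multiset and the sizes, and
  # this makes the seeded p-value invariant to swapping the group labels
  z <- sort(c(a, b))
  obs <- abs(mean(a) - mean(b))
  S <- sum(z)
  k <- min(na, nb)
  run <- function() {
    stats <- numeric(n_iterations)
    for (i in seq_len(n_iterations)) {
      sk <- sum(z[sample.int(n, k)])
      stats[i] <- abs(sk / k - (S - sk) / (n - k))
    }
    sum(stats >= obs - 1e-12)
  }
  bcount <- if (is.null(seed)) run() else .with_seed(seed, run())
  .perm_result(obs, (bcount + 1) / (n_iterations + 1),
               as.integer(n_iterations), "monte_carlo",
               if (is.null(seed)) NULL else as.integer(seed))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> |mean diff| = %.4g, p = %.4g (%s, %d %s)\n",
              x$observed_stat, x$p_value, x$backend, x$n_iterations,
              if (x$backend == "exact") "splits" else "iterations"))
  invisible(x)
}

#' Type-I error and power of the permutation test by simulation
#'
#' Repeatedly draws two groups from `sampler` (the second shifted by each
#' value in `effects`), runs the permutation test, and reports the fraction
#' of p-values below `alpha` with an exact binomial confidence interval.
#' `effects = 0` estimates the type-I error rate; nonzero effects trace a
#' power curve.
#'
#' @param n_reps Monte-Carlo repetitions per effect size (>= 100).
#' @param group_sizes Integer vector of length 2.
#' @param seed Integer seed for the whole simulation.
#' @param effects Numeric vector of mean shifts applied to group b.
#' @param n_iterations Permutation iterations per test (smaller than the
#'   analysis default is fine here: only the alpha-level decision is used).
#' @param alpha Nominal level (default 0.05).
#' @param sampler Function `n -> numeric(n)` drawing a group under the null.
#' @param conf_level Confidence level of the binomial interval.
#' @return A data frame with `effect`, `n_reps`, `rejection_rate`,
#'   `ci_lower`, `ci_upper`.
#' @export
calibration_study <- function(n_reps = 1000, group_sizes = c(20, 20),
                              seed = 1, effects = 0, n_iterations = 800,
                              alpha = 0.05, sampler = stats::rnorm,
                              conf_level = 0.99) {
  if (n_reps < 100) stop("`n_reps` must be at least 100", call. = FALSE)
  .with_seed(seed, {
    out <- do.call(rbind, lapply(effects, function(eff) {
      rej <- 0L
      for (r in seq_len(n_reps)) {
        a <- sampler(group_sizes[1])
        b <- sampler(group_sizes[2]) + eff
        p <- permutation_test(a, b, n_iterations = n_iterations)$p_value
        if (p < alpha) rej <- rej + 1L
      }
      ci <- stats::binom.test(rej, n_reps, conf.level = conf_level)$conf.int
      data.frame(effect = eff, n_reps = n_reps,
                 rejection_rate = rej / n_reps,
                 ci_lower = ci[1], ci_upper = ci[2])
    }))
    rownames(out) <- NULL
    out
  })
}
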