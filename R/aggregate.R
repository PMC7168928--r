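# Exact binomial majority-vote error analysis.
#
# A sample is measured with N independent spectra (N odd) and called ROD
# when more than N/2 of them score above 1.  If a single spectrum is scored
# correctly with probability p, the majority vote errs exactly when fewer
# than N/2 spectra are correct:
#
#   Q(N) = sum_{k = 0}^{k < N/2}  C(N, k) p^k (1 - p)^(N - k)
#
# evaluated exactly (no normal approximation).  Applied with p = p1
# (specificity) this is the Type I error of calling a normal sample ROD;
# with p = p2 (sensitivity) the Type II error of calling a ROD sample
# normal.

check_odd_n <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != floor(N))
    stop("`N` must be a positive integer", call. = FALSE)
  if (N %% 2 == 0)
    stop("`N` must be odd: the majority vote leaves ties undefined for ",
         "even N", call. = FALSE)
  as.integer(N)
}

check_prob <- function(p, name = "p") {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  p
}

# Tail sum over k in `ks`; direct binomial coefficients up to N = 60,
# log-gamma accumulation above to avoid overflow.
binom_tail <- function(p, N, ks) {
  if (length(ks) == 0L) return(0)
  if (N <= 60L) {
    sum(choose(N, ks) * p^ks * (1 - p)^(N - ks))
  } else {
    sum(exp(lchoose(N, ks) + ks * log(p) + (N - ks) * log1p(-p)))
  }
}

#' Exact majority-vote error probability
#'
#' Probability that a majority vote over `N` independent spectra is wrong
#' when each spectrum is scored correctly with probability `p`: the exact
#' binomial lower tail over the outcomes with fewer than `N / 2` correct
#' spectra.
#'
#' @param p Per-spectrum correct-classification probability, strictly in
#'   (0, 1).
#' @param N Odd positive number of independent spectra.
#' @return The error probability in \[0, 1\].
#' @examples
#' majority_error(0.783, 11)   # ~0.0174
#' majority_error(0.5, 101)    # exactly 0.5 by symmetry
#' @export
majority_error <- function(p, N) {
  p <- check_prob(p)
  N <- check_odd_n(N)
  binom_tail(p, N, 0:((N - 1L) %/% 2L))
}

#' Exact majority-vote success probability
#'
#' Complement of [majority_error()], summed over the outcomes with more than
#' `N / 2` correct spectra (for odd `N` the two tails partition all
#' outcomes).
#'
#' @inheritParams majority_error
#' @return The success probability in \[0, 1\].
#' @export
majority_correct <- function(p, N) {
  p <- check_prob(p)
  N <- check_odd_n(N)
  binom_tail(p, N, ((N + 1L) %/% 2L):N)
}

#' Minimal odd number of spectra meeting a target error probability
#'
#' Scans N = 1, 3, 5, ... and returns the first odd N whose
#' [majority_error()] falls strictly below `alpha`.  Requires `p > 0.5`:
#' a per-spectrum classifier no better than chance cannot be rescued by
#' majority voting.
#'
#' @inheritParams majority_error
#' @param alpha Target error probability, strictly in (0, 1); default 0.05.
#' @param n_max Search cap (default 10001); exceeding it is an error.
#' @return The minimal odd N (integer).
#' @examples
#' minimal_odd_n(0.783, 0.05)  # 7
#' minimal_odd_n(0.837, 0.05)  # 5
#' @export
minimal_odd_n <- function(p, alpha = 0.05, n_max = 10001) {
  p <- check_prob(p)
  check_prob(alpha, "alpha")
  if (p <= 0.5)
    stop("per-spectrum classifier is no better than chance (p <= 0.5); ",
         "no N attains alpha < 0.5", call. = FALSE)
  for (N in seq(1L, as.integer(n_max), by = 2L))
    if (majority_error(p, N) < alpha) return(N)
  stop(sprintf("no odd N <= %d reaches error < %g", n_max, alpha),
       call. = FALSE)
}

#' Type I / Type II error curves versus N
#'
#' Evaluates the exact majority-vote error for N = 1, 3, ..., `n_max`:
#' `q1` from `p1` (Type I, normal sample called ROD) and `q2` from `p2`
#' (Type II, ROD sample called normal).  Both curves are strictly
#' decreasing in N whenever the corresponding p exceeds 0.5.
#'
#' @param p1 Probability a normal spectrum scores below 1 (specificity).
#' @param p2 Probability a ROD spectrum scores above 1 (sensitivity).
#' @param n_max Largest (odd) N evaluated.
#' @return A data frame with columns `N`, `q1`, `q2`.
#' @export
error_curves <- function(p1, p2, n_max = 101) {
  check_prob(p1, "p1")
  check_prob(p2, "p2")
  n_max <- check_odd_n(n_max)
  N <- seq(1L, n_max, by = 2L)
  data.frame(
    N = N,
    q1 = vapply(N, function(n) majority_error(p1, n), numeric(1)),
    q2 = vapply(N, function(n) majority_error(p2, n), numeric(1)))
}

#' N-spectra confusion matrix on the probability scale
#'
#' The diagnostic report of the N-spectrum majority-vote classifier,
#' computed in closed form: the condition-ROD column carries probability
#' mass `prevalence * (1 - q2, q2)` and the condition-normal column
#' `(1 - prevalence) * (q1, 1 - q1)`, with `q1 = majority_error(p1, N)` and
#' `q2 = majority_error(p2, N)`.  Accuracy is the prevalence-weighted
#' probability of a correct call.
#'
#' @inheritParams error_curves
#' @param prevalence ROD sample fraction (default 4/7, the study cohort).
#' @param N Odd number of spectra.
#' @return A [diagnostic_report_from_counts()] object whose "counts" are
#'   probability masses summing to 1.
#' @examples
#' r <- n_spectra_confusion(0.837, 0.783, 4/7, 11)
#' round(100 * r$accuracy, 1)  # 98.8
#' @export
n_spectra_confusion <- function(p1, p2, prevalence = 4 / 7, N) {
  check_prob(p1, "p1")
  check_prob(p2, "p2")
  check_prob(prevalence, "prevalence")
  N <- check_odd_n(N)
  q1 <- majority_error(p1, N)
  q2 <- majority_error(p2, N)
  diagnostic_report_from_counts(
    tp = prevalence * (1 - q2),
    fp = (1 - prevalence) * q1,
    fn = prevalence * q2,
    tn = (1 - prevalence) * (1 - q1))
}

#' Monte-Carlo estimate of the majority-vote error
#'
#' Mechanical simulation used as an independent check on the closed form:
#' `reps` majority votes over `N` Bernoulli(`p`) correctness draws.
#'
#' @inheritParams majority_error
#' @param reps Number of simulated votes (>= 1).
#' @param seed Optional integer seed.
#' @return A list: `estimate`, its binomial standard error `se`, and `reps`.
#' @export
monte_carlo_majority <- function(p, N, reps = 2e5, seed = NULL) {
  p <- check_prob(p)
  N <- check_odd_n(N)
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  correct <- matrix(stats::runif(reps * N) < p, reps, N)
  err <- mean(rowSums(correct) < N / 2)
  list(estimate = err, se = sqrt(err * (1 - err) / reps), reps = reps)
}

#' Full majority-vote aggregation analysis
#'
#' Bundles the replicate-number analysis for one pair of single-spectrum
#' probabilities: minimal odd N for each error type at `alpha`, the error
#' curves up to `n_max`, and the `n_eval`-spectra confusion report.
#'
#' Note on labelling: Type I (normal sample called ROD) is governed by `p1`,
#' the specificity, and Type II by `p2`, the sensitivity, exactly as the
#' binomial construction assigns them.
#'
#' @param inputs An [aggregation_inputs()] object (or any list with `p1`,
#'   `p2`, `prevalence`, `alpha`).
#' @param n_eval Odd N for the confusion report (default 11).
#' @param n_max Largest odd N of the error curves (default 51).
#' @return An object of class `aggregation_result`: the inputs,
#'   `n_star_type1`, `n_star_type2`, `curves`, `n_eval` and
#'   `n_spectra_report`.
#' @export
aggregate_analysis <- function(inputs, n_eval = 11, n_max = 51) {
  p1 <- check_prob(inputs$p1, "p1")
  p2 <- check_prob(inputs$p2, "p2")
  prevalence <- check_prob(inputs$prevalence, "prevalence")
  alpha <- check_prob(inputs$alpha, "alpha")
  n_eval <- check_odd_n(n_eval)
  structure(
    list(p1 = p1, p2 = p2, prevalence = prevalence, alpha = alpha,
         n_star_type1 = minimal_odd_n(p1, alpha),
         n_star_type2 = minimal_odd_n(p2, alpha),
         curves = error_curves(p1, p2, n_max),
         n_eval = n_eval,
         n_spectra_report = n_spectra_confusion(p1, p2, prevalence,
                                                n_eval)),
    class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat("<aggregation_result>\n")
  cat(sprintf("  p1 (specificity) %.4f   p2 (sensitivity) %.4f   prevalence %.4f\n",
              x$p1, x$p2, x$prevalence))
  cat(sprintf("  minimal odd N for error < %g: Type I %d, Type II %d\n",
              x$alpha, x$n_star_type1, x$n_star_type2))
  cat(sprintf("  %d-spectra majority vote: accuracy %.1f%%, Type I %.2f%%, Type II %.2f%%\n",
              x$n_eval, 100 * x$n_spectra_report$accuracy,
              100 * majority_error(x$p1, x$n_eval),
              100 * majority_error(x$p2, x$n_eval)))
  invisible(x)
}
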