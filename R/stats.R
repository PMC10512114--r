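# Expert-agreement evaluation statistics: reconstruction of binomial counts
# from printed percentages, odds ratios, grouped-binomial likelihood-ratio
# tests, and logit agreement models with optional participant-level random
# intercepts.

#' Reconstruct a count from a printed percentage
#'
#' Returns the integer `k` nearest to `percent * n / 100`, and errors if that
#' integer does not round back to the same percentage at one decimal — i.e.
#' if the printed (percent, n) pair is internally inconsistent.
#'
#' @param percent printed percentage (one decimal).
#' @param n denominator.
#' @return Integer count `k`.
#' @export
#' @examples
#' counts_from_percent(89.3, 56)  # 50
counts_from_percent <- function(percent, n) {
  stopifnot(percent >= 0, percent <= 100, n > 0)
  k <- round(percent * n / 100)
  back <- round(100 * k / n, 1)
  if (back != round(percent, 1))
    stop(sprintf(paste0("inconsistent (percent, n): %.1f%% of %d gives k = %d, ",
                        "which re-rounds to %.1f%%"), percent, n, k, back))
  as.integer(k)
}

#' Agreement counts for a set of explanation methods
#'
#' @param name method names; the first is taken as the reference group unless
#'   `reference` says otherwise.
#' @param k,n successes and trials per method.
#' @param outcome label of the binary outcome (e.g. "final_agreement").
#' @param reference name of the reference method.
#' @return A data frame of class `primo_counts` with attributes `outcome` and
#'   `reference`.
#' @export
agreement_counts <- function(name, k, n, outcome = "agreement",
                             reference = name[1]) {
  stopifnot(length(name) == length(k), length(k) == length(n),
            all(k >= 0), all(k <= n), reference %in% name)
  out <- data.frame(name = name, k = as.integer(k), n = as.integer(n))
  attr(out, "outcome") <- outcome
  attr(out, "reference") <- reference
  class(out) <- c("primo_counts", "data.frame")
  out
}

#' Odds ratio between two binomial counts
#'
#' `[k1/(n1-k1)] / [k0/(n0-k0)]`, group 0 being the reference. No continuity
#' correction: a zero cell returns `Inf` or `0` with a warning rather than a
#' corrected value.
#'
#' @param k1,n1 successes/trials in the comparison group.
#' @param k0,n0 successes/trials in the reference group.
#' @return The odds ratio.
#' @export
#' @examples
#' odds_ratio(50, 56, 38, 56)  # 3.95
odds_ratio <- function(k1, n1, k0, n0) {
  stopifnot(k1 >= 0, k1 <= n1, k0 >= 0, k0 <= n0)
  if (k1 == 0 || k1 == n1 || k0 == 0 || k0 == n0)
    warning("zero cell: odds ratio is unbounded (0 or Inf), no continuity correction applied")
  (k1 / (n1 - k1)) / (k0 / (n0 - k0))
}

#' Likelihood-ratio test for equal proportions across groups
#'
#' Grouped-binomial LRT: twice the log-likelihood gap between the saturated
#' model (one proportion per group, MLE k/n) and the pooled model (one common
#' proportion), referred to a chi-square with groups - 1 degrees of freedom.
#' This is the zero-random-effect limit of a mixed-logit LRT, appropriate
#' when the between-participant variance is negligible (ICC near 0).
#'
#' @param counts a `primo_counts` table (or data frame with columns `k`, `n`).
#' @return List with `chi2`, `df`, `p`.
#' @export
#' @examples
#' binomial_lrt(agreement_counts(c("a", "b", "c"), k = c(50, 43, 38),
#'                               n = c(56, 56, 56)))
binomial_lrt <- function(counts) {
  k <- counts$k; n <- counts$n
  if (length(k) < 2) stop("need at least two groups")
  if (any(n == 0)) stop("empty group")
  ll <- function(k, n, p) {
    # binomial log-likelihood kernel, safe at p in {0, 1}
    term <- function(x, lp) ifelse(x == 0, 0, x * log(lp))
    sum(term(k, p) + term(n - k, 1 - p))
  }
  p_hat <- k / n
  ll_sat <- sum(vapply(seq_along(k), function(i) ll(k[i], n[i], p_hat[i]), 0))
  p_pool <- sum(k) / sum(n)
  ll_pool <- ll(k, n, rep(p_pool, length(k)))
  chi2 <- 2 * (ll_sat - ll_pool)
  df <- length(k) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Fit a logit agreement model over methods
#'
#' Logistic model of a binary agreement outcome on explanation method, with
#' the reference method as intercept. Without a random intercept this is the
#' grouped-binomial MLE (fit by [stats::glm()]), whose coefficients
#' reproduce the marginal odds ratios exactly. With `random_intercept =
#' TRUE` a participant-level random intercept is added and the model is fit
#' by adaptive Gauss-Hermite quadrature via [lme4::glmer()]; the intraclass
#' correlation is `sigma^2 / (sigma^2 + pi^2 / 3)` on the latent logit scale.
#'
#' @param x a `primo_counts` table (fixed effects only), or a response table
#'   as returned by [simulate_responses()] with columns `participant`,
#'   `method`, `outcome`.
#' @param random_intercept add a participant-level random intercept
#'   (requires a response table).
#' @param reference reference method (default: attribute of `x`, else first
#'   level).
#' @param nAGQ quadrature points for the mixed fit.
#' @return A data frame of class `primo_agreement_fit` with one row per
#'   model term (`term`, `odds_ratio`, `ci_low`, `ci_high`, `p`), plus
#'   attributes `icc`, `sigma`, `logLik`, and `model`.
#' @export
fit_agreement_model <- function(x, random_intercept = FALSE, reference = NULL,
                                nAGQ = 7L) {
  if (inherits(x, "primo_counts")) {
    if (random_intercept)
      stop("random intercepts require participant-level responses, not aggregate counts")
    reference <- reference %||% attr(x, "reference")
    meth <- factor(x$name, levels = c(reference, setdiff(x$name, reference)))
    fit <- stats::glm(cbind(k, n - k) ~ meth, family = stats::binomial(),
                      data = data.frame(k = x$k, n = x$n, meth = meth))
    sigma <- 0
  } else {
    stopifnot(all(c("participant", "method", "outcome") %in% names(x)))
    reference <- reference %||% sort(unique(x$method))[1]
    x$method <- factor(x$method,
                       levels = c(reference, setdiff(unique(x$method), reference)))
    if (random_intercept) {
      fit <- lme4::glmer(outcome ~ method + (1 | participant), data = x,
                         family = stats::binomial(), nAGQ = nAGQ)
      conv <- fit@optinfo$conv$opt
      if (!is.null(conv) && conv != 0)
        stop("mixed model did not converge (optimizer code ", conv, ")")
      sigma <- sqrt(unname(lme4::VarCorr(fit)$participant[1]))
    } else {
      fit <- stats::glm(outcome ~ method, family = stats::binomial(), data = x)
      sigma <- 0
    }
  }
  cf <- if (random_intercept) lme4::fixef(fit) else stats::coef(fit)
  se <- if (random_intercept) sqrt(diag(as.matrix(stats::vcov(fit))))
        else sqrt(diag(stats::vcov(fit)))
  zval <- cf / se
  out <- data.frame(term = sub("^meth(od)?", "", names(cf)),
                    odds_ratio = exp(unname(cf)),
                    ci_low = exp(unname(cf - 1.96 * se)),
                    ci_high = exp(unname(cf + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(zval))))
  out$term[1] <- "(intercept)"
  attr(out, "sigma") <- sigma
  attr(out, "icc") <- sigma^2 / (sigma^2 + pi^2 / 3)
  attr(out, "logLik") <- as.numeric(stats::logLik(fit))
  attr(out, "model") <- fit
  class(out) <- c("primo_agreement_fit", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate participant-level agreement responses
#'
#' Per participant, a latent intercept is drawn from Normal(0, sigma^2); each
#' (method, item) response is Bernoulli with
#' `logit p = logit(p_method) + intercept`. This provides known ground truth
#' for parameter-recovery checks of [fit_agreement_model()].
#'
#' @param participants number of participants.
#' @param p_method named vector of marginal-scale method agreement
#'   probabilities (on the latent scale; the conditional probability of a
#'   median participant).
#' @param sigma between-participant SD on the logit scale (e.g. 0.855 gives
#'   ICC 0.18).
#' @param items responses per participant and method (the study used 4
#'   archetype items).
#' @param seed integer seed.
#' @return A data frame with columns `participant`, `method`, `item`,
#'   `outcome`, deterministic given the seed.
#' @export
simulate_responses <- function(participants, p_method, sigma, items = 4L,
                               seed = 1L) {
  stopifnot(all(p_method > 0), all(p_method < 1), sigma >= 0)
  methods <- names(p_method)
  if (is.null(methods)) methods <- paste0("method_", seq_along(p_method))
  with_seed(seed, {
    b <- stats::rnorm(participants, 0, sigma)
    grid <- expand.grid(item = seq_len(items), method = methods,
                        participant = seq_len(participants),
                        stringsAsFactors = FALSE)
    eta <- stats::qlogis(p_method[grid$method]) + b[grid$participant]
    grid$outcome <- stats::rbinom(nrow(grid), 1L, stats::plogis(eta))
    grid[, c("participant", "method", "item", "outcome")]
  })
}

#' Reconstructed agreement counts from the expert study
#'
#' The published evaluation reports, for 14 experts responding to 4 archetype
#' items under each of three explanation methods (56 responses per method):
#' final agreement of 67.9% (best-worst case), 76.8% (monotonicity) and
#' 89.3% (PRIMO); initially correct responses of 66.1%, 69.6% and 67.9%; and,
#' among the initially correct, switches to disagree of 18.9%, 5.1% and 2.6%.
#' This helper turns those printed percentages back into integer counts.
#'
#' @param outcome `"final_agreement"` or `"switch_to_disagree"`.
#' @return A `primo_counts` table with reference group `"best_worst"`.
#' @export
#' @examples
#' study_counts("final_agreement")
study_counts <- function(outcome = c("final_agreement", "switch_to_disagree")) {
  outcome <- match.arg(outcome)
  methods <- c("best_worst", "monotonicity", "primo")
  if (outcome == "final_agreement") {
    n <- rep(56L, 3)
    k <- vapply(c(67.9, 76.8, 89.3), counts_from_percent, 0L, n = 56)
  } else {
    # denominators: initially correct responses per method
    n <- vapply(c(66.1, 69.6, 67.9), counts_from_percent, 0L, n = 56)
    k <- vapply(seq_len(3), function(i)
      counts_from_percent(c(18.9, 5.1, 2.6)[i], n[i]), 0L)
  }
  agreement_counts(methods, k, n, outcome = outcome, reference = "best_worst")
}

#' Read or write agreement counts as JSON
#'
#' Schema: `{"outcome", "reference", "groups":[{"name","n","k"}, ...]}`.
#'
#' @param counts a `primo_counts` table.
#' @param path file path.
#' @return `read_counts` returns a `primo_counts`; `write_counts` invisibly
#'   returns `path`.
#' @export
write_counts <- function(counts, path) {
  obj <- list(outcome = attr(counts, "outcome"),
              reference = attr(counts, "reference"),
              groups = lapply(seq_len(nrow(counts)), function(i)
                list(name = counts$name[i], n = counts$n[i], k = counts$k[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  agreement_counts(vapply(obj$groups, `[[`, "", "name"),
                   vapply(obj$groups, function(g) as.integer(g$k), 0L),
                   vapply(obj$groups, function(g) as.integer(g$n), 0L),
                   outcome = obj$outcome, reference = obj$reference)
}
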