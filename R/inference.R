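# Binomial log-likelihood at a given probability, without the binomial
# coefficient (it cancels in every likelihood ratio). Uses the 0*log(0) = 0
# convention so arms at 0% or 100% mortality are handled exactly.
.binom_loglik <- function(x, n, p) {
  ifelse(x == 0, 0, x * log(p)) + ifelse(x == n, 0, (n - x) * log(1 - p))
}

# Vectorized two-sample binomial LRT statistic from arm totals. The one-factor
# binomial GLM is saturated in the arm factor, so the arm MLEs are the pooled
# proportions and the deviance difference has this closed form; it is identical
# to a converged glm() fit, including complete-separation cases.
.lrt_stat <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  stat <- 2 * (.binom_loglik(x1, n1, p1) + .binom_loglik(x2, n2, p2) -
                 .binom_loglik(x1, n1, pp) - .binom_loglik(x2, n2, pp))
  pmax(stat, 0)  # guard against -1e-16 from floating point
}

# Arm totals from a tube observation table; errors if an arm is absent.
.arm_totals <- function(obs) {
  validate_tube_observations(obs)
  for (a in c("reference", "treatment")) {
    if (!any(!is.na(obs$arm) & obs$arm == a)) {
      stop("observations must contain both arms; '", a, "' is missing",
           call. = FALSE)
    }
  }
  keep <- !is.na(obs$arm)
  dead <- c(tapply(obs$n_dead[keep], obs$arm[keep], sum))
  exposed <- c(tapply(obs$n_exposed[keep], obs$arm[keep], sum))
  list(dead = dead[c("reference", "treatment")],
       exposed = exposed[c("reference", "treatment")])
}

#' Fit the two-arm binomial GLM
#'
#' Fits the binomial GLM with a single fixed effect for treatment group (no
#' random effects) to a set of tube observations. Because the model is
#' saturated in the arm factor, the maximum-likelihood mortality estimate for
#' each arm is simply that arm's pooled deaths over pooled exposed; the fit is
#' computed in closed form and is identical to a converged iterative fit,
#' including arms at exactly 0% or 100% mortality, which stall iterative
#' fitters through complete separation.
#'
#' Log-likelihoods are reported without the binomial-coefficient constant
#' (which cancels in any likelihood ratio), with the \eqn{0 \log 0 = 0}
#' convention.
#'
#' @param obs A data frame of tube observations containing both arms.
#' @return An object of class `two_arm_fit`: a list with `estimates` (named
#'   per-arm mortality MLEs), `deaths`, `exposed`, per-arm log-likelihoods
#'   `loglik_by_arm`, and the full-model `loglik`.
#' @examples
#' obs <- tube_observations(day_id = 1, tube_id = c("r", "t"),
#'                          arm = c("reference", "treatment"),
#'                          n_exposed = 100, n_dead = c(90, 100))
#' fit_two_arm_glm(obs)$estimates
#' @export
fit_two_arm_glm <- function(obs) {
  tot <- .arm_totals(obs)
  est <- tot$dead / tot$exposed
  ll_arm <- .binom_loglik(tot$dead, tot$exposed, est)
  structure(
    list(estimates = est, deaths = tot$dead, exposed = tot$exposed,
         loglik_by_arm = ll_arm, loglik = sum(ll_arm)),
    class = "two_arm_fit"
  )
}

#' @export
print.two_arm_fit <- function(x, ...) {
  cat(sprintf("Two-arm binomial GLM: reference %d/%d (%.1f%%), treatment %d/%d (%.1f%%)\n",
              x$deaths[["reference"]], x$exposed[["reference"]],
              100 * x$estimates[["reference"]],
              x$deaths[["treatment"]], x$exposed[["treatment"]],
              100 * x$estimates[["treatment"]]))
  cat(sprintf("log-likelihood (full model): %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for a mortality difference between arms
#'
#' Compares the two-arm binomial GLM against the intercept-only (pooled)
#' model: the statistic is twice the log-likelihood difference, referred to a
#' chi-square distribution with 1 degree of freedom (no continuity
#' correction). Only arm totals matter — the statistic is invariant to how
#' deaths are split among tubes within an arm. Arms at 0% or 100% mortality
#' are handled exactly through the \eqn{0 \log 0 = 0} convention, never by
#' dropping data; two arms with identical pooled mortality give statistic 0
#' and p-value 1.
#'
#' @param obs A data frame of tube observations containing both arms.
#' @return An object of class `lrt_result`: a list with `statistic`, `df`
#'   (always 1), `p_value`, `pooled_mortality`, `arm_mortalities`, and
#'   `degenerate_flag` (`TRUE` when an arm estimate is exactly 0 or 1).
#' @examples
#' obs <- tube_observations(day_id = 1, tube_id = c("r", "t"),
#'                          arm = c("reference", "treatment"),
#'                          n_exposed = 100, n_dead = c(90, 100))
#' lrt_p_value(obs)
#' @export
lrt_p_value <- function(obs) {
  tot <- .arm_totals(obs)
  stat <- .lrt_stat(tot$dead[["reference"]], tot$exposed[["reference"]],
                    tot$dead[["treatment"]], tot$exposed[["treatment"]])
  est <- tot$dead / tot$exposed
  structure(
    list(
      statistic = stat,
      df = 1L,
      p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      pooled_mortality = sum(tot$dead) / sum(tot$exposed),
      arm_mortalities = est,
      degenerate_flag = any(est == 0 | est == 1)
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("Arm mortalities: reference %.3f, treatment %.3f (pooled %.3f)%s\n",
              x$arm_mortalities[["reference"]], x$arm_mortalities[["treatment"]],
              x$pooled_mortality,
              if (x$degenerate_flag) " [degenerate arm]" else ""))
  invisible(x)
}
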