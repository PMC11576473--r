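# Independent oracle for the two-sample binomial LRT: direct evaluation of
# 2 * [l(p1_hat) + l(p2_hat) - l(p_pooled)] using dbinom; the binomial
# coefficients cancel in the difference.
oracle_lrt_stat <- function(x1, n1, x2, n2) {
  pp <- (x1 + x2) / (n1 + n2)
  ll <- function(x, n, p) {
    if (p == 0 || p == 1) {
      # dbinom(log=TRUE) handles boundaries, incl. 0*log(0)
      return(dbinom(x, n, p, log = TRUE))
    }
    dbinom(x, n, p, log = TRUE)
  }
  max(0, 2 * (ll(x1, n1, x1 / n1) + ll(x2, n2, x2 / n2) -
                ll(x1, n1, pp) - ll(x2, n2, pp)))
}

# Build a two-arm observation table from arm totals, optionally split over
# several tubes per arm.
two_arm_obs <- function(dead_ref, exposed_ref, dead_trt, exposed_trt) {
  tube_observations(
    day_id = c(1L, 1L),
    tube_id = c("ref1", "trt1"),
    arm = c("reference", "treatment"),
    n_exposed = c(exposed_ref, exposed_trt),
    n_dead = c(dead_ref, dead_trt)
  )
}

# Exact type-I error rate of the LRT at alpha for two arms of n_arm
# mosquitoes each with true mortality p: full enumeration over arm totals.
exact_type1 <- function(n_arm, p, alpha = 0.05) {
  crit <- qchisq(1 - alpha, df = 1)
  px <- dbinom(0:n_arm, n_arm, p)
  reject <- outer(0:n_arm, 0:n_arm, Vectorize(function(x1, x2) {
    oracle_lrt_stat(x1, n_arm, x2, n_arm) > crit
  }))
  sum(outer(px, px) * reject)
}
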