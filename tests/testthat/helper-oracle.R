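# Independent reference implementation: dense nested 2-D Gauss-Legendre
# quadrature over (theta, theta2_hat), conditioning the phase III success
# layer on theta directly (no posterior collapse).  Deliberately written
# from the defining integrals rather than the package's conjugate-normal
# reduction, so the two paths share no algebra beyond dnorm/pnorm.
oracle_characteristics <- function(design, prior, test = test_spec(),
                                   thresholds = c(0.95, 0.85),
                                   n_theta = 200, n_est = 400, trunc = 10) {
  s2 <- 4 / design$d2
  sd2 <- sqrt(s2)
  keff <- effective_threshold(design$kappa, design$adj,
                              design$apply_to_decision, design$d2)
  zsum <- test$z_alpha + test$z_beta
  l1 <- -log(thresholds[1])
  l2 <- -log(thresholds[2])

  acc <- c(p_go = 0, d3 = 0, e2_num = 0, psp = 0, p1 = 0, p2 = 0, p3 = 0)
  for (k in seq_along(prior$weights)) {
    sk <- sqrt(prior$variances[k])
    gth <- pracma::gaussLegendre(n_theta, prior$means[k] - trunc * sk,
                                 prior$means[k] + trunc * sk)
    for (i in seq_len(n_theta)) {
      theta <- gth$x[i]
      wtheta <- gth$w[i] * prior$weights[k] *
        dnorm(theta, prior$means[k], sk)
      upper <- theta + trunc * sd2
      if (upper <= keff) next
      gt <- pracma::gaussLegendre(n_est, keff, upper)
      t <- gt$x
      ft <- dnorm(t, theta, sd2)
      a <- adjust_estimate(t, design$adj, design$d2)
      cc <- zsum / a
      # P(T3 > z + l*cc | theta): T3 ~ N(theta * sqrt(D3)/2, 1)
      s0 <- pnorm(theta * cc - test$z_alpha)
      s1 <- pnorm(theta * cc - test$z_alpha - l1 * cc)
      s2v <- pnorm(theta * cc - test$z_alpha - l2 * cc)
      acc["p_go"] <- acc["p_go"] + wtheta * sum(gt$w * ft)
      acc["d3"] <- acc["d3"] + wtheta * sum(gt$w * ft * 4 * cc^2)
      acc["e2_num"] <- acc["e2_num"] + wtheta * sum(gt$w * ft * a)
      acc["psp"] <- acc["psp"] + wtheta * sum(gt$w * ft * s0)
      acc["p1"] <- acc["p1"] + wtheta * sum(gt$w * ft * (s0 - s1))
      acc["p2"] <- acc["p2"] + wtheta * sum(gt$w * ft * (s1 - s2v))
      acc["p3"] <- acc["p3"] + wtheta * sum(gt$w * ft * s2v)
    }
  }
  list(p_go = unname(acc["p_go"]), d3 = unname(acc["d3"]),
       e2 = unname(acc["e2_num"] / acc["p_go"]), psp = unname(acc["psp"]),
       category_probs = unname(acc[c("p1", "p2", "p3")]))
}
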