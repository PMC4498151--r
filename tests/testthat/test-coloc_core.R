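test_that("coloc_priors validates its invariants", {
  pri <- coloc_priors()
  expect_equal(pri$p0 + pri$p1 + pri$p2 + pri$p12, 1)
  expect_error(coloc_priors(p12 = 1e-4), "p12")
  expect_error(coloc_priors(p12 = 2e-4), "p12")
  expect_error(coloc_priors(p12 = 0), "p12")
  expect_error(coloc_priors(p1 = 0.6, p2 = 0.5, p12 = 0.1), "< 1")
})

test_that("log_abf matches the closed-form density ratio and its limits", {
  # hand value: r = 0.8, z = 3 -> 0.5*log(0.2) + 3.6
  expect_equal(log_abf(0.3, 0.01, 0.04), 0.5 * log(0.2) + 3.6,
               tolerance = 1e-12)
  # beta = 0: evidence favours the null
  r <- 0.04 / (0.04 + 0.01)
  expect_equal(log_abf(0, 0.01, 0.04), 0.5 * log(1 - r))
  expect_lt(log_abf(0, 0.01, 0.04), 0)
  # degenerate prior limit: W -> 0 gives log ABF -> 0 for any beta
  expect_equal(log_abf(5, 0.01, 1e-12), 0, tolerance = 1e-6)
  expect_error(log_abf(Inf, 0.01, 0.04), "non-finite")
  expect_error(log_abf(0.3, 0, 0.04), "varbeta")
})

test_that("abf_from_pvalue reconstructs z and the variance approximation", {
  st <- abf_settings()
  # quantitative, maf = 0.5, n = 1000 -> varbeta = 1/(2*1000*0.25) = 0.002
  vb <- 0.002
  z <- qnorm(0.05 / 2, lower.tail = FALSE)  # 1.959964
  expect_equal(z, 1.959964, tolerance = 1e-6)
  expect_equal(abf_from_pvalue(0.05, 0.5, 1000, "quantitative"),
               log_abf(z * sqrt(vb), vb, st$W_quant), tolerance = 1e-12)
  # p = 1 -> z = 0 -> 0.5 * log(1 - r)
  r <- st$W_quant / (st$W_quant + vb)
  expect_equal(abf_from_pvalue(1, 0.5, 1000, "quantitative"), 0.5 * log(1 - r))
  # case-control divides the variance by s(1-s)
  s <- 0.35
  vb_cc <- vb / (s * (1 - s))
  expect_equal(abf_from_pvalue(0.05, 0.5, 1000, "case-control",
                               case_fraction = s),
               log_abf(z * sqrt(vb_cc), vb_cc, st$W_cc), tolerance = 1e-12)
  expect_warning(abf_from_pvalue(1e-310, 0.3, 1000, "quantitative"),
                 "clamped")
  expect_error(abf_from_pvalue(0, 0.3, 1000, "quantitative"), "p-values")
  expect_error(abf_from_pvalue(0.05, 0.6, 1000, "quantitative"), "maf")
})

test_that("log_abf agrees with the numerical-integration oracle (|z| <= 10)", {
  for (W in c(0.15^2, 0.2^2)) {
    for (vb in c(0.001, 0.01, 0.1)) {
      for (z in c(0, 0.5, 1, 3, 5, 10)) {
        beta <- z * sqrt(vb)
        expect_equal(log_abf(beta, vb, W),
                     log_abf_integration_oracle(beta, vb, W),
                     tolerance = 1e-8,
                     label = sprintf("W=%g vb=%g z=%g", W, vb, z))
      }
    }
  }
})

test_that("hypothesis_priors implements the five-hypothesis prior algebra", {
  pri <- coloc_priors()
  # Q = 1 forces P3 = 0
  expect_equal(hypothesis_priors(1, pri)$P3, 0)
  # Q = 101 at default priors: P4/P3 = p0*p12/(100*p1*p2) ~ 1
  hp <- hypothesis_priors(101, pri)
  expect_equal(hp$p4_over_p3, pri$p0 * pri$p12 / (100 * pri$p1 * pri$p2),
               tolerance = 1e-12)
  expect_equal(round(hp$p4_over_p3, 5), 0.99980)
  # the Eq-style approximation 1e8 * p12 / (Q - 1)
  expect_equal(hp$p4_over_p3, 1e8 * pri$p12 / 100, tolerance = 1e-3)
  # priors nearly exhaust the probability for large Q
  hp1000 <- hypothesis_priors(1000, pri)
  total <- hp1000$P0 + hp1000$P1 + hp1000$P2 + hp1000$P3 + hp1000$P4
  expect_gt(total, 0.99)
  expect_lte(total, 1)
  # P4/P3 strictly decreases with Q
  ratios <- vapply(c(2, 5, 10, 100, 1000, 5000),
                   function(q) hypothesis_priors(q, pri)$p4_over_p3,
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("coloc_posteriors matches hand-computed and prior-ratio cases", {
  pri <- coloc_priors()
  # Q = 2, BF = (10, 1) for both traits: PP4/PP3 = (1e-6*101)/(1e-8*20)
  r <- coloc_posteriors(log(c(10, 1)), log(c(10, 1)), pri)
  expect_equal(r$PP4 / r$PP3, 505, tolerance = 1e-9)
  # uninformative data (all BFs = 1): posterior ratios equal prior ratios
  Q <- 25L
  r0 <- coloc_posteriors(rep(0, Q), rep(0, Q), pri)
  hp <- hypothesis_priors(Q, pri)
  expect_equal(r0$PP1 / r0$PP0, hp$P1 / hp$P0, tolerance = 1e-3)
  expect_equal(r0$PP3 / r0$PP0, hp$P3 / hp$P0, tolerance = 1e-3)
  expect_equal(r0$PP4 / r0$PP3, hp$P4 / hp$P3, tolerance = 1e-3)
  # Q = 1: PP3 exactly 0
  r1 <- coloc_posteriors(log(5), log(7), pri)
  expect_identical(r1$PP3, 0)
  expect_error(coloc_posteriors(c(0, 0), 0, pri), "mismatch")
})

test_that("posteriors normalize and match the enumeration oracle", {
  pri <- coloc_priors()
  set.seed(11)
  for (rep in 1:60) {
    Q <- sample(1:20, 1)
    labf1 <- runif(Q, -2, 8)
    labf2 <- runif(Q, -2, 8)
    r <- coloc_posteriors(labf1, labf2, pri)
    pp <- c(r$PP0, r$PP1, r$PP2, r$PP3, r$PP4)
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    expect_equal(pp, coloc_enum_oracle(labf1, labf2, pri), tolerance = 1e-10)
  }
})

test_that("log-space evidence sums survive Table-3-scale Bayes factors", {
  pri <- coloc_priors()
  labf <- c(900, 880, rep(0, 98))  # would overflow exp() on natural scale
  r <- coloc_posteriors(labf, labf, pri)
  expect_true(all(is.finite(c(r$PP0, r$PP1, r$PP2, r$PP3, r$PP4))))
  expect_gt(r$PP4, 0.9)
})

test_that("PP4/PP3 is exactly proportional to p12 at fixed Bayes factors", {
  set.seed(21)
  Q <- 60L
  labf1 <- rnorm(Q, 1, 2); labf2 <- rnorm(Q, 1, 2)
  grid <- 10^seq(-7, -5, length.out = 7)
  ratio <- vapply(grid, function(p12) {
    r <- coloc_posteriors(labf1, labf2, coloc_priors(p12 = p12))
    r$PP4 / r$PP3
  }, numeric(1))
  slope <- ratio / grid
  expect_equal(max(slope) / min(slope), 1, tolerance = 1e-9)
})

test_that("classify_pair reproduces the published decision rules", {
  # convincing: PP3+PP4 = 1, PP4/PP3 = 32.013 with gates passed
  r <- fake_coloc_result(PP3 = 1 / 33.013, PP4 = 32.013 / 33.013)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "convincing")
  # suggestive: ratio 1.890
  r <- fake_coloc_result(PP3 = 1 / 2.890, PP4 = 1.890 / 2.890)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "suggestive")
  # distinct: overlap but odds favour separate variants
  r <- fake_coloc_result(PP3 = 0.80, PP4 = 0.195)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "distinct")
  # no overlap: PP3+PP4 = 0.054 + 0.218 association pattern
  r <- fake_coloc_result(PP0 = 0.70, PP1 = 0.1, PP2 = 0.146,
                         PP3 = 0.04, PP4 = 0.014)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "no_assoc")
  # one-trait: H1 modal below the overlap bar
  r <- fake_coloc_result(PP0 = 0.1, PP1 = 0.6, PP2 = 0.1, PP3 = 0.1, PP4 = 0.1)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "one_trait")
  # failed gates block overlap classes
  r <- fake_coloc_result(PP3 = 0.01, PP4 = 0.99)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "convincing")
  expect_equal(classify_pair(r, 1e-6, 1e-12), "no_assoc")
  expect_equal(classify_pair(r, 1e-12, 1e-8), "no_assoc")
  # PP3 = 0 with PP4 > 0: infinite ratio -> convincing
  r <- fake_coloc_result(PP3 = 0, PP4 = 1, Q = 1L)
  expect_equal(classify_pair(r, 1e-12, 1e-12), "convincing")
})
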