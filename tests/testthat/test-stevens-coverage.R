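# The hand-checkable values asserted below come from two independent
# routes: direct geometry on the unit circle (arcs of known length, where
# the covering probability can be integrated by hand) and exact enumeration
# over the binomial thinning of off-target reads.

test_that("series limiter respects strict positivity of 1 - beta*phi", {
  expect_equal(series_limiter(2, 0.6), 1)   # 1/0.6 = 1.67
  expect_equal(series_limiter(5, 1.0), 0)   # phi >= 1: one read covers all
  expect_equal(series_limiter(0, 0.1), 0)   # limited by R
  # integer 1/phi: beta = 2 would give 1 - 2*0.5 = 0, excluded
  expect_equal(series_limiter(10, 0.5), 1)
  expect_equal(series_limiter(10, 0.25), 3)
  expect_equal(series_limiter(2, 0.25), 2)  # limited by R again
  expect_error(series_limiter(2, 0), "positive")
  expect_error(series_limiter(2, -0.5), "positive")
})

test_that("coverage_query stores phi = l/L and validates its domain", {
  q <- coverage_query(2, 60, 100, 1.0)
  expect_identical(q$phi, 60 / 100)
  expect_equal(q$eta, 1)
  expect_error(coverage_query(-1, 60, 100), "non-negative")
  expect_error(coverage_query(2.5, 60, 100), "non-negative integer")
  expect_error(coverage_query(2, 0, 100), "positive")
  expect_error(coverage_query(2, 60, 100, 0), "abundance")
  expect_error(coverage_query(2, 60, 100, 1.5), "abundance")
  # non-integer lengths are fine; only phi matters
  expect_silent(coverage_query(2, 60.5, 100.25))
})

test_that("worked examples match geometric and enumeration oracles", {
  # two arcs of 0.6 on the unit circle: the second closes the single gap
  # iff it starts in [0.4, 0.6], measure 0.2
  q1 <- coverage_query(2, 60, 100, 1.0)
  expect_equal(full_coverage_probability(q1), 0.2, tolerance = 1e-9)
  expect_equal(gap_probability(q1, 1), 0.8, tolerance = 1e-9)
  expect_equal(gap_probability(q1, 2), 0.0)  # k = 2 > eta = 1

  # binomial thinning at alpha = 0.5, enumerated by hand:
  # P(B=0) = 0.25*1 (no on-target read) + 2*0.25*0 + 0.25*0.2 = 0.30
  q2 <- coverage_query(2, 60, 100, 0.5)
  expect_equal(full_coverage_probability(q2), 0.30, tolerance = 1e-9)
  expect_equal(gap_probability(q2, 1), 0.70, tolerance = 1e-9)

  # eta = 1 at phi = 0.6, so the series is 1 - C(10,1)*0.5*(0.7)^9
  q3 <- coverage_query(10, 60, 100, 0.5)
  expect_equal(full_coverage_probability(q3), 1 - 5 * 0.7^9,
               tolerance = 1e-9)

  # two half-circle arcs only meet at a measure-zero antipodal placement
  expect_equal(full_coverage_probability(coverage_query(2, 50, 100, 1)), 0,
               tolerance = 1e-9)
})

test_that("degenerate inputs follow the no-reads-no-gaps convention", {
  expect_equal(full_coverage_probability(coverage_query(0, 60, 100, 1)), 1)
  expect_equal(full_coverage_probability(coverage_query(0, 60, 100, 0.3)), 1)
  # phi >= 1: any on-target read covers everything, eta = 0, P(B=0) = 1
  expect_equal(full_coverage_probability(coverage_query(7, 120, 100, 1)), 1)
  expect_equal(full_coverage_probability(coverage_query(1, 100, 100, 1)), 1)
  d0 <- gap_distribution(coverage_query(0, 60, 100, 1), k_max = 0)
  expect_equal(unname(d0$probabilities), 1)
})

test_that("gap_probability validates k", {
  q <- coverage_query(2, 60, 100, 1)
  expect_error(gap_probability(q, -1), "non-negative")
  expect_error(gap_probability(q, 3), "exceed")
  expect_error(gap_probability(q, 0.5), "non-negative integer")
})

test_that("for alpha = 1 the series reduces to classic Stevens covering", {
  for (R in c(1, 2, 3, 5, 10, 25)) {
    for (phi in c(0.3, 0.6, 0.9, 0.05)) {
      q <- coverage_query(R, phi * 1000, 1000, 1)
      expect_equal(full_coverage_probability(q),
                   viroplan:::stevens_classic(R, q$phi),
                   tolerance = 1e-12,
                   info = sprintf("R=%d phi=%g", R, phi))
    }
  }
})

test_that("gap distribution normalises and agrees with the k = 0 route", {
  for (R in c(1, 3, 5, 10)) {
    for (alpha in c(0.25, 0.5, 1)) {
      q <- coverage_query(R, 30, 100, alpha)
      d <- gap_distribution(q, k_max = R)
      expect_equal(sum(d$probabilities), 1, tolerance = 1e-9,
                   info = sprintf("R=%d alpha=%g", R, alpha))
      expect_true(all(d$probabilities >= 0 & d$probabilities <= 1))
      expect_equal(unname(d$probabilities["0"]),
                   full_coverage_probability(q), tolerance = 1e-12)
    }
  }
})

test_that("full coverage probability is monotone for alpha = 1", {
  # in R at fixed phi
  p_by_R <- vapply(1:15, function(R)
    full_coverage_probability(coverage_query(R, 30, 100, 1)), numeric(1))
  expect_true(all(diff(p_by_R) >= -1e-12))
  # in phi at fixed R
  p_by_phi <- vapply(seq(0.1, 0.9, by = 0.1), function(phi)
    full_coverage_probability(coverage_query(8, phi * 100, 100, 1)),
    numeric(1))
  expect_true(all(diff(p_by_phi) >= -1e-12))
})

test_that("evaluate_stable honours its acceptance and failure contracts", {
  # identity case: constant series stabilises at the starting precision
  res <- evaluate_stable(function(bits) 1.0)
  expect_equal(res$value, 1.0)
  expect_equal(res$precision_bits, 128L)

  # sub-1e-300 values compare absolutely: these evaluations differ by a
  # factor of two yet both count as a stable (numerically zero) result
  tiny <- evaluate_stable(function(bits) 1e-310 * (bits %/% 128))
  expect_lt(abs(tiny$value), 1e-300)

  # a sequence that never settles must raise a typed non-convergence error
  flip <- local({
    i <- 0
    function(bits) {
      i <<- i + 1
      if (i %% 2 == 0) 1 else 2
    }
  })
  expect_error(evaluate_stable(flip, start_bits = 64L, max_bits = 256L),
               class = "viroplan_nonconvergence")
  expect_error(evaluate_stable(function(bits) 1, start_bits = 16L),
               "at least 64")
})

test_that("cancellation-heavy series evaluate inside [0, 1]", {
  # C(1000, 199) ~ 1e216 overflows double precision; the alternating sum
  # only makes sense in extended precision
  q <- coverage_query(1000, 5, 1000, 1)
  expect_equal(q$eta, 199)
  p <- full_coverage_probability(q)
  expect_true(p >= 0 && p <= 1)
  # 1000 arcs of 5/1000: expected coverage 5x, full closure still unlikely;
  # cross-check against the classic-series route at escalated precision
  expect_equal(p, viroplan:::stevens_classic(1000, 0.005), tolerance = 1e-10)
})
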