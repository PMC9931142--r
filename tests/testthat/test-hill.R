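p <- default_parameters()

test_that("sweeps respect coupling, domains and monotonicity", {
  tied <- sweep_response(p, "S1")
  expect_s3_class(tied, "response_curve")
  expect_equal(max(tied$xs), 0.91 / 1.13)
  expect_true(all(diff(tied$ys) >= 0))
  eph <- sweep_response(p, "ephrin", fixed = list(S1 = 0.3))
  expect_true(all(diff(eph$ys) <= 0))
  # independent S1 sweep matches pointwise re-evaluation
  ind <- sweep_response(p, "S1", fixed = list(S2 = 0.3),
                        coupling = "independent", n = 21)
  manual <- vapply(ind$xs, function(s)
    aline_cell_response(p, data.frame(S1 = s, S2 = 0.3))$erk_star, numeric(1))
  expect_equal(ind$ys, manual, tolerance = 1e-12)
  expect_equal(max(ind$xs), 0.7)   # 1 - S2
  # inconsistent coupling specifications fail fast
  expect_error(sweep_response(p, "S1", coupling = "independent"),
               "requires the other surface")
  expect_error(sweep_response(p, "S1", fixed = list(S2 = 0.3)), "tied")
  expect_error(sweep_response(p, "erk_star"), "otx")
})

test_that("curve fitting recovers the exponent of ideal Hill data", {
  for (n_true in c(0.8, 2, 6)) {
    cv <- ideal_hill_curve(n_true, K = 0.4)
    fit <- fit_hill(cv)
    expect_equal(fit$n_hill, n_true, tolerance = 1e-6)
    expect_equal(fit$half_point, 0.4, tolerance = 1e-6)
  }
  # decreasing data are reflected and fit with the same family
  dec <- ideal_hill_curve(2, K = 0.4, decreasing = TRUE)
  fit <- fit_hill(dec)
  expect_equal(fit$n_hill, 2, tolerance = 1e-6)
  expect_identical(fit$direction, "decreasing")
  # a free baseline is recovered when asked for
  shifted <- ideal_hill_curve(2, K = 0.4, baseline = 0.2)
  expect_equal(fit_hill(shifted, baseline = "free")$n_hill, 2,
               tolerance = 1e-5)
  expect_error(fit_hill(list(xs = 0:100 / 100, ys = rep(1, 101))), "flat")
})

test_that("the potency formula is exact on ideal Hill curves", {
  # the domain must span saturation: the formula reads 10%/90% of the
  # maximal response, and the maximum is taken over the evaluated domain
  for (n_true in c(1, 2.5, 6)) {
    cv <- ideal_hill_curve(n_true, K = 0.3, xs = saturating_grid(0.3))
    expect_equal(hill_from_potency(cv)$n_hill, n_true, tolerance = 1e-3)
  }
})

test_that("the potency estimate is invariant to affine response rescaling", {
  cv <- sweep_response(p, "erk_star", n = 2001, response = "otx")
  n0 <- hill_from_potency(cv)$n_hill
  cv$ys <- 7.3 * cv$ys + 42
  expect_equal(hill_from_potency(cv)$n_hill, n0, tolerance = 1e-9)
})

test_that("fit and potency estimators agree on ideal data, diverge on model curves", {
  cv <- ideal_hill_curve(2, K = 0.4, xs = saturating_grid(0.4))
  n_fit <- fit_hill(cv)$n_hill
  n_pot <- hill_from_potency(cv)$n_hill
  expect_lt(abs(n_fit - n_pot) / n_fit, 0.1)
  # saturating model curve: different estimators of steepness, same ballpark
  mc <- sweep_response(p, "erk_star", n = 2001, response = "otx")
  expect_lt(abs(fit_hill(mc)$n_hill - hill_from_potency(mc)$n_hill) /
              fit_hill(mc)$n_hill, 0.25)
  # without the repressor the Hill shape fits the curve poorly and the two
  # estimators drift further apart -- the reason the potency formula is used
  mc0 <- sweep_response(p, "erk_star", n = 2001, response = "otx",
                        repressor = FALSE)
  gap0 <- abs(fit_hill(mc0)$n_hill - hill_from_potency(mc0)$n_hill) /
    fit_hill(mc0)$n_hill
  gap1 <- abs(fit_hill(mc)$n_hill - hill_from_potency(mc)$n_hill) /
    fit_hill(mc)$n_hill
  expect_gt(gap0, gap1)
})

test_that("ephrin presence steepens the ERK response to contact area", {
  n_with <- fit_hill(sweep_response(p, "S1"))$n_hill
  n_without <- fit_hill(sweep_response(apply_scenario(p, "NVP"), "S1"))$n_hill
  expect_gt(n_with, n_without)
})

test_that("heatmap scans report per-value Hill differences", {
  args_a <- list(x_name = "S1", n = 101)
  args_b <- list(x_name = "FGF", fixed = list(S1 = 0.3), n = 101)
  hm <- hill_difference_heatmap(p, args_a, args_b, "Kb",
                                scan_values = c(0.1, 0.2, 0.4))
  expect_equal(nrow(hm), 3)
  expect_equal(hm$delta, hm$n_b - hm$n_a)
  # at the default Kb the entries reproduce the single-curve fits
  i <- which(hm$scan_value == 0.2)
  expect_equal(hm$n_a[i], fit_hill(do.call(sweep_response,
    c(list(params = p), args_a)))$n_hill, tolerance = 1e-8)
  # scanning a parameter that affects neither curve gives a constant row
  hm0 <- hill_difference_heatmap(p, args_a, args_b, "vb",
                                 scan_values = c(0.0005, 0.001, 0.002))
  expect_equal(diff(range(hm0$n_a)), 0, tolerance = 1e-10)
  expect_equal(diff(range(hm0$delta)), 0, tolerance = 1e-10)
  expect_error(hill_difference_heatmap(p, args_a, args_b, "nope", 1),
               "parameter field")
})
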