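test_that("state classification follows the lambda/chi cutoff rules", {
  cz <- state_cutoffs()
  expect_equal(as.character(classify_state(0.9, 0.1, cz)), "deprotonated")
  expect_equal(as.character(classify_state(0.1, 0.5, cz)), "discarded")
  expect_equal(as.character(classify_state(0.5, 0.9, cz)), "discarded")
  expect_equal(as.character(classify_state(0.1, 0.1, cz)), "protonated")
  # boundary values belong to the pure bands, the mixed chi band is open
  expect_equal(as.character(classify_state(0.8, 0.9, cz)), "deprotonated")
  expect_equal(as.character(classify_state(0.2, 0.1, cz)), "protonated")
  expect_equal(as.character(classify_state(0.9, 0.2, cz)), "discarded")
  # single-site residues: chi purity vacuously true
  expect_equal(as.character(classify_state(c(0.95, 0.05), NA_real_, cz)),
               c("deprotonated", "protonated"))
  expect_error(classify_state(1.2, 0.1, cz, residue_id = "ASP6"), "ASP6")
  expect_error(classify_state(0.5, -0.1, cz), "chi")
  expect_error(state_cutoffs(deprot_lambda_min = 0.1, prot_lambda_max = 0.5),
               "ordering")
})

test_that("count_states matches an independent per-record tally and keeps the partition", {
  cz <- state_cutoffs()
  # direct tallies
  rec <- data.frame(frame = 0:99, residue_id = "ASP1",
                    lambda = rep(c(0.9, 0.1), c(80, 20)), chi = 0.05)
  rec <- rec[order(rec$frame), ]
  cnt <- count_states(rec, cz)
  expect_equal(c(cnt$n_deprot, cnt$n_prot, cnt$n_discarded, cnt$n_total),
               c(80L, 20L, 0L, 100L))
  idn <- data.frame(frame = 0:49, residue_id = "GLU2", lambda = 1, chi = 0)
  cid <- count_states(idn, cz)
  expect_equal(c(cid$n_deprot, cid$n_prot, cid$n_discarded), c(50L, 0L, 0L))
  # brute-force re-count oracle over random series
  for (seed in c(11L, 12L, 13L)) {
    r <- random_records(1000L, seed)
    cnt <- count_states(r, cz)
    orc <- naive_tally(r, cz)
    expect_equal(cnt$n_deprot, unname(orc["n_deprot"]))
    expect_equal(cnt$n_prot, unname(orc["n_prot"]))
    expect_equal(cnt$n_discarded, unname(orc["n_discarded"]))
    expect_equal(cnt$n_deprot + cnt$n_prot + cnt$n_discarded, cnt$n_total)
  }
  expect_error(count_states(rec[0, ], cz), "empty")
  two <- rbind(rec, idn)
  expect_error(count_states(two, cz), "one residue")
})

test_that("deprotonated fraction excludes discarded frames and flags undefined points", {
  expect_equal(deprotonated_fraction(list(n_deprot = 80, n_prot = 20)), 0.8)
  expect_equal(deprotonated_fraction(list(n_deprot = 0, n_prot = 50)), 0)
  expect_equal(deprotonated_fraction(list(n_deprot = 7, n_prot = 0)), 1)
  expect_warning(out <- deprotonated_fraction(list(n_deprot = 0, n_prot = 0)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("cumulative fraction series converges and agrees with the full-series count", {
  cz <- state_cutoffs()
  alt <- data.frame(frame = 0:199, residue_id = "ASP1",
                    lambda = rep(c(0.95, 0.05), 100), chi = NA_real_)
  s <- cumulative_fraction_series(alt, cz)
  expect_equal(s$cumulative_fraction[200], 0.5)
  const <- data.frame(frame = 0:49, residue_id = "ASP1", lambda = 1,
                      chi = NA_real_)
  expect_true(all(cumulative_fraction_series(const, cz)$cumulative_fraction == 1))
  # internal consistency: last element equals the full-series fraction
  r <- random_records(500L, 21L)
  s <- cumulative_fraction_series(r, cz)
  expect_equal(s$cumulative_fraction[500],
               deprotonated_fraction(count_states(r, cz)))
  # undefined prefix stays NA, never interpolated
  pre <- data.frame(frame = 0:3, residue_id = "ASP1",
                    lambda = c(0.5, 0.5, 0.9, 0.1), chi = NA_real_)
  s <- cumulative_fraction_series(pre, cz)
  expect_true(all(is.na(s$cumulative_fraction[1:2])))
  expect_equal(s$cumulative_fraction[3:4], c(1, 0.5))
})

test_that("charge interpolation is linear with exact end states", {
  cs <- charge_set(c("OD1", "OD2", "CG"), q_prot = c(-0.55, -0.61, 0.75),
                   q_deprot = c(-0.76, -0.76, 0.62))
  expect_equal(unname(interpolate_charges(1, cs)), cs$q_deprot)
  expect_equal(unname(interpolate_charges(0, cs)), cs$q_prot)
  cs1 <- charge_set("O", q_prot = 0.1, q_deprot = -0.5)
  expect_equal(unname(interpolate_charges(0.5, cs1)), -0.2)
  # linearity: q(a) + q(b) = 2 q((a+b)/2), element-wise
  set.seed(3)
  for (k in 1:10) {
    ab <- runif(2)
    expect_equal(interpolate_charges(ab[1], cs) + interpolate_charges(ab[2], cs),
                 2 * interpolate_charges(mean(ab), cs))
  }
  expect_error(charge_set(c("A", "B"), 1, c(1, 2)), "equal length")
  expect_error(interpolate_charges(1.5, cs), "\\[0,1\\]")
})

test_that("the Hill curve is monotone and the fit is self-consistent at its midpoint", {
  ph <- seq(0, 14, by = 0.1)
  for (n in c(0.5, 1, 2)) expect_true(all(diff(hh_curve(ph, 7, n)) > 0))
  # noiseless self-consistency
  pts <- data.frame(ph = 3:7, fraction_deprot = hh_curve(3:7, 4.0, 1.0))
  fit <- fit_titration_curve(pts, "ASP1")
  expect_true(fit$converged)
  expect_equal(fit$pka, 4.0, tolerance = 1e-6)
  expect_equal(fit$hill_n, 1.0, tolerance = 1e-6)
  expect_lt(abs(predict(fit, fit$pka) - 0.5), 1e-9)
  # property: midpoint self-consistency for perturbed point sets
  set.seed(17)
  for (k in 1:20) {
    truth <- c(runif(1, 3.5, 6.5), runif(1, 0.7, 1.5))
    S <- hh_curve(3:7, truth[1], truth[2]) +
      rnorm(5, 0, 0.02)
    f <- fit_titration_curve(data.frame(ph = 3:7,
                                        fraction_deprot = pmin(1, pmax(0, S))))
    if (f$converged)
      expect_lt(abs(hh_curve(f$pka, f$pka, f$hill_n) - 0.5), 1e-9)
  }
})

test_that("fitting agrees with an independent nonlinear least-squares route", {
  skip_if_not_installed("minpack.lm")
  set.seed(5)
  S <- pmin(1, pmax(0, hh_curve(3:7, 4.6, 1.1) + rnorm(5, 0, 0.03)))
  pts <- data.frame(ph = 3:7, fraction_deprot = S)
  fit <- fit_titration_curve(pts, "GLU1")
  ref <- minpack.lm::nlsLM(S ~ 1 / (1 + 10^(n * (pka - ph))),
                           data = data.frame(ph = 3:7, S = S),
                           start = list(pka = 5, n = 1),
                           lower = c(-10, 1e-3), upper = c(20, 50))
  expect_equal(fit$pka, coef(ref)[["pka"]], tolerance = 1e-4)
  expect_equal(fit$hill_n, coef(ref)[["n"]], tolerance = 1e-4)
})

test_that("degenerate titrations report one-sided bounds instead of extrapolating", {
  hi <- data.frame(ph = 3:7, fraction_deprot = c(0.97, 0.98, 0.99, 1, 1))
  f <- fit_titration_curve(hi, "ASP1")
  expect_false(f$converged)
  expect_equal(f$ph_range_flag, "below_grid")
  expect_equal(f$pka, 3)
  lo <- data.frame(ph = 3:7, fraction_deprot = c(0, 0.01, 0.01, 0.02, 0.04))
  f <- fit_titration_curve(lo, "HIS1")
  expect_equal(f$ph_range_flag, "above_grid")
  expect_equal(f$pka, 7)
  expect_error(predict(f, 5), "non-converged")
  # undefined points are dropped with a warning; too few points rejected
  pts <- data.frame(ph = 3:7,
                    fraction_deprot = c(0.1, NA, 0.5, NA, NA))
  expect_warning(expect_error(fit_titration_curve(pts), "at least 3"),
                 "dropping")
})

test_that("count weighting pulls the fit toward well-sampled pH points", {
  set.seed(8)
  pts <- data.frame(ph = 3:7,
                    fraction_deprot = c(0.08, 0.45, 0.93, 0.99, 0.999),
                    n_deprot = c(80, 4500, 930, 99, 999),
                    n_prot = c(920, 5500, 70, 1, 1))
  fw <- fit_titration_curve(pts, weights = "counts")
  fu <- fit_titration_curve(pts)
  expect_true(fw$converged && fu$converged)
  expect_false(isTRUE(all.equal(fw$pka, fu$pka)))
  expect_error(fit_titration_curve(pts, weights = "bogus"), "weights")
})

test_that("pKa shifts subtract the type reference with the documented sign convention", {
  pts <- data.frame(ph = 1:5, fraction_deprot = hh_curve(1:5, 3.0, 1.0))
  fit <- fit_titration_curve(pts, "ASP6")
  ref <- reference_pka_table(c(ASP = 4.0, GLU = 4.4, HIS = 6.5))
  expect_equal(pka_shift(fit, ref), -1.0, tolerance = 1e-6)
  pts2 <- data.frame(ph = 2:6, fraction_deprot = hh_curve(2:6, 4.0, 1.0))
  expect_equal(pka_shift(fit_titration_curve(pts2, "ASP11"), ref), 0,
               tolerance = 1e-6)
  # raised pKa -> positive shift
  pts3 <- data.frame(ph = 3:8, fraction_deprot = hh_curve(3:8, 5.3, 1.0))
  expect_gt(pka_shift(fit_titration_curve(pts3, "ASP11"), ref), 1)
  expect_error(pka_shift(fit_titration_curve(pts2, "LYS1"), ref),
               "no reference")
  bad <- fit_titration_curve(data.frame(ph = 3:7,
                                        fraction_deprot = rep(0.99, 5)),
                             "ASP1")
  expect_error(pka_shift(bad, ref), "converged")
})

test_that("titration records survive a TSV round trip and malformed files are rejected", {
  rec <- random_records(200L, 31L)
  f <- tempfile(fileext = ".tsv")
  write_titration_records(rec, f, ph = 4.5)
  back <- read_titration_records(f)
  expect_equal(attr(back, "ph"), 4.5)
  expect_equal(back$lambda, rec$lambda, tolerance = 1e-9)
  expect_equal(back$chi, rec$chi, tolerance = 1e-9)
  expect_equal(back$frame, rec$frame)
  # chi-absent records round trip as NA
  rec2 <- random_records(10L, 32L, with_chi = FALSE)
  f2 <- tempfile(fileext = ".tsv")
  write_titration_records(rec2, f2, ph = 7)
  expect_true(all(is.na(read_titration_records(f2)$chi)))
  writeLines(c("frame\tresidue_id\tlambda\tchi", "0\tASP1\t0.5\t0.5"), f2)
  expect_error(read_titration_records(f2), "header")
})
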