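# Barrier/stepping extraction and cap-length estimation.

mk_trace <- function(e, converged = TRUE) {
  structure(list(e_total = e, converged = converged,
                 steps_taken = length(e), peak_energy = max(e),
                 e_initial = e[1], e_final = e[length(e)],
                 components = NULL),
            class = "mt_trace")
}

test_that("barrier and stepping are the peak and endpoint offsets", {
  p <- mt_params(kBT_internal = 1)   # unit conversion factor of one
  out <- extract_barrier_and_stepping(mk_trace(c(10, 50, 12)), 10, p)
  expect_equal(unname(out["barrier"]), 40)
  expect_equal(unname(out["stepping"]), 2)
  # monotone decreasing trace from equilibrium: no transient peak
  out2 <- extract_barrier_and_stepping(mk_trace(c(20, 15, 12)), 20, p)
  expect_equal(unname(out2["barrier"]), 0)
  # kBT conversion
  p2 <- mt_params()
  out3 <- extract_barrier_and_stepping(mk_trace(c(10, 50, 12)), 10, p2)
  expect_equal(unname(out3["barrier"]), 40 / p2$kBT_internal)
  expect_error(extract_barrier_and_stepping(
    mk_trace(c(10, 5), converged = FALSE), 10, p), "converge")
})

test_that("barrier and stepping are invariant to a uniform energy offset", {
  p <- mt_params(kBT_internal = 1)
  e <- c(3, 9, 4, 2)
  a <- extract_barrier_and_stepping(mk_trace(e), 3, p)
  b <- extract_barrier_and_stepping(mk_trace(e + 100), 103, p)
  expect_equal(a, b)
})

test_that("minimum stable cap detects the plateau drop", {
  sweep <- data.frame(sheet_length = 1:6,
                      barrier_kBT = c(1, 1, 1, 10, 10, 10))
  expect_equal(minimum_stable_cap(sweep, tolerance = 0.1), 2L)
  # flat sweep: everything is on the plateau
  flat <- data.frame(sheet_length = 1:6, barrier_kBT = rep(7, 6))
  expect_equal(minimum_stable_cap(flat, tolerance = 0.1), 1L)
  # invariant to uniform rescaling of all barriers
  sweep2 <- sweep
  sweep2$barrier_kBT <- sweep2$barrier_kBT * 137
  expect_equal(minimum_stable_cap(sweep2, tolerance = 0.1), 2L)
  # order of rows must not matter
  expect_equal(minimum_stable_cap(sweep[sample(6), ], tolerance = 0.1), 2L)
})
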