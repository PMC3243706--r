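# Experiment orchestration: closure sequences and Tetris growth.

test_that("a zero-closure sequence is a no-op", {
  p <- fast_params()
  st <- standard_sheet_state(p, n_closed_turns = 4, sheet_length = 3)
  out <- run_closure_sequence(st, n_closures = 0)
  expect_equal(nrow(out$result), 0L)
  expect_identical(out$state$lattice$monomers, st$lattice$monomers)
  expect_identical(out$state$conf$pos, st$conf$pos)
  expect_equal(out$state$E0, st$E0)
})

test_that("tetris fills a layer with 13 dimers and then zips one dimer length", {
  p <- fast_params()
  set.seed(41)
  st <- standard_sheet_state(p, n_closed_turns = 5, sheet_length = 4)
  n0 <- nrow(st$lattice$monomers)
  s0 <- mtzip:::sheet_length(st$lattice)
  tt <- run_tetris(p, n_layers = 1, state = st, force_accept = TRUE,
                   max_steps = 20000L)
  expect_false(tt$stalled)
  expect_equal(tt$completed_layers, 1L)
  ev <- tt$events
  expect_equal(sum(ev$event == "assembly"), 13L)
  expect_equal(sum(ev$event == "closure"), 2L)
  # assemblies first, closures last
  expect_true(all(which(ev$event == "closure") > sum(ev$event == "assembly")))
  # 26 monomers added per completed layer
  expect_equal(nrow(tt$state$lattice$monomers), n0 + 26L)
  # the sheet returns to its starting length after the full cycle
  expect_equal(ev$sheet_length[nrow(ev)], s0)
  # every protofilament received exactly one dimer
  expect_equal(sort(ev$pf[ev$event == "assembly"]), 0:12)
})

test_that("closure running ahead of assembly exhausts the sheet", {
  p <- fast_params()
  st <- standard_sheet_state(p, n_closed_turns = 5, sheet_length = 2)
  # no assembly: two closures empty the open seam, a third is impossible
  s1 <- close_monomer_pair(st$lattice, st$conf, p, E_before = st$E0)
  expect_equal(mtzip:::sheet_length(s1$lattice), 1L)
  s2 <- close_monomer_pair(s1$lattice, s1$conf, p,
                           E_before = s1$trace$e_final)
  expect_equal(mtzip:::sheet_length(s2$lattice), 0L)
  expect_error(close_monomer_pair(s2$lattice, s2$conf, p),
               "blunt|zipped")
})

test_that("sensitivity sweep at factor one reproduces the standard closure", {
  p <- fast_params()
  res <- run_sensitivity_sweep(p, constant = "k_diag", factors = 1,
                               n_closed_turns = 5, sheet_length = 4)
  ref <- run_single_closure(p, n_closed_turns = 5, sheet_length = 4,
                            curl_deg = p$theta0_long_GTP)
  expect_equal(res$barrier_kBT, ref$barrier_kBT, tolerance = 1e-10)
  expect_equal(res$stepping_kBT, ref$stepping_kBT, tolerance = 1e-10)
})
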