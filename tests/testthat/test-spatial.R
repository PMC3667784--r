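test_that("the default lattice carries a 49-compartment invadopodium disc", {
  g <- buildGrid()
  expect_identical(length(g@mask), 49L)
  ## compartment size ~0.098 um; disc diameter ~0.9 um
  h <- g@extent[1] / g@divisions[1]
  expect_equal(h, 5e-6 / 51)
  nx <- g@divisions[1]
  ix <- (g@mask - 1) %% nx + 1; iy <- (g@mask - 1) %/% nx + 1
  diam <- (max(ix) - min(ix) + 1) * h
  expect_equal(diam * 1e6, 0.88, tolerance = 0.05)
  ## disc area consistent with pi r^2 at the compartment scale
  expect_equal(49 * h^2, pi * (0.45e-6)^2, tolerance = 0.05)
  ## five invadopodia: disjoint discs, five times the area
  g5 <- buildGrid(n_invadopodia = 5)
  expect_identical(length(g5@mask), 5L * 49L)
  expect_error(buildGrid(divisions = c(7, 7, 1)), "clipped")
  expect_error(buildGrid(divisions = c(50, 50, 1)), "odd")
})

test_that("zero diffusion reduces to independent well-mixed compartments", {
  net <- buildPoolsNetwork(par0, ecm = TRUE, preassembled = FALSE)
  g <- buildGrid(divisions = c(11, 11, 1), mask_radius = 1.2, D = 0)
  sp <- speciesTable(net)
  y <- stats::setNames(numeric(nrow(sp)), sp$name)
  y[c("T2", "M2", "ECM")] <- c(100, par0$M2_0, par0$ECM_0)
  field <- matrix(y, nrow = nrow(sp), ncol = 121)
  field[match(c("M14X", "M14D"), sp$name), g@mask] <- c(1.5, 3.5)
  fs <- invadosim:::.run_spatial(net, g, field, t_end = 20, dt = 0.01,
                                 trace_stride = 50L)
  ref <- integrateRK4(net, c(T2 = 100, M2 = par0$M2_0, ECM = par0$ECM_0,
                             M14X = 1.5, M14D = 3.5),
                      t_end = 20, dt = 0.01, out_stride = 50L)
  i <- nrow(ref@states)
  expect_equal(unname(fs@trace[nrow(fs@trace), ]),
               unname(ref@states[i, ]), tolerance = 1e-8)
})

test_that("free diffusion spreads a point source with variance 4 D t", {
  p0 <- par0
  for (nm in grep("^k", names(p0), value = TRUE)) p0[[nm]] <- 0
  net <- buildCoreNetwork(p0, pools = "XD", preassembled = FALSE)
  D <- 5e-15
  g <- buildGrid(divisions = c(41, 41, 1), mask_radius = 1.2,
                 diffusing = c("T2", "M2", "M2act", "T2.M2act"), D = D)
  sp <- speciesTable(net)
  field <- matrix(0, nrow = nrow(sp), ncol = 41 * 41)
  centre <- (41 * 41 + 1) / 2
  field[match("T2", sp$name), centre] <- 1000
  t_end <- 40
  fs <- invadosim:::.run_spatial(net, g, field, t_end = t_end, dt = 0.05,
                                 snap_times = t_end)
  sn <- fs@snaps[[1]]
  h <- g@extent[1] / 41
  v <- sn[match("T2", sp$name), ]
  ix <- ((seq_along(v) - 1) %% 41 - 20) * h
  iy <- ((seq_along(v) - 1) %/% 41 - 20) * h
  W <- v / sum(v)
  varsum <- sum(W * (ix^2 + iy^2))
  expect_equal(varsum, 4 * D * t_end, tolerance = 0.02)
  ## diffusing mass conserved under closed boundaries
  expect_equal(sum(v), 1000, tolerance = 1e-10)
})

test_that("uniform fields are fixed points of pure diffusion", {
  p0 <- par0
  for (nm in grep("^k", names(p0), value = TRUE)) p0[[nm]] <- 0
  net <- buildCoreNetwork(p0, pools = "XD", preassembled = FALSE)
  g <- buildGrid(divisions = c(11, 11, 1), mask_radius = 1.2, D = 2e-13)
  sp <- speciesTable(net)
  field <- matrix(0, nrow = nrow(sp), ncol = 121)
  field[match("T2", sp$name), ] <- 42
  fs <- invadosim:::.run_spatial(net, g, field, t_end = 5, dt = 0.01,
                                 snap_times = 5)
  expect_equal(unname(fs@snaps[[1]][match("T2", sp$name), ]),
               rep(42, 121), tolerance = 1e-12)
})

test_that("line scans locate the degradation focus and preserve symmetry", {
  g <- buildGrid(D = 2e-13)
  fs <- runFocalDegradation(par0, T2 = 50, "continuous", "present", g,
                            t_end = 20, dt = 0.01, snap_times = c(10, 20))
  sc <- lineScan(fs)
  expect_identical(dim(sc), c(51L, 2L))
  ## minimum of the ECM profile inside the mask columns
  expect_true(abs(which.min(sc[, 2]) - 26) <= 4)
  ## symmetric geometry: scan symmetric about the centre
  expect_equal(sc[1:25, 2], rev(sc[27:51, 2]), tolerance = 1e-8)
  ## uniform species scan is constant
  scm2 <- lineScan(fs, species = "M2")
  expect_lt(diff(range(scm2[, 1])) / mean(scm2[, 1]), 0.05)
})

test_that("the explicit stepper advances a field by one operator-split step", {
  net <- buildPoolsNetwork(par0, ecm = TRUE, preassembled = FALSE)
  g <- buildGrid(divisions = c(11, 11, 1), mask_radius = 1.2, D = 2e-13)
  sp <- speciesTable(net)
  y <- stats::setNames(numeric(nrow(sp)), sp$name)
  y[c("T2", "M2", "ECM")] <- c(100, 100, 1000)
  field <- matrix(y, nrow = nrow(sp), ncol = 121)
  out <- stepReactionDiffusion(g, field, net, dt = 0.01)
  expect_identical(dim(out), dim(field))
  expect_false(identical(out, field))
})
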