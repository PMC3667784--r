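test_that("ECM reactions cover the five enzyme classes", {
  net <- buildCoreNetwork(par0, include_ecm = TRUE, pools = "XD")
  rx <- reactions(net)
  cleav <- rx[rx$tag == "ecm_cleavage", ]
  ## four MT1 classes per pool plus active MMP-2
  expect_identical(nrow(cleav), 9L)
  expect_true("M2act.ECM" %in% cleav$r1)
  expect_error(addEcmReactions(buildCoreNetwork(par0), par0), "ECM")
  ## zero cleavage rate: ECM constant forever
  p0 <- par0; p0$kcat_ecm <- 0; p0$kcat_ecm_m2a <- 0
  p0$kon_ecm <- 0; p0$kon_ecm_m2a <- 0
  tr <- runPoolsModel(p0, T2 = 0, ecm = TRUE, t_end = 200, dt = 0.02,
                      out_stride = 100L)
  expect_true(all(concentrations(tr, "ECM") == p0$ECM_0))
})

test_that("either enzyme route alone still degrades ECM", {
  ## MT1-only (MMP-2 routes silenced)
  p1 <- par0; p1$kon_ecm_m2a <- 0
  t1 <- runPoolsModel(p1, T2 = 0, ecm = TRUE, t_end = 400, dt = 0.02,
                      out_stride = 100L)
  expect_lt(concentrations(t1, "ECM")[nrow(t1@states), 1], p1$ECM_0)
  ## MMP-2-only: MT1 cannot engage ECM but still activates proMMP-2
  p2 <- par0; p2$kon_ecm <- 0
  t2 <- runPoolsModel(p2, T2 = 20, ecm = TRUE, t_end = 2000, dt = 0.02,
                      out_stride = 100L)
  expect_lt(concentrations(t2, "ECM")[nrow(t2@states), 1], p2$ECM_0)
})

test_that("tau-half interpolates the first half-degradation crossing", {
  ## exponential decay: tau_H = ln 2 / lambda
  net <- tiny_decay_network(k = 0.02)
  tr <- integrateRK4(net, c(ECM = 100), t_end = 100, dt = 0.01,
                     out_stride = 100L)
  expect_equal(tauHalf(tr), log(2) / 0.02, tolerance = 1e-4)
  ## never below 60%: explicit not-reached result
  tr2 <- integrateRK4(net, c(ECM = 100), t_end = 10, dt = 0.01,
                      out_stride = 100L)
  expect_true(is.na(tauHalf(tr2)))
})

test_that("ECM mass accounting closes against the cleavage flux", {
  tr <- runPoolsModel(par0, T2 = 0, ecm = TRUE, t_end = 300, dt = 0.02,
                      out_stride = 20L)
  sp <- speciesTable(tr)
  es <- sp$name[sp$ecm > 0 & sp$name != "ECM"]
  bound <- rowSums(concentrations(tr, es))
  kcat <- par0$kcat_ecm  # identical for both enzyme classes by default
  tt <- trajTimes(tr)
  flux <- kcat * bound
  cleaved <- c(0, cumsum(0.5 * (flux[-1] + flux[-length(flux)]) * diff(tt)))
  drop <- par0$ECM_0 - concentrations(tr, "ECM")[, 1] - bound
  expect_equal(cleaved, drop, tolerance = 5e-3)
})

test_that("integrated active-complex concentration behaves as an integral", {
  tr <- runPoolsModel(par0, T2 = 100, ecm = TRUE, t_end = 300, dt = 0.02,
                      out_stride = 20L)
  integ <- integratedActiveEcmComplex(tr)
  expect_identical(integ[1], 0)
  expect_true(all(diff(integ) >= 0))
  ## zero series integrates to zero
  p0 <- par0; p0$kon_ecm <- 0
  tr0 <- runPoolsModel(p0, T2 = 100, ecm = TRUE, t_end = 50, dt = 0.02,
                       out_stride = 20L)
  expect_true(all(integratedActiveEcmComplex(tr0) == 0))
})

test_that("the initial degradation rate recovers a linear slope", {
  net <- tiny_decay_network(k = 1e-4)   # quasi-linear over the window
  tr <- integrateRK4(net, c(ECM = 1000), t_end = 20, dt = 0.01,
                     out_stride = 10L)
  expect_equal(initialDegradationRate(tr, window = 10), 1e-4 * 1000,
               tolerance = 1e-3)
  expect_error(initialDegradationRate(tr, window = 1e-4), "2 samples")
})

test_that("regular and random insertion give similar degraded totals", {
  ## the integrated active MT1-ECM complex (the direct measure of degraded
  ## matrix) differs by < 10% between regular and random intervals
  vals <- vapply(1:10, function(s) {
    sched <- insertionSchedule(interval_mode = "random", seed = s)
    tr <- runPoolsModel(par0, T2 = 100, regimen = "pulsatile", sched = sched,
                        ecm = TRUE, t_end = 1200, dt = 0.05, out_stride = 40L)
    max(integratedActiveEcmComplex(tr))
  }, numeric(1))
  reg <- runPoolsModel(par0, T2 = 100, regimen = "pulsatile",
                       sched = insertionSchedule(), ecm = TRUE, t_end = 1200,
                       dt = 0.05, out_stride = 40L)
  regv <- max(integratedActiveEcmComplex(reg))
  expect_lt(abs(mean(vals) - regv) / regv, 0.10)
})
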