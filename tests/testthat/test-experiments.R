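test_that("M14a weighting counts the dimer twice and inhibited forms not at all", {
  net <- buildCoreNetwork(par0)
  y <- stats::setNames(numeric(nSpecies(net)), speciesNames(net))
  mk <- function(vals) {
    st <- matrix(rep(y, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, names(y)))
    for (nm in names(vals)) st[, nm] <- vals[[nm]]
    methods::new("Trajectory", times = c(0, 1), states = st,
                 species = speciesTable(net),
                 events = data.frame(time = numeric(0), pool = character(0),
                                     requested = numeric(0),
                                     applied = numeric(0)),
                 metadata = list())
  }
  expect_equal(computeM14a(mk(c(M14.M14 = 1))), c(2, 2))
  expect_equal(computeM14a(mk(c(M14.T2 = 5))), c(0, 0))
  expect_equal(computeM14a(mk(c(M14 = 1, M14.M14.T2 = 2,
                                M14.M14.T2.M2 = 3))), c(6, 6))
  expect_equal(computeM14a(mk(c())), c(0, 0))
})

test_that("half-width measures FWHM above the steady baseline", {
  t <- seq(0, 10, 0.01)
  tri <- pmax(0, 1 - abs(t - 5) / 5)
  expect_equal(halfWidth(t, tri, 0), 5, tolerance = 1e-3)
  ## nonzero plateau baseline
  expect_equal(halfWidth(t, tri + 2, 2), 5, tolerance = 1e-3)
  ## flat series has no transient
  expect_identical(halfWidth(t, rep(3, length(t)), 3), 0)
  ## series starting at its peak: width measured from the first sample
  dec <- exp(-t)
  expect_equal(halfWidth(t, dec, 0), log(2), tolerance = 1e-3)
})

test_that("the TIMP-2 titration is monotone with its knee at MT1 exhaustion", {
  sw <- sweepTimp2(values = c(0, 60, 100, 200), variant = "closed")
  expect_equal(sw$M14a_steady[1], 100, tolerance = 1e-6)  # no inhibitor
  expect_true(all(diff(sw$M14a_steady) < 0))
  expect_true(all(sw$t_transient > 0))
})

test_that("ensembles of identical schedules have zero spread", {
  ens <- runEnsemble(T2_values = 0, n_runs = 3, seeds = c(1, 5, 9),
                     interval_mode = "regular", amount_mode = "regular",
                     t_end = 600, dt = 0.05)
  expect_equal(ens$summary$sd, 0, tolerance = 1e-9)
  expect_equal(nrow(ens$raw), 3L)
})

test_that("presets return metrics tables and honour their seeds", {
  res <- runFigurePreset("s13")
  expect_true(is.data.frame(res$metrics))
  expect_identical(nrow(res$metrics), 2L)
  ## shedding at the default slow rate barely moves the activity peak
  expect_lt(abs(res$metrics$M14a_peak[2] - res$metrics$M14a_peak[1]) /
              res$metrics$M14a_peak[1], 0.05)
})
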