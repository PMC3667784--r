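test_that("species enumeration is closed, deterministic and variant-aware", {
  sp <- enumerateSpecies()
  expect_false(anyDuplicated(sp$name) > 0)
  ## highest-order inactive complex and full dimer ladder present
  expect_true(all(c("M14", "T2", "M2", "M2act", "T2.M2", "T2.M2act",
                    "M14.T2", "M14.T2.M2", "M14.M14", "M14.M14.T2",
                    "M14.M14.T2.M2", "M14.T2.M14.T2", "M14.T2.M14.T2.M2",
                    "M14.T2.M2.M14.T2.M2") %in% sp$name))
  ## activity weights: dimer 2; monomer and half-inhibited dimers 1; rest 0
  w <- stats::setNames(sp$activity_weight, sp$name)
  expect_identical(unname(w["M14.M14"]), 2)
  expect_identical(unname(w[c("M14", "M14.M14.T2", "M14.M14.T2.M2")]),
                   c(1, 1, 1))
  expect_true(all(w[setdiff(sp$name,
    c("M14.M14", "M14", "M14.M14.T2", "M14.M14.T2.M2"))] == 0))
  ## membrane species carry MT1; solution species do not (shed fragment aside)
  expect_true(all(sp$m14[sp$location != "solution"] >= 1))
  expect_true(all(sp$m14[sp$location == "solution"] == 0))

  spe <- enumerateSpecies(include_ecm = TRUE)
  expect_true(all(c("ECM", "M14.ECM", "M14.M14.ECM", "M14.M14.T2.ECM",
                    "M14.M14.T2.M2.ECM", "M2act.ECM") %in% spe$name))
  spx <- enumerateSpecies(pools = "XD")
  expect_true(all(c("M14X.M14X", "M14D", "M14X.T2.M14X.T2.M2") %in% spx$name))
  sps <- enumerateSpecies(include_shedding = TRUE)
  expect_true(all(c("M14f", "M14f.T2") %in% sps$name))
  expect_true(all(sps$m14[sps$name == "M14f"] == 1))
  ## deterministic enumeration order
  expect_identical(enumerateSpecies(TRUE, TRUE, "XD"),
                   enumerateSpecies(TRUE, TRUE, "XD"))
})

test_that("core network wiring matches the binding rules", {
  net <- buildCoreNetwork(par0)
  expect_true(validObject(net))
  rx <- reactions(net)
  ## reversible TIMP-2 binding to the free monomer
  expect_true(any(rx$tag == "binding" &
                  rx$r1 == "M14" & rx$r2 %in% "T2" & rx$p1 == "M14.T2"))
  expect_true(any(rx$tag == "dissociation" & rx$r1 == "M14.T2"))
  ## the activation step consumes the quaternary complex and releases M2act
  act <- rx[rx$tag == "activation", ]
  expect_identical(act$r1, "M14.M14.T2.M2")
  expect_true("M2act" %in% c(act$p1, act$p2))
  expect_identical(act$k, par0$k_act)
  ## missing constants are named
  bad <- par0; bad$kon_dim <- NULL
  expect_error(buildCoreNetwork(bad), "kon_dim")
})

test_that("a null-rate network has identically zero derivatives", {
  p0 <- par0
  for (nm in grep("^k", names(p0), value = TRUE)) p0[[nm]] <- 0
  net <- buildCoreNetwork(p0)
  v <- massActionRHS(net, c(M14 = 50, T2 = 30, M2 = 20, M2act = 5))
  expect_true(all(v == 0))
})

test_that("path deletions remove complexes consistently", {
  net <- buildCoreNetwork(par0)
  expect_identical(applyPathDeletions(net, integer(0)), net)
  nd <- applyPathDeletions(net, c(1, 2))
  expect_false(any(c("M14.T2.M2", "M14.T2.M2.M14.T2.M2") %in%
                     speciesNames(nd)))
  expect_true(validObject(nd))
  ## idempotent and commutative
  expect_identical(speciesNames(applyPathDeletions(nd, c(1, 2))),
                   speciesNames(nd))
  a <- applyPathDeletions(applyPathDeletions(net, 3), c(5, 1))
  b <- applyPathDeletions(applyPathDeletions(net, c(1, 5)), 3)
  expect_identical(speciesNames(a), speciesNames(b))
  expect_identical(reactions(a)$k, reactions(b)$k)
  ## deleting all inactive complexes leaves only the half-inhibited dimers
  ## as TIMP-2-carrying membrane species
  full <- applyPathDeletions(net, 1:5)
  spf <- speciesTable(full)
  inhibited <- spf$name[spf$location != "solution" & spf$t2 > 0]
  expect_setequal(inhibited, c("M14.M14.T2", "M14.M14.T2.M2"))
  ## pools variant: deletion applies to both pools
  nx <- applyPathDeletions(buildCoreNetwork(par0, pools = "XD"), 5)
  expect_false(any(c("M14X.T2", "M14D.T2") %in% speciesNames(nx)))
})

test_that("ectodomain shedding drains membrane MT1 and scavenges TIMP-2", {
  net <- buildCoreNetwork(par0)
  expect_error(addEctodomainShedding(net, -1), "k_shed")
  shed0 <- addEctodomainShedding(net, 0)
  shed <- addEctodomainShedding(net, 1e-3)
  expect_true(all(c("M14f", "M14f.T2") %in% speciesNames(shed)))
  y0 <- c(M14 = 100, T2 = 100, M2 = 100)
  t0 <- integrateRK4(buildCoreNetwork(par0), y0, t_end = 100, dt = 0.01,
                     out_stride = 100L)
  ta <- integrateRK4(shed0, y0, t_end = 100, dt = 0.01, out_stride = 100L)
  common <- speciesNames(t0)
  expect_equal(concentrations(ta, common), concentrations(t0, common),
               tolerance = 1e-12)
  ## with k_shed > 0, membrane MT1 monomer equivalents strictly decrease
  tb <- integrateRK4(shed, y0, t_end = 100, dt = 0.01, out_stride = 100L)
  sp <- speciesTable(shed)
  mem <- sp$name[sp$location != "solution"]
  memtot <- as.numeric(concentrations(tb, mem) %*%
                         sp$m14[match(mem, sp$name)])
  expect_lt(memtot[length(memtot)], memtot[1])
  ## total MT1 (membrane + shed fragment) still conserved
  ct <- conservationTotals(tb)
  expect_lt(diff(range(ct[, "m14"])) / ct[1, "m14"], 1e-8)
})

test_that("reaction table round-trips through the export format", {
  net <- buildCoreNetwork(par0)
  path <- tempfile(fileext = ".tsv")
  exportReactionTable(net, path)
  back <- readReactionTable(path, speciesTable(net))
  y0 <- c(M14 = 100, T2 = 100, M2 = 100)
  a <- integrateRK4(net, y0, t_end = 20, dt = 0.01, out_stride = 50L)
  b <- integrateRK4(back, y0, t_end = 20, dt = 0.01, out_stride = 50L)
  expect_equal(a@states, b@states, tolerance = 1e-12)
})
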