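test_that("FBA solves capacity-limited chains and sourceless exports", {
  m <- chainModel()
  expect_equal(fba(m, "E_C")$objective, 10, tolerance = 1e-9)
  expect_equal(maxProduction(m, "C_c"), 10, tolerance = 1e-9)
  # every chain flux is forced through at the optimum
  sol <- fba(m, "E_C")
  expect_equal(unname(sol$fluxes), rep(10, 4), tolerance = 1e-9)

  # a metabolite nothing produces cannot be exported
  mets <- rbind(metabolites(m),
                data.frame(id = "D_c", name = "D_c", compartment = "c",
                           boundary = FALSE))
  S <- rbind(as.matrix(stoichMatrix(m)), D_c = 0)
  m2 <- MetabolicModel(S, mets, reactions(m))
  expect_equal(maxProduction(m2, "D_c"), 0, tolerance = 1e-9)
})

test_that("FBA optimum matches the basic-feasible-solution oracle", {
  set.seed(202)
  for (i in 1:20) {
    net <- randomNetwork()
    j <- sample(net$n, 1)
    obj <- numeric(net$n); obj[j] <- 1
    got <- fba(net$model, paste0("r", j))$objective
    want <- bruteForceLP(net$S, net$lb, net$ub, obj)
    expect_equal(got, want, tolerance = 1e-6, info = paste("net", i))
  }
})

test_that("steady state holds at solver solutions", {
  set.seed(99)
  for (i in 1:5) {
    net <- randomNetwork()
    sol <- fba(net$model, paste0("r", sample(net$n, 1)))
    expect_lt(max(abs(net$S %*% sol$fluxes)), 1e-6)
    bounds <- fluxBounds(net$model)
    expect_true(all(sol$fluxes >= bounds[, "lb"] - 1e-9))
    expect_true(all(sol$fluxes <= bounds[, "ub"] + 1e-9))
  }
})

test_that("FVA pins unique pathways and frees parallel branches", {
  m <- chainModel()
  env <- fva(m, "E_C", optimalityFraction = 1)
  r <- fluxRanges(env)
  for (rx in c("E_A", "R_AB", "R_BC", "E_C")) {
    expect_equal(unname(r[rx, "min"]), 10, tolerance = 1e-6)
    expect_equal(unname(r[rx, "max"]), 10, tolerance = 1e-6)
  }

  p <- parallelModel()
  envp <- fva(p, "EX", optimalityFraction = 1)
  rp <- fluxRanges(envp)
  for (rx in c("BR1a", "BR1b", "BR2a", "BR2b")) {
    expect_equal(unname(rp[rx, "min"]), 0, tolerance = 1e-6)
    expect_equal(unname(rp[rx, "max"]), 10, tolerance = 1e-6)
  }
  expect_equal(unname(rp["EX", ]), c(10, 10), tolerance = 1e-6)
})

test_that("blocked reactions get a (0,0) envelope", {
  # B2 branch consumes a metabolite with no source once UP is closed
  p <- parallelModel()
  ri <- reactions(p)
  ri["BR2a", "ub"] <- 0   # starve B2
  p2 <- MetabolicModel(stoichMatrix(p), metabolites(p), ri)
  env <- fva(p2, "EX", optimalityFraction = 0)
  expect_equal(unname(fluxRanges(env)["BR2b", ]), c(0, 0),
               tolerance = 1e-9)
})

test_that("FBA optima lie inside the zero-fraction envelope", {
  set.seed(11)
  for (i in 1:5) {
    net <- randomNetwork()
    j <- sample(net$n, 1)
    sol <- fba(net$model, paste0("r", j))
    env <- fva(net$model, paste0("r", j), optimalityFraction = 0)
    r <- fluxRanges(env)
    expect_true(all(sol$fluxes >= r[, "min"] - 1e-6))
    expect_true(all(sol$fluxes <= r[, "max"] + 1e-6))
  }
})

test_that("tightening bounds never raises, scaling bounds rescales", {
  toy <- makeToyNetwork(2, 3, 0, 0, seed = 5)
  m <- toy$model
  met <- "m1_3_c"
  base <- maxProduction(m, met)
  set.seed(31)
  for (i in 1:5) {
    ri <- reactions(m)
    j <- sample(nrow(ri), 1)
    ri$ub[j] <- ri$ub[j] * stats::runif(1)
    m2 <- MetabolicModel(stoichMatrix(m), metabolites(m), ri)
    expect_lte(maxProduction(m2, met), base + 1e-9)
  }
  lambda <- 2.5
  ri <- reactions(m)
  ri$lb <- ri$lb * lambda; ri$ub <- ri$ub * lambda
  m3 <- MetabolicModel(stoichMatrix(m), metabolites(m), ri)
  expect_equal(maxProduction(m3, met), lambda * base, tolerance = 1e-6)
})

test_that("infeasible models are reported as such", {
  # forced consumption of a metabolite with no source
  mets <- data.frame(id = "A_c", compartment = "c", boundary = FALSE)
  rxns <- data.frame(id = c("IN", "OUT"), lb = c(0, 5), ub = c(0, 10))
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A_c", c("IN", "OUT")))
  m <- MetabolicModel(S, mets, rxns)
  expect_error(fba(m, "OUT"), "infeasible")
})
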