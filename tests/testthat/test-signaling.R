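test_that("model construction follows the scenario configuration", {
  wt <- build_model(list(egf_nM = 8))
  expect_false(any(grepl("NRG|R3|D23|D33|D13", wt$species$name)))
  expect_false(any(grepl("LAP|R1i|R2i", wt$species$name)))

  m3 <- build_model(list(nrg_nM = 25))
  expect_true(all(c("NRG", "R3L", "D23_0", "D33", "D13_0") %in% m3$species$name))
  # exactly one catalytic-rate parameter carries the 1/1000 ErbB3 scale
  kcats <- m3$params[grep("^kcat", names(m3$params))]
  weak <- names(kcats)[abs(unlist(kcats) - m3$params[["kcat"]] / 1000) < 1e-12]
  expect_equal(weak, "kcat_erbb3")

  ml <- build_model(list(nrg_nM = 25, lapatinib_nM = 10000))
  expect_true(all(c("LAP", "R1i", "R1Li", "R2i", "D23_1") %in% ml$species$name))
  # zero catalytic flux through inhibitor-bound dimers: no reaction consumes
  # D23_1 except dissociation
  consuming <- Filter(function(r) "D23_1" %in% names(r$reactants), ml$reactions)
  prods <- unlist(lapply(consuming, function(r) names(r$products)))
  expect_false(any(grepl("D23p", prods)))
  expect_error(build_model(list(mutant = "nope")), class = "erbb_config_error")
})

test_that("the mass-action evaluator follows the law of mass action exactly", {
  m <- tiny_model(c(A = 2, B = 3, C = 0),
                  list(rxn(c("A", "B"), "C", "k1")),
                  params = list(k1 = 0.5))
  rhs <- mass_action_rhs(m)
  d <- rhs(0, c(A = 2, B = 3, C = 0))[[1]]
  expect_equal(d, c(-3, -3, 3))

  # reversible pair at detailed balance
  m2 <- tiny_model(c(A = 4, B = 2),
                   list(rxn("A", "B", "kf"), rxn("B", "A", "kr")),
                   params = list(kf = 1, kr = 2))
  expect_equal(mass_action_rhs(m2)(0, c(A = 4, B = 2))[[1]], c(0, 0))

  # A + A with stoichiometric power 2
  m3 <- tiny_model(c(A = 3, D = 0), list(rxn(c("A", "A"), "D", "k")),
                   params = list(k = 1))
  expect_equal(mass_action_rhs(m3)(0, c(A = 3, D = 0))[[1]], c(-18, 9))
  expect_error(mass_action_rhs(m)(0, c(A = -1, B = 1, C = 0)),
               class = "erbb_input_error")
})

test_that("conservation vectors lie in the left null space of the stoichiometry", {
  m <- build_model(list(egf_nM = 8, nrg_nM = 25, lapatinib_nM = 100))
  rhs <- mass_action_rhs(m)
  set.seed(5)
  for (i in 1:5) {
    y <- stats::setNames(runif(nrow(m$species), 0, 1e4), m$species$name)
    dy <- rhs(0, y)[[1]]
    drift <- m$composition %*% dy
    expect_lt(max(abs(drift)), 1e-6 * max(abs(dy)))
  }
})

test_that("integration conserves totals, stays non-negative and is deterministic", {
  m <- build_model(list(egf_nM = 8, nrg_nM = 25))
  r1 <- simulate_model(m, t_end = 30)
  expect_lt(r1$diagnostics$drift, 1e-6)
  expect_gt(r1$diagnostics$min_amount, -1e-9)
  r2 <- simulate_model(m, t_end = 30)
  expect_identical(r1$state, r2$state)
})

test_that("baseline, inhibited and resistant regimes behave as designed", {
  # zero ligand, WT, no constitutive flux: flat baseline
  m0 <- build_model(list(egf_nM = 0, params = list(kconst = 0)))
  r0 <- simulate_model(m0, t_end = 30)
  expect_equal(max(r0$state[, "ERKp"]), 0)
  expect_equal(max(r0$state[, "AKTp"]), 0)

  # saturating lapatinib without ErbB3: pAKT has no catalytic source
  mlap <- build_model(list(egf_nM = 8, lapatinib_nM = 10000))
  rlap <- simulate_model(mlap, t_end = 60)
  expect_lt(max(rlap$state[, "AKTp"]), 0.02 *
              max(simulate_model(build_model(list(egf_nM = 8)), t_end = 60)$state[, "AKTp"]))

  # ErbB3 + NRG keeps pAKT alive at maximal inhibition
  mres <- build_model(list(nrg_nM = 25, lapatinib_nM = 10000))
  rres <- simulate_model(mres, t_end = 60)
  expect_gt(rres$state[nrow(rres$state), "AKTp"], 0)
})

test_that("output metrics match closed forms and refined-grid interpolation", {
  m <- tiny_model(c(A = 5), list(), params = list())
  # constant trajectory: integral = c * T, peak = c
  mconst <- tiny_model(c(A = 5, B = 0), list(rxn("B", "A", "k")), params = list(k = 0))
  r <- simulate_model(mconst, t_end = 10, dt = 0.5)
  expect_equal(output_metric(r, "A", "integral"), 50, tolerance = 1e-8)
  expect_equal(output_metric(r, "A", "peak"), 5)

  mdecay <- tiny_model(c(A = 10, S = 0), list(rxn("A", "S", "k")), params = list(k = 0.3))
  rd <- simulate_model(mdecay, t_end = 10, dt = 0.25)
  expect_equal(output_metric(rd, "A", "peak"), 10)
  v <- output_metric(rd, "A", "value_at", t = 3.37)
  rf <- simulate_model(mdecay, t_end = 10, dt = 0.01)
  expect_equal(v, output_metric(rf, "A", "value_at", t = 3.37), tolerance = 1e-3)
  expect_error(output_metric(rd, "missing", "peak"), class = "erbb_lookup_error")
})

test_that("mutant profiles rescale exactly the tail-site kinetics", {
  m <- build_model(list(egf_nM = 8))
  expect_identical(apply_mutant(m, "WT")$params, m$params)

  dm <- apply_mutant(m, "L834R/T766M")
  expect_equal(dm$params[["kp68"]], 100 * m$params[["kp68"]])
  expect_equal(dm$params[["kp73"]], 100 * m$params[["kp73"]])

  # deletion mutant signals without ligand
  d0 <- simulate_model(build_model(list(egf_nM = 0, mutant = "del723-729insS")), t_end = 60)
  expect_gt(max(d0$state[, "ERKp"]), 0)
  expect_gt(max(d0$state[, "AKTp"]), 0)
})

test_that("pAKT responds monotonically to NRG dose and lapatinib dose", {
  peak_akt <- function(cfg) {
    max(simulate_model(build_model(cfg), t_end = 60, dt = 1)$state[, "AKTp"])
  }
  nrg <- vapply(c(5, 25, 100), function(d) peak_akt(list(nrg_nM = d)), numeric(1))
  expect_true(all(diff(nrg) > 0))
  lap <- vapply(c(0, 100, 10000), function(d)
    peak_akt(list(nrg_nM = 25, lapatinib_nM = d)), numeric(1))
  expect_true(all(diff(lap) < 0))
})

test_that("local sensitivity matches the production-degradation closed form", {
  # S (constant catalyst) -> S + X, X -> sink; steady X = ks*S/kd
  m <- tiny_model(c(S = 10, X = 0, SINK = 0),
                  list(rxn("S", c("S", "X"), "ks"), rxn("X", "SINK", "kd")),
                  params = list(ks = 2, kd = 1),
                  composition = matrix(c(1, 0, 0), 1, 3,
                                       dimnames = list("S", c("S", "X", "SINK"))))
  # the saturating rise peaks at its steady state ks*S/kd
  s <- local_sensitivity(m, c("ks", "kd"), species = "X", metric = "peak",
                         t_end = 40)
  expect_equal(s$coefficient[s$parameter == "ks"], 1, tolerance = 1e-3)
  expect_equal(s$coefficient[s$parameter == "kd"], -1, tolerance = 1e-3)
  mz <- tiny_model(c(S = 10, X = 0, SINK = 0, Z = 0),
                   list(rxn("S", c("S", "X"), "ks"), rxn("X", "SINK", "kd")),
                   params = list(ks = 2, kd = 1))
  expect_error(local_sensitivity(mz, "ks", species = "Z", metric = "peak"),
               class = "erbb_statistics_error")
})

test_that("global sensitivity isolates the driving parameter and is seeded", {
  m <- tiny_model(c(S = 10, X = 0, SINK = 0),
                  list(rxn("S", c("S", "X"), "ks"), rxn("X", "SINK", "kd")),
                  params = list(ks = 2, kd = 1),
                  composition = matrix(c(1, 0, 0), 1, 3,
                                       dimnames = list("S", c("S", "X", "SINK"))))
  ranges <- list(ks = c(0.5, 8), kd = c(1, 1), S = c(2, 50))
  expect_warning(
    g <- global_sensitivity(m, ranges, n_samples = 60, species = "X",
                            metric = "peak", seed = 3, t_end = 40),
    "degenerate")
  expect_gt(abs(g$coefficient[g$parameter == "ks"]), 0.9)
  expect_equal(g$coefficient[g$parameter == "kd"], 0)
  expect_warning(
    g2 <- global_sensitivity(m, ranges, n_samples = 60, species = "X",
                             metric = "peak", seed = 3, t_end = 40))
  expect_identical(g$coefficient, g2$coefficient)
})

test_that("rate-constant fitting recovers parameters and flags non-identifiability", {
  m <- build_model(list(egf_nM = 8))
  truth <- c(kras_shc = m$params[["kras_shc"]], kerk_on = m$params[["kerk_on"]])
  data <- make_signaling_dataset(m, c("ERKp", "RasGTP"), noise_cv = 0,
                                 replicates = 1, seed = 1, times = seq(0, 40, 4))
  start <- m
  start$params[["kras_shc"]] <- truth[["kras_shc"]] * 3
  start$params[["kerk_on"]] <- truth[["kerk_on"]] / 3
  fit <- fit_rate_constants(start, list(times = data$times, data = data$data[[1]]),
                            free = c("kras_shc", "kerk_on"), seed = 2, n_starts = 2)
  expect_lt(abs(fit$estimates[["kras_shc"]] / truth[["kras_shc"]] - 1), 0.01)
  expect_lt(abs(fit$estimates[["kerk_on"]] / truth[["kerk_on"]] - 1), 0.01)

  # a parameter with no influence on the observed species is flagged
  expect_warning(
    flat <- fit_rate_constants(start, list(times = data$times, data = data$data[[1]]),
                               free = c("kras_shc", "kpip_gab"), seed = 2,
                               n_starts = 2),
    "non-identifiable")
  expect_false(flat$identifiable[["kpip_gab"]])
  expect_error(fit_rate_constants(m, list(), free = letters[1:6]),
               class = "erbb_usage_error")
})
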