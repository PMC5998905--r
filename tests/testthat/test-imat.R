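test_that("reaction states come from GPR evaluation of the sample", {
  net <- branch_network()
  st <- reaction_states(net, c(g1 = 1L, g2 = 1L, g3 = 0L))
  expect_identical(unname(st[c("AB", "AC", "CB")]), c(1L, 1L, 0L))
  # exchange reactions (empty GPR) are always moderate
  expect_identical(unname(st[c("EX_a", "EX_b")]), c(0L, 0L))
  # and/or combinations
  net2 <- metabolic_network(data.frame(
    reaction_id = c("EX_a", "R", "EX_b"),
    equation = c("=> A", "A => B", "B =>"),
    lower_bound = NA, upper_bound = NA,
    gpr = c("", "g1 or g2", ""), subsystem = ""))
  expect_identical(unname(reaction_states(net2, c(g1 = -1L, g2 = 0L))["R"]),
                   0L)
  expect_identical(unname(reaction_states(net2, c(g1 = -1L, g2 = -1L))["R"]),
                   -1L)
})

test_that("iMAT picks the expression-consistent branch", {
  net <- branch_network(uptake = 10)
  fit <- imat(net, c(AB = 1L, AC = -1L), epsilon = 1)
  expect_identical(fit$status, "optimal")
  expect_identical(fit$objective, 2L)
  expect_gte(fit$fluxes[["AB"]], 1)
  expect_identical(fit$fluxes[["AC"]], 0)
  expect_setequal(fit$satisfied_high, "AB")
  expect_setequal(fit$satisfied_low, "AC")
  expect_identical(unname(residuals(fit)), c(0L, 0L))
})

test_that("with no flags the zero flux vector is optimal", {
  net <- branch_network()
  fit <- imat(net, setNames(integer(0), character(0)))
  expect_identical(fit$objective, 0L)
  expect_true(all(fit$fluxes == 0))
})

test_that("mutually exclusive high flags satisfy only one", {
  # uptake capped at 1: A=>B and A=>C=>B cannot both carry >= 1
  net <- branch_network(uptake = 1)
  fit <- imat(net, c(AB = 1L, AC = 1L), epsilon = 1)
  expect_identical(fit$objective, 1L)
  expect_identical(sum(residuals(fit)), 1L)
})

test_that("MILP objective equals the brute-force enumeration oracle", {
  for (seed in 1:120) {
    inst <- random_imat_instance(seed)
    fit <- imat(inst$network, inst$states, canonicalize = FALSE)
    expect_identical(fit$objective,
                     as.integer(imat_objective_oracle(inst$network,
                                                      inst$states)))
  }
})

test_that("fluxes conserve mass and respect bounds", {
  for (seed in c(3, 17, 42)) {
    inst <- random_imat_instance(seed)
    fit <- imat(inst$network, inst$states)
    S <- stoichiometric_matrix(inst$network)
    expect_lt(max(abs(S %*% fit$fluxes)), 1e-6)
    expect_true(all(fit$fluxes >=
                      inst$network$reactions$lower_bound - 1e-7))
    expect_true(all(fit$fluxes <=
                      inst$network$reactions$upper_bound + 1e-7))
  }
})

test_that("adding a high flag never decreases the objective", {
  for (seed in 1:40) {
    inst <- random_imat_instance(seed, max_flags = 5)
    base <- imat(inst$network, inst$states, canonicalize = FALSE)$objective
    free <- setdiff(reaction_ids(inst$network), names(inst$states))
    if (!length(free)) next
    states2 <- c(inst$states, setNames(1L, free[1]))
    more <- imat(inst$network, states2, canonicalize = FALSE)$objective
    expect_gte(more, base)
    expect_lte(more, base + 1L)
  }
})

test_that("fully consistent planted scenarios are satisfied completely", {
  sc <- make_scenario(seed = 9)
  states <- discretize(sc$expression)
  for (s in sc$manifest$sample_id) {
    rs <- reaction_states(sc$network, states, s)
    fit <- imat(sc$network, rs, epsilon = 1)
    expect_identical(fit$objective,
                     sum(rs == 1L) + sum(rs == -1L))
    planted <- sc$truth$samples[[s]]
    expect_true(all(abs(fit$fluxes[planted$r_high]) >= 1 - 1e-9))
    expect_true(all(fit$fluxes[planted$r_low] == 0))
  }
})

test_that("an unreachable epsilon for a high flag warns", {
  net <- metabolic_network(data.frame(
    reaction_id = c("EX_a", "R1", "EX_b"),
    equation = c("=> A", "A => B", "B =>"),
    lower_bound = 0, upper_bound = c(10, 0.5, 10),
    gpr = "", subsystem = ""))
  expect_warning(imat(net, c(R1 = 1L), epsilon = 1), "attainable")
  expect_error(imat(net, c(R1 = 1L), epsilon = 0), "epsilon")
  expect_error(imat(net, c(nope = 1L)), "unknown reaction")
  expect_error(imat(net, c(R1 = 5L)), "states")
})

test_that("tissue models keep reactions above the activity tolerance", {
  net <- branch_network()
  fit <- imat(net, c(AB = 1L))
  tm <- extract_tissue_model(net, fit, "t1")
  expect_s3_class(tm, "tissue_model")
  expect_setequal(tm$active_reactions, c("EX_a", "AB", "EX_b"))

  # manual fit object: thresholding and the sub-tolerance case
  fit2 <- fit
  fit2$fluxes <- setNames(c(10, 10, 0, 1e-9, 0), reaction_ids(net))
  tm2 <- extract_tissue_model(net, fit2, "t2")
  expect_setequal(tm2$active_reactions, c("EX_a", "AB"))

  fit3 <- fit
  fit3$fluxes[] <- 0
  expect_warning(tm3 <- extract_tissue_model(net, fit3, "t3"),
                 "no active reactions")
  expect_length(tm3$active_reactions, 0L)

  fit4 <- fit
  fit4$status <- "time-limit"
  expect_error(extract_tissue_model(net, fit4, "t4"), "non-optimal")
})

test_that("active-set overlap counts every Venn region", {
  net <- branch_network()
  mk <- function(tissue, active) {
    structure(list(tissue = tissue, active_reactions = active,
                   fluxes = setNames(numeric(5), reaction_ids(net)),
                   epsilon = 1, source_states = NULL,
                   network_fingerprint =
                     fluxshift:::network_fingerprint(net)),
              class = "tissue_model")
  }
  ov <- active_set_overlap(list(mk("A", c("a", "b", "c")),
                                mk("B", c("b", "c", "d"))))
  expect_identical(unname(ov["shared"]), 2L)
  expect_identical(unname(ov["A"]), 1L)
  expect_identical(unname(ov["B"]), 1L)
  expect_identical(unname(ov["A&B"]), 2L)

  ov2 <- active_set_overlap(list(mk("A", c("x", "y")), mk("B", c("x", "y"))))
  expect_identical(unname(ov2["shared"]), 2L)
  expect_identical(unname(ov2["A"]), 0L)

  ov3 <- active_set_overlap(list(mk("A", "a"), mk("B", "b"), mk("C", "c")))
  expect_identical(unname(ov3["shared"]), 0L)

  other <- chain_network()
  bad <- structure(list(tissue = "Z", active_reactions = "R1",
                        fluxes = NULL, epsilon = 1, source_states = NULL,
                        network_fingerprint =
                          fluxshift:::network_fingerprint(other)),
                   class = "tissue_model")
  expect_error(active_set_overlap(list(mk("A", "a"), bad)),
               "different networks")
  expect_error(active_set_overlap(list(mk("A", "a"))), "at least two")
})
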