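test_that("tabular model files round-trip through the reader", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
    "R1\tA[c] => B[c]\t0\t1000\tg1 and g2\tglycolysis",
    "R2\tB[c] <=> C[c]\t\t\tg3\tglycolysis",
    "R3\t2 A[c] + B[c] => 3 C[c]\t0\t500\t\tother"), tf)
  net <- read_network(tf)
  expect_identical(dim(stoichiometric_matrix(net)), c(3L, 3L))
  # blank bounds with a reversible arrow default to [-1000, 1000]
  expect_identical(net$reactions$lower_bound[2], -1000)
  expect_identical(net$reactions$upper_bound[2], 1000)
  expect_true(net$reactions$reversible[2])
  # coefficients and compartment suffixes
  expect_identical(net$stoichiometry$R3,
                   c(`A[c]` = -2, `B[c]` = -1, `C[c]` = 3))
  expect_identical(net$metabolites$compartment, c("c", "c", "c"))
  expect_setequal(net$genes, c("g1", "g2", "g3"))

  out <- tempfile(fileext = ".tsv")
  write_network(net, out)
  net2 <- read_network(out)
  expect_identical(stoichiometric_matrix(net2), stoichiometric_matrix(net))
  expect_identical(net2$reactions, net$reactions)
})

test_that("irreversible reactions with blank bounds default to [0, 1000]", {
  net <- metabolic_network(data.frame(
    reaction_id = c("EX_a", "R1", "EX_b"),
    equation = c("=> A", "A => B", "B =>"),
    lower_bound = NA, upper_bound = NA, gpr = "", subsystem = ""))
  expect_identical(net$reactions$lower_bound, c(0, 0, 0))
  expect_identical(net$reactions$upper_bound, c(1000, 1000, 1000))
})

test_that("duplicate reaction ids are a validation error", {
  df <- data.frame(reaction_id = c("R1", "R1"),
                   equation = c("A => B", "B => C"),
                   lower_bound = NA, upper_bound = NA,
                   gpr = "", subsystem = "")
  expect_error(metabolic_network(df), "duplicate reaction id: R1")
})

test_that("stoichiometric matrix columns agree with reaction stoichiometry", {
  net <- make_network(n_linear_chains = 3, n_branch_points = 1, seed = 5)
  S <- stoichiometric_matrix(net)
  for (id in reaction_ids(net)) {
    s <- net$stoichiometry[[id]]
    col <- S[, id]
    expect_identical(col[names(s)], s)
    expect_true(all(col[setdiff(rownames(S), names(s))] == 0))
  }
})

test_that("exchange reactions are detected by topology and by prefix", {
  net <- metabolic_network(data.frame(
    reaction_id = c("EX_glc", "uptake_b", "R1"),
    equation = c("GLC =>", "=> B", "GLC + B => C"),
    lower_bound = NA, upper_bound = NA, gpr = "", subsystem = ""))
  expect_identical(net$reactions$is_exchange, c(TRUE, TRUE, FALSE))
})

test_that("referential and structural problems are caught", {
  expect_error(metabolic_network(
    data.frame(reaction_id = "R1", equation = "A => B",
               lower_bound = 5, upper_bound = 1, gpr = "", subsystem = "")),
    "lower_bound > upper_bound")
  expect_error(metabolic_network(
    data.frame(reaction_id = "R1", equation = "A => B",
               lower_bound = NA, upper_bound = NA, gpr = "", subsystem = ""),
    metabolites = data.frame(id = "A", name = "A", compartment = "")),
    "not declared")
  expect_error(metabolic_network(
    data.frame(reaction_id = "R1", equation = "A + B",
               lower_bound = NA, upper_bound = NA, gpr = "", subsystem = "")),
    "lacks")
  expect_error(read_network(tempfile()), "no such file")
})

test_that("the SBML-FBC reader agrees with the tabular twin", {
  sbml <- system.file("extdata", "mini_model.xml", package = "fluxshift")
  tsv <- system.file("extdata", "mini_model.tsv", package = "fluxshift")
  expect_true(nzchar(sbml) && nzchar(tsv))
  a <- read_network(sbml)
  b <- read_network(tsv)
  expect_identical(sort(reaction_ids(a)), sort(reaction_ids(b)))
  for (id in reaction_ids(a)) {
    ia <- match(id, a$reactions$id)
    ib <- match(id, b$reactions$id)
    expect_identical(a$stoichiometry[[id]], b$stoichiometry[[id]])
    expect_equal(a$reactions$lower_bound[ia], b$reactions$lower_bound[ib])
    expect_equal(a$reactions$upper_bound[ia], b$reactions$upper_bound[ib])
    expect_identical(parse_gpr(a$reactions$gpr[ia]),
                     parse_gpr(b$reactions$gpr[ib]))
    expect_identical(a$reactions$subsystem[ia], b$reactions$subsystem[ib])
  }
})
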