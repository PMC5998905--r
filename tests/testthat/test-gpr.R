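test_that("GPR parsing honours AND > OR precedence and parentheses", {
  e <- parse_gpr("g1 and g2")
  expect_identical(e$type, "and")
  expect_identical(vapply(e$children, `[[`, "", "gene"), c("g1", "g2"))

  e <- parse_gpr("g1 or g2 and g3")
  expect_identical(e$type, "or")
  expect_identical(e$children[[1]]$gene, "g1")
  expect_identical(e$children[[2]]$type, "and")

  e <- parse_gpr("(g1 or g2) and g3")
  expect_identical(e$type, "and")
  expect_identical(e$children[[1]]$type, "or")

  # keywords are case-insensitive; chains flatten to n-ary nodes
  e <- parse_gpr("g1 OR g2 Or g3")
  expect_identical(e$type, "or")
  expect_length(e$children, 3L)
})

test_that("malformed GPR text is a parse error", {
  expect_error(parse_gpr("(g1 or"), "parse error")
  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("g1 or or g2"), "parse error")
  expect_error(parse_gpr("g1 g2"), "unexpected token")
  expect_error(parse_gpr(")g1("), "parse error")
})

test_that("empty GPR text yields the empty expression evaluating to 0", {
  for (txt in list("", "   ", NA_character_, NULL)) {
    e <- parse_gpr(txt)
    expect_identical(e$type, "empty")
    expect_identical(evaluate_gpr(e, c(g1 = 1L)), 0L)
  }
})

test_that("AND/OR evaluate as min/max over the full trilean truth table", {
  vals <- c(-1L, 0L, 1L)
  for (a in vals) {
    for (b in vals) {
      st <- c(g1 = a, g2 = b)
      expect_identical(evaluate_gpr(parse_gpr("g1 and g2"), st), min(a, b))
      expect_identical(evaluate_gpr(parse_gpr("g1 or g2"), st), max(a, b))
    }
  }
  # genes absent from the state map count as moderate
  expect_identical(evaluate_gpr(parse_gpr("g1 and gX"), c(g1 = 1L)), 0L)
  expect_identical(evaluate_gpr(parse_gpr("g1 or gX"), c(g1 = -1L)), 0L)
  expect_error(evaluate_gpr(parse_gpr("g1"), c(g1 = 3)), "states")
})

test_that("evaluation matches an expression built with a known value", {
  # generate random expressions, computing the expected value during
  # generation (an independent recursion from the parser/evaluator path)
  set.seed(11)
  gen <- function(depth, states) {
    if (depth == 0 || runif(1) < 0.3) {
      g <- sample(names(states), 1)
      return(list(text = g, value = unname(states[[g]])))
    }
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    kids <- lapply(seq_len(k), function(i) gen(depth - 1, states))
    vals <- vapply(kids, `[[`, 0L, "value")
    list(text = paste0("(", paste(vapply(kids, `[[`, "", "text"),
                                  collapse = paste0(" ", op, " ")), ")"),
         value = if (op == "and") min(vals) else max(vals))
  }
  for (i in 1:1000) {
    states <- setNames(sample(c(-1L, 0L, 1L), 6, replace = TRUE),
                       paste0("g", 1:6))
    e <- gen(sample(1:5, 1), states)
    expect_identical(evaluate_gpr(parse_gpr(e$text), states), e$value)
  }
})

test_that("parse -> deparse -> parse is the identity on the tree", {
  set.seed(12)
  rnd_text <- function(depth) {
    if (depth == 0 || runif(1) < 0.35) return(sample(paste0("g", 1:9), 1))
    op <- sample(c(" and ", " or "), 1)
    kids <- replicate(sample(2:3, 1), rnd_text(depth - 1))
    paste0("(", paste(kids, collapse = op), ")")
  }
  for (i in 1:300) {
    t1 <- parse_gpr(rnd_text(sample(1:5, 1)))
    t2 <- parse_gpr(gpr_to_text(t1))
    expect_identical(t2, t1)
  }
  # OR under AND keeps its parentheses
  expect_identical(gpr_to_text(parse_gpr("(g1 or g2) and g3")),
                   "(g1 or g2) and g3")
  expect_identical(gpr_to_text(parse_gpr("g1 or (g2 and g3)")),
                   "g1 or g2 and g3")
})

test_that("gpr_genes collects each leaf once", {
  expect_setequal(gpr_genes(parse_gpr("(g1 or g2) and (g2 or g3)")),
                  c("g1", "g2", "g3"))
  expect_identical(gpr_genes(parse_gpr("")), character(0))
})
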