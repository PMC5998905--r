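test_that("total variation sums absolute consecutive differences", {
  expect_equal(total_variation(c(5, 3, 8)), 7)
  expect_equal(total_variation(rep(4, 6)), 0)
  expect_equal(total_variation(c(0, 1000, -1000)), 3000)
  expect_error(total_variation(5), "at least two")
  expect_error(total_variation(c(1, NA)), "finite")
})

test_that("total variation matches the loop oracle and its invariances", {
  set.seed(41)
  for (i in 1:1000) {
    x <- rnorm(sample(2:10, 1), sd = 100)
    tv <- total_variation(x)
    expect_equal(tv, tv_oracle(x))
    expect_gte(tv, 0)
    expect_equal(total_variation(rev(x)), tv)
    if (length(x) >= 3) {
      j <- sample(2:(length(x) - 1), 1)
      expect_lte(total_variation(x[-j]), tv + 1e-12)
    }
  }
  # zero iff constant
  expect_identical(total_variation(c(2, 2, 2)) == 0, TRUE)
  set.seed(42)
  x <- rnorm(5)
  expect_gt(total_variation(x), 0)
})

test_that("fluctuation ranking is descending with lexicographic ties", {
  m <- rbind(const = c(5, 5, 5), osc = c(0, 10, 0),
             b_tie = c(0, 1, 0), a_tie = c(1, 0, 1))
  colnames(m) <- c("t1", "t2", "t3")
  r <- rank_fluctuating_reactions(m)
  expect_identical(r$reaction_id, c("osc", "a_tie", "b_tie", "const"))
  expect_identical(r$rank, 1:4)
  expect_error(rank_fluctuating_reactions(m[, 1, drop = FALSE]),
               "at least two")
  expect_error(rank_fluctuating_reactions(m, order = c("t1", "zz")),
               "unknown tissue")
})

test_that("the flux-change ratio follows the +/-0.5 rule", {
  fc <- flux_change(2, 8, 0, 10)
  expect_equal(fc$ratio, 0.6)
  expect_identical(fc$call, "up")
  # absolute-value semantics for reversible fluxes
  fc2 <- flux_change(-8, 2, -10, 10)
  expect_equal(fc2$ratio, -0.3)
  expect_identical(fc2$call, "unchanged")
  # degenerate range: undefined, not an error
  fc3 <- flux_change(4, 4, 4, 4)
  expect_true(is.na(fc3$ratio))
  expect_identical(fc3$call, "undefined")
  # the ratio compares flux magnitudes: gaining reverse flux is "up"
  fc4 <- flux_change(0, -9, 0, 10)
  expect_identical(fc4$call, "up")
  fc5 <- flux_change(-9, 0, 0, 10)
  expect_identical(fc5$call, "down")
})

test_that("ratio is antisymmetric and bounded for irreversible ranges", {
  set.seed(43)
  for (i in 1:500) {
    lo <- runif(1, 0, 50)
    hi <- lo + runif(1, 0.1, 100)
    f1 <- runif(1, lo, hi)
    f2 <- runif(1, lo, hi)
    a <- flux_change(f1, f2, lo, hi)$ratio
    b <- flux_change(f2, f1, lo, hi)$ratio
    expect_equal(a, -b)
    expect_gte(a, -1)
    expect_lte(a, 1)
  }
  # identical fluxes are never "up"/"down"
  for (v in c(-3, 0, 7)) {
    expect_true(flux_change(v, v, -10, 10)$call %in%
                  c("unchanged", "undefined"))
    expect_true(flux_change(v, v, 5, 5)$call %in%
                  c("unchanged", "undefined"))
  }
})

test_that("flux_change accepts an fva_range table", {
  net <- chain_network(len = 1, uptake = 10)
  rng <- fva(net)
  fc <- flux_change(c(0, 0, 0), c(8, 8, 8), rng)
  expect_identical(fc$reaction_id, rng$reaction_id)
  expect_equal(fc$ratio, rep(0.8, 3))
  expect_identical(unique(fc$call), "up")
})

test_that("clustering merges identical patterns first, ties by label", {
  m <- cbind(a = c(1, 0, 0), b = c(0, 5, 1), d = c(0, 5, 1))
  cl <- cluster_patterns(m, axis = "columns")
  expect_identical(sort(cl$labels), c("a", "b", "d"))
  # identical columns b, d merge first at height 0
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$labels[-first], c("b", "d"))
  expect_equal(cl$heights[1], 0)
  expect_true(all(diff(cl$heights) >= 0))
  expect_true(grepl("b", cl$newick) && grepl("d", cl$newick))

  # two columns: exactly one merge
  cl2 <- cluster_patterns(m[, 1:2])
  expect_length(cl2$heights, 1L)

  # orthogonal one-hot columns: all distances equal, merge order by label
  m3 <- cbind(z = c(1, 0, 0), y = c(0, 1, 0), x = c(0, 0, 1))
  cl3 <- cluster_patterns(m3)
  first3 <- cl3$hclust$merge[1, ]
  expect_setequal(cl3$labels[-first3], c("x", "y"))

  expect_error(cluster_patterns(m[, 1, drop = FALSE]), "at least two")
  m_na <- m
  m_na[1, 1] <- NA
  expect_error(cluster_patterns(m_na), "missing")
})
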