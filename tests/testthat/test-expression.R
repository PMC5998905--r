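test_that("FPKM is fragments over (mapped millions x length kb)", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(100, 2000, 1e7), 5)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  # vectorized over genes, names kept
  expect_equal(compute_fpkm(c(gA = 10, gB = 0), c(1000, 500), 1e6),
               c(gA = 10, gB = 0))
  expect_error(compute_fpkm(10, 1000, 0), "positive")
  expect_error(compute_fpkm(10, 0, 1e6), "positive")
  expect_error(compute_fpkm(-1, 1000, 1e6), ">= 0")
})

test_that("discretization keeps the top/bottom 15% and handles ties", {
  m <- cbind(s1 = 1:20)
  rownames(m) <- paste0("g", 1:20)
  st <- discretize(m)$states[, 1]
  expect_identical(names(st)[st == 1L], c("g18", "g19", "g20"))
  expect_identical(names(st)[st == -1L], c("g1", "g2", "g3"))

  # degenerate: all equal -> everything moderate
  m2 <- cbind(s1 = rep(7, 30))
  rownames(m2) <- paste0("g", 1:30)
  expect_true(all(discretize(m2)$states == 0L))

  # a tie block at the cutoff shared by too many genes drops to moderate
  m3 <- cbind(s1 = c(rep(100, 8), 51:62, rep(1, 2)))
  rownames(m3) <- paste0("g", 1:22)
  st3 <- discretize(m3)$states[, 1]  # k = ceiling(0.15*22) = 4 < 8 tied
  expect_identical(sum(st3 == 1L), 0L)          # tied top block dropped
  expect_identical(sum(st3 == -1L), 4L)         # low side fits within k

  expect_error(discretize(m, low_q = 0.5, high_q = 0.5), "low_q")
  expect_warning(discretize(cbind(s = c(1, 2, 3))), "fewer than")
})

test_that("extreme-class sizes match a sort-based oracle", {
  set.seed(21)
  for (n in c(7, 20, 100, 1001)) {
    v <- sample(seq_len(10 * n), n)  # distinct
    names(v) <- paste0("g", seq_len(n))
    st <- discretize(cbind(s = v))$states[, 1]
    k <- ceiling(0.15 * n)
    top <- names(sort(v, decreasing = TRUE))[seq_len(k)]
    bottom <- names(sort(v))[seq_len(k)]
    expect_setequal(names(st)[st == 1L], top)
    expect_setequal(names(st)[st == -1L], bottom)
    # tied copies never inflate the extreme classes beyond k
    vt <- v
    vt[] <- round(vt / (2 * n))  # heavy ties
    stt <- discretize(cbind(s = vt))$states[, 1]
    expect_lte(sum(stt == 1L), k)
    expect_lte(sum(stt == -1L), k)
  }
})

test_that("discretization is invariant under strictly monotone transforms", {
  set.seed(22)
  m <- matrix(rexp(200, rate = 1 / 50), 100, 2,
              dimnames = list(paste0("g", 1:100), c("s1", "s2")))
  base <- discretize(m)$states
  expect_identical(discretize(m^3)$states, base)
  expect_identical(discretize(log1p(m))$states, base)
  expect_identical(discretize(2 * m + 5)$states, base)
})

test_that("fold-change calls follow the 2 / 0.5 rule", {
  m <- cbind(t1 = c(2, 4, 3, 0), t2 = c(5, 1, 3, 9))
  rownames(m) <- paste0("g", 1:4)
  fc <- gene_fold_changes(m, "t1", "t2", pseudocount = 0)
  expect_equal(fc$fc[1], 2.5)
  expect_identical(fc$call[1], "up")
  expect_equal(fc$fc[2], 0.25)
  expect_identical(fc$call[2], "down")
  expect_identical(fc$call[3], "unchanged")  # fc exactly 1
  # default pseudocount guards zero FPKM
  fc1 <- gene_fold_changes(m, "t1", "t2")
  expect_equal(fc1$fc[4], 10)
  expect_error(gene_fold_changes(m, "t1", "nope"), "unknown sample")
})

test_that("swapping the samples mirrors the calls (pseudocount 0)", {
  set.seed(23)
  m <- matrix(rexp(100, 1 / 20) + 0.5, 50, 2,
              dimnames = list(paste0("g", 1:50), c("a", "b")))
  ab <- gene_fold_changes(m, "a", "b", pseudocount = 0)
  ba <- gene_fold_changes(m, "b", "a", pseudocount = 0)
  expect_equal(ba$fc, 1 / ab$fc)
  expect_identical(ba$call[ab$call == "up"],
                   rep("down", sum(ab$call == "up")))
  expect_identical(ba$call[ab$call == "down"],
                   rep("up", sum(ab$call == "down")))
})

test_that("expression tables round-trip through read_expression", {
  tf <- tempfile(fileext = ".tsv")
  m <- matrix(c(1.5, 0, 3, 2, 8, 0.25), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(tf), m)
  writeLines(c("foo\ts1", "g1\t2"), tf)
  expect_error(read_expression(tf), "gene_id")
})
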