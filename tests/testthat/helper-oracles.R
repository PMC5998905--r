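# Fixture builders and independent oracles used across the suite.

# A => B => ... linear chain with a capped uptake, all built in code.
chain_network <- function(len = 2, uptake = 10) {
  mets <- paste0("M", seq_len(len + 1))
  rows <- data.frame(
    reaction_id = c("EX_in",
                    paste0("R", seq_len(len)),
                    "EX_out"),
    equation = c(paste("=>", mets[1]),
                 paste(mets[seq_len(len)], "=>", mets[seq_len(len) + 1]),
                 paste(mets[len + 1], "=>")),
    lower_bound = 0,
    upper_bound = c(uptake, rep(1000, len), 1000),
    gpr = "", subsystem = "chain", stringsAsFactors = FALSE)
  metabolic_network(rows)
}

# Diamond: one uptake, two parallel routes A->B, used for iMAT choice tests.
branch_network <- function(uptake = 10) {
  metabolic_network(data.frame(
    reaction_id = c("EX_a", "AB", "AC", "CB", "EX_b"),
    equation = c("=> A", "A => B", "A => C", "C => B", "B =>"),
    lower_bound = 0,
    upper_bound = c(uptake, 1000, 1000, 1000, 1000),
    gpr = c("", "g1", "g2", "g3", ""), subsystem = "",
    stringsAsFactors = FALSE))
}

# Small random network (<= 12 reactions) plus a random trilean reaction
# state map with at most `max_flags` non-zero flags.
random_imat_instance <- function(seed, max_flags = 8) {
  net <- make_network(
    n_linear_chains = 1 + seed %% 2,
    n_branch_points = if (seed %% 2) seed %% 2 else 0,
    reversible_fraction = (seed %% 5) / 10,
    chain_length = 1 + (seed %% 3),
    seed = seed)
  ids <- reaction_ids(net)
  set.seed(seed + 7L)
  nf <- sample(0:min(max_flags, length(ids)), 1)
  flagged <- sample(ids, nf)
  states <- setNames(sample(c(-1L, 1L), nf, replace = TRUE), flagged)
  list(network = net, states = states)
}

# Brute-force iMAT oracle: enumerate every subset of the flagged reactions,
# test by LP whether all of them can be satisfied simultaneously (trying
# both directions for reversible high flags), and return the size of the
# largest satisfiable subset. Supersets of infeasible subsets are pruned,
# which is sound because constraints only accumulate.
imat_objective_oracle <- function(network, states, epsilon = 1) {
  ids <- reaction_ids(network)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  S <- stoichiometric_matrix(network)
  zero <- rep(0, nrow(S))
  flagged <- names(states)[states != 0]
  k <- length(flagged)
  subset_feasible <- function(sel) {
    highs <- sel[states[sel] == 1]
    lows <- sel[states[sel] == -1]
    revh <- highs[lb[match(highs, ids)] < 0]
    fwdh <- setdiff(highs, revh)
    nd <- length(revh)
    for (mask in 0:(2^nd - 1)) {
      lb2 <- lb
      ub2 <- ub
      for (r in fwdh) {
        j <- match(r, ids)
        lb2[j] <- max(lb2[j], epsilon)
      }
      if (nd) {
        for (t in seq_len(nd)) {
          j <- match(revh[t], ids)
          if (bitwAnd(mask, 2^(t - 1))) {
            ub2[j] <- min(ub2[j], -epsilon)
          } else {
            lb2[j] <- max(lb2[j], epsilon)
          }
        }
      }
      for (r in lows) {
        j <- match(r, ids)
        lb2[j] <- max(lb2[j], 0)
        ub2[j] <- min(ub2[j], 0)
      }
      if (any(lb2 > ub2)) next
      r <- lp_solve(numeric(length(ids)), S, zero, lb2, ub2)
      if (r$status == "optimal") return(TRUE)
    }
    FALSE
  }
  if (k == 0) return(0L)
  masks <- 0:(2^k - 1)
  bits <- function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
  popcount <- vapply(masks, function(m) length(bits(m)), 0L)
  feasible <- logical(length(masks))
  feasible[1] <- TRUE  # empty subset: base network realizable by v = 0
  best <- 0L
  for (m in masks[order(popcount)][-1]) {
    bs <- bits(m)
    parents_ok <- all(vapply(bs, function(b) {
      feasible[bitwAnd(m, bitwNot(2^(b - 1))) + 1]
    }, TRUE))
    if (!parents_ok) next
    if (subset_feasible(flagged[bs])) {
      feasible[m + 1] <- TRUE
      best <- max(best, length(bs))
    }
  }
  best
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients in log space (independent of phyper).
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Literal-loop total variation.
tv_oracle <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}
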