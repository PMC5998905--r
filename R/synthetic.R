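#' Generate a toy metabolic network
#'
#' Builds a connected stoichiometric network of linear pathway chains, each
#' with its own uptake (`EX_in_*`) and secretion (`EX_out_*`) exchange
#' reaction, plus optional irreversible connector reactions between chains.
#' Internal reactions carry bounds `[0, 1000]` (`[-1000, 1000]` when drawn
#' reversible) and GPR rules cycling through the three forms a real model
#' mixes: a single gene, an `and` pair (complex), an `or` pair (isozymes).
#' Each chain is one subsystem (`pathway_1`, `pathway_2`, ...); connector
#' reactions are labelled `connector`; exchanges are unlabelled. Every gene
#' belongs to exactly one reaction, which makes planted expression states
#' map exactly onto reaction states.
#'
#' Generation is a pure function of the parameters and `seed` (the
#' caller's RNG state is untouched): the same call reproduces the same
#' network byte for byte.
#'
#' @param n_linear_chains number of chains (>= 1; >= 2 when
#'   `n_branch_points > 0`).
#' @param n_branch_points number of connector reactions between chains.
#' @param reversible_fraction probability that an internal reaction is
#'   reversible.
#' @param chain_length internal reactions per chain.
#' @param seed integer seed.
#' @param bound magnitude of the default flux bounds.
#' @return a [metabolic_network].
#' @export
make_network <- function(n_linear_chains = 8, n_branch_points = 2,
                         reversible_fraction = 0.2, chain_length = 4,
                         seed = 1, bound = 1000) {
  stopifnot(n_linear_chains >= 1, chain_length >= 1, n_branch_points >= 0,
            reversible_fraction >= 0, reversible_fraction <= 1)
  if (n_branch_points > 0 && n_linear_chains < 2) {
    stop("connector reactions need at least two chains", call. = FALSE)
  }
  with_seed(seed, {
    gene_counter <- 0L
    next_genes <- function(k) {
      g <- sprintf("gene_%03d", gene_counter + seq_len(k))
      gene_counter <<- gene_counter + k
      g
    }
    rows <- list()
    add <- function(id, eq, lb, ub, gpr, subsystem) {
      rows[[length(rows) + 1L]] <<- data.frame(
        reaction_id = id, equation = eq, lower_bound = lb, upper_bound = ub,
        gpr = gpr, subsystem = subsystem, stringsAsFactors = FALSE)
    }
    gpr_forms <- c("single", "and", "or")
    ridx <- 0L
    for (ch in seq_len(n_linear_chains)) {
      sub <- sprintf("pathway_%d", ch)
      mets <- sprintf("M%d_%d", ch, seq_len(chain_length + 1L))
      add(sprintf("EX_in_%d", ch), paste("=>", mets[1L]), 0, bound, "", "")
      for (i in seq_len(chain_length)) {
        ridx <- ridx + 1L
        rev <- stats::runif(1) < reversible_fraction
        form <- gpr_forms[(ridx - 1L) %% 3L + 1L]
        gpr <- switch(form,
          single = next_genes(1L),
          and = paste(next_genes(2L), collapse = " and "),
          or = paste(next_genes(2L), collapse = " or "))
        add(sprintf("R%d_%d", ch, i),
            paste(mets[i], if (rev) "<=>" else "=>", mets[i + 1L]),
            if (rev) -bound else 0, bound, gpr, sub)
      }
      add(sprintf("EX_out_%d", ch), paste(mets[chain_length + 1L], "=>"),
          0, bound, "", "")
    }
    for (k in seq_len(n_branch_points)) {
      a <- sample(n_linear_chains, 1L)
      others <- setdiff(seq_len(n_linear_chains), a)
      b <- others[sample.int(length(others), 1L)]
      ia <- sample(chain_length + 1L, 1L)
      ib <- sample(chain_length + 1L, 1L)
      add(sprintf("B%d", k),
          sprintf("M%d_%d => M%d_%d", a, ia, b, ib),
          0, bound, next_genes(1L), "connector")
    }
    metabolic_network(do.call(rbind, rows), default_bound = bound)
  })
}

# gene -> subsystem of the (unique) reaction whose GPR mentions it
gene_pathways <- function(network) {
  out <- character(0)
  for (j in seq_len(nrow(network$reactions))) {
    gs <- gpr_genes(network$gpr_trees[[j]])
    gs <- setdiff(gs, names(out))
    if (length(gs)) {
      out[gs] <- network$reactions$subsystem[j]
    }
  }
  out
}

#' Plant expression strata over a network
#'
#' Emits a gene x sample FPKM table in which genes of each sample's "on"
#' pathways draw from a high stratum, genes of "off" pathways from a low
#' stratum, and everything else (including background genes outside the
#' model) from a middle stratum. At `noise_sd = 0` the strata are constant
#' and separated by wide gaps, so the per-sample 15\%/15\% quantile
#' discretization recovers the planted gene states exactly: the quantile
#' cutoff always falls on the (tied) middle stratum and the tie rule drops
#' tied genes to moderate, leaving precisely the planted extremes. The
#' generator refuses plans whose extreme strata would exceed the nominal
#' quantile fractions, and checks by linear programming that the planted
#' reaction states are realizable as a steady-state flux (all planted-high
#' reactions at `|v| >= epsilon`, planted-low at 0) — an unrealizable plan
#' fails at generation time, naming the sample.
#'
#' @param network a [metabolic_network] (typically from [make_network()]).
#' @param samples character vector of sample ids.
#' @param active_plan named list, one entry per sample, each a list with
#'   character elements `on` and `off` naming subsystems.
#' @param noise_sd Gaussian noise (FPKM units) added to the strata,
#'   truncated at 0.
#' @param seed integer seed.
#' @param n_background_genes extra non-model genes in the middle stratum.
#' @param strata named numeric `c(low=, mid=, high=)` FPKM levels.
#' @param low_q,high_q discretization fractions the plan must respect.
#' @param epsilon activation threshold used in the realizability check.
#' @return list with `expression` (gene x sample matrix) and `truth`
#'   (per-sample planted `gene_states`, `r_high`, `r_low`, plus the strata
#'   and plan).
#' @export
plant_expression <- function(network, samples, active_plan, noise_sd = 0,
                             seed = 1, n_background_genes = 50,
                             strata = c(low = 2, mid = 50, high = 500),
                             low_q = 0.15, high_q = 0.15, epsilon = 1) {
  stopifnot(inherits(network, "metabolic_network"), noise_sd >= 0)
  if (!all(samples %in% names(active_plan))) {
    stop("active_plan must have an entry per sample", call. = FALSE)
  }
  gp <- gene_pathways(network)
  subsystems <- unique(network$reactions$subsystem)
  for (s in samples) {
    bad <- setdiff(c(active_plan[[s]]$on, active_plan[[s]]$off), subsystems)
    if (length(bad)) {
      stop("sample ", s, ": unknown pathway(s) in plan: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  genes <- c(names(gp),
             if (n_background_genes > 0)
               sprintf("bg_%03d", seq_len(n_background_genes)))
  n <- length(genes)
  k_hi <- ceiling(high_q * n)
  k_lo <- ceiling(low_q * n)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  ids <- reaction_ids(network)

  with_seed(seed, {
    expr <- matrix(0, n, length(samples), dimnames = list(genes, samples))
    truth_samples <- list()
    for (s in samples) {
      on <- active_plan[[s]]$on %||% character()
      off <- active_plan[[s]]$off %||% character()
      stratum <- rep("mid", n)
      names(stratum) <- genes
      stratum[names(gp)[gp %in% on]] <- "high"
      stratum[names(gp)[gp %in% off]] <- "low"
      if (sum(stratum == "high") > k_hi) {
        stop("sample ", s, ": ", sum(stratum == "high"), " planted high ",
             "genes exceed the top-quantile capacity of ", k_hi,
             call. = FALSE)
      }
      if (sum(stratum == "low") > k_lo) {
        stop("sample ", s, ": ", sum(stratum == "low"), " planted low ",
             "genes exceed the bottom-quantile capacity of ", k_lo,
             call. = FALSE)
      }
      v <- strata[stratum]
      if (noise_sd > 0) v <- pmax(0, v + stats::rnorm(n, sd = noise_sd))
      expr[, s] <- v
      gstate <- stats::setNames(integer(n), genes)
      gstate[stratum == "high"] <- 1L
      gstate[stratum == "low"] <- -1L
      rstates <- reaction_states(network, gstate[names(gp)])
      r_high <- ids[rstates == 1L]
      r_low <- ids[rstates == -1L]
      lb2 <- lb
      ub2 <- ub
      lb2[match(r_high, ids)] <- pmax(lb2[match(r_high, ids)], epsilon)
      lb2[match(r_low, ids)] <- 0
      ub2[match(r_low, ids)] <- 0
      if (length(r_high) && any(ub2[match(r_high, ids)] < epsilon)) {
        stop("sample ", s, ": planted active reactions cannot reach ",
             "epsilon = ", epsilon, call. = FALSE)
      }
      if (!lp_feasible(network$S, rep(0, nrow(network$S)), lb2, ub2)) {
        stop("sample ", s, ": planted reaction states are not realizable ",
             "as a steady-state flux", call. = FALSE)
      }
      truth_samples[[s]] <- list(gene_states = gstate, r_high = r_high,
                                 r_low = r_low)
    }
    list(expression = expr,
         truth = list(samples = truth_samples, strata = strata,
                      plan = active_plan[samples], noise_sd = noise_sd,
                      epsilon = epsilon, seed = seed))
  })
}

#' Generate a full synthetic scenario with planted ground truth
#'
#' Couples [make_network()] and [plant_expression()] into the study layout
#' the pipeline expects: an ordered sample manifest over two stages
#' (`booting` then `mature`), gene and reaction pathway annotations, and a
#' planted design — `pathway_1` active in every sample, `pathway_2` toggled
#' on only in the mature-stage samples (the planted differential pathway,
#' up-regulated from the first booting sample to the first mature sample),
#' `pathway_3` inactive everywhere, remaining chains at background
#' expression. The truth slot records the planted per-sample reaction sets
#' (`r_high`, `r_low`), the differential pair, and the toggled/always-on
#' pathway labels, which is what end-to-end recovery tests assert against.
#'
#' @param seed integer seed driving both network and expression generation.
#' @param n_chains,n_branch_points,reversible_fraction,chain_length passed
#'   to [make_network()].
#' @param n_samples number of samples (>= 2; first half booting, second
#'   half mature).
#' @param noise_sd expression noise; 0 gives exact state recovery.
#' @param n_background_genes extra non-model genes.
#' @param epsilon activation threshold recorded in the truth.
#' @return object of class `flux_scenario`: `network`, `expression`,
#'   `manifest`, `truth`, `gene_annotation`, `reaction_annotation`, `seed`.
#' @export
make_scenario <- function(seed = 1, n_chains = 8, n_branch_points = 2,
                          reversible_fraction = 0.2, chain_length = 4,
                          n_samples = 4, noise_sd = 0,
                          n_background_genes = 50, epsilon = 1) {
  stopifnot(n_chains >= 3, n_samples >= 2)
  network <- make_network(n_linear_chains = n_chains,
                          n_branch_points = n_branch_points,
                          reversible_fraction = reversible_fraction,
                          chain_length = chain_length, seed = seed)
  samples <- sprintf("s%d", seq_len(n_samples))
  n_boot <- ceiling(n_samples / 2)
  stages <- rep(c("booting", "mature"), c(n_boot, n_samples - n_boot))
  plan <- lapply(seq_len(n_samples), function(i) {
    on <- "pathway_1"
    if (stages[i] == "mature") on <- c(on, "pathway_2")
    list(on = on, off = "pathway_3")
  })
  names(plan) <- samples
  planted <- plant_expression(network, samples, plan, noise_sd = noise_sd,
                              seed = seed + 1L,
                              n_background_genes = n_background_genes,
                              epsilon = epsilon)
  manifest <- data.frame(sample_id = samples, stage = stages,
                         order = seq_len(n_samples),
                         stringsAsFactors = FALSE)
  gp <- gene_pathways(network)
  gp <- gp[nzchar(gp)]
  gene_annotation <- rbind(
    data.frame(item_id = names(gp), pathway = unname(gp),
               stringsAsFactors = FALSE),
    if (n_background_genes > 0) {
      data.frame(item_id = sprintf("bg_%03d", seq_len(n_background_genes)),
                 pathway = "background", stringsAsFactors = FALSE)
    })
  keep <- nzchar(network$reactions$subsystem)
  reaction_annotation <- data.frame(
    item_id = network$reactions$id[keep],
    pathway = network$reactions$subsystem[keep], stringsAsFactors = FALSE)
  truth <- planted$truth
  truth$differential <- list(
    sample1 = samples[1L], sample2 = samples[n_boot + 1L],
    pathway = "pathway_2", direction = "up")
  truth$always_on <- "pathway_1"
  truth$toggled <- "pathway_2"
  truth$always_off <- "pathway_3"
  structure(list(network = network, expression = planted$expression,
                 manifest = manifest, truth = truth,
                 gene_annotation = gene_annotation,
                 reaction_annotation = reaction_annotation, seed = seed),
            class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed ", x$seed, "): ",
      nrow(x$network$reactions), " reactions, ",
      nrow(x$expression), " genes, ", ncol(x$expression),
      " samples (", paste(unique(x$manifest$stage), collapse = "/"),
      ")\n", sep = "")
  cat("  toggled pathway: ", x$truth$toggled, " (",
      x$truth$differential$sample1, " -> ", x$truth$differential$sample2,
      " ", x$truth$differential$direction, ")\n", sep = "")
  invisible(x)
}

#' Write a scenario to disk in the pipeline's input formats
#'
#' Emits `model.tsv` (tabular dialect), `expression.tsv`, `manifest.tsv`,
#' `gene_annotation.tsv`, `reaction_annotation.tsv` and `truth.json`.
#'
#' @param scenario a [flux_scenario][make_scenario].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "flux_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    model = file.path(dir, "model.tsv"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    gene_annotation = file.path(dir, "gene_annotation.tsv"),
    reaction_annotation = file.path(dir, "reaction_annotation.tsv"),
    truth = file.path(dir, "truth.json"))
  write_network(scenario$network, paths["model"])
  expr_df <- data.frame(gene_id = rownames(scenario$expression),
                        scenario$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(expr_df, paths["expression"])
  write_tsv(scenario$manifest, paths["manifest"])
  write_tsv(scenario$gene_annotation, paths["gene_annotation"])
  write_tsv(scenario$reaction_annotation, paths["reaction_annotation"])
  jsonlite::write_json(scenario$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
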