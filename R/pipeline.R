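#' Default pipeline configuration
#'
#' Returns the full configuration list with the conventional defaults: the
#' 15\%/15\% discretization fractions, the 2 / 0.5 expression fold-change
#' thresholds, the +/-0.5 flux-change ratio threshold, activation threshold
#' `epsilon = 1`, Euclidean/average clustering, and Benjamini-Hochberg
#' adjusted p-values reported alongside raw ones (significance flagged on
#' raw p < 0.05 by default).
#'
#' @param ... overrides of any default (unknown keys are an error).
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    model = NULL, expression = NULL, manifest = NULL,
    gene_annotation = NULL, reaction_annotation = NULL, outdir = NULL,
    low_q = 0.15, high_q = 0.15,
    epsilon = 1, activity_tol = 1e-6,
    fva_scope = "generic",
    ratio_threshold = 0.5, fc_up = 2, fc_down = 0.5, pseudocount = 1,
    alpha = 0.05, adjust = "none",
    metric = "euclidean", linkage = "average",
    time_limit = 60, seed = 1,
    enrich = TRUE, pairs = NULL,
    log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' coerced to numeric or logical where possible. Keys must be known
#' configuration fields.
#'
#' @param path configuration file.
#' @return a [run_config][pipeline_config] list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 0L) stop("bad config line: '", ln, "'", call. = FALSE)
    key <- m[2L]
    val <- trimws(m[3L])
    if (grepl("^-?[0-9.eE+-]+$", val) &&
        !is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    } else if (tolower(val) %in% c("true", "false")) {
      val <- tolower(val) == "true"
    }
    kv[[key]] <- val
  }
  do.call(pipeline_config, kv)
}

config_hash <- function(cfg) {
  keys <- sort(names(cfg))
  dump <- vapply(keys, function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (is.null(v)) "" else paste(format(v), collapse = ","))
  }, "")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(dump, tf)
  unname(tools::md5sum(tf))
}

#' Run the full expression-to-flux pipeline
#'
#' Executes, in order: expression discretization; GPR-based reaction
#' states and the iMAT model extraction per sample; flux variability
#' analysis; the comparative statistics (total variation ranking,
#' FVA-normalized flux changes and expression fold changes per compared
#' pair, rate-limiting detection, active-set overlap, hierarchical
#' clustering of the flux matrix); and hypergeometric pathway enrichment
#' of the differential and rate-limiting sets. Every intermediate is
#' written to `outdir` as TSV/JSON carrying the configuration hash in a
#' header comment, so reruns with an identical configuration are
#' byte-identical (the MILP optimum is canonicalized). A machine-readable
#' run manifest closes the run.
#'
#' @param config a [run_config][pipeline_config] list or the path of a
#'   key=value configuration file. Required fields: `model`, `expression`,
#'   `manifest`, `outdir`; `gene_annotation` is required when `enrich` is
#'   `TRUE` (checked before any solving).
#' @return invisibly, a list with `artifacts` (named file paths), `config`,
#'   `hash`, the fitted `models`, the `flux_matrix` and the fva table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) {
    config <- do.call(pipeline_config, config)
  }
  log_msg <- function(...) {
    if (!identical(config$log_level, "quiet")) {
      message("[fluxshift] ", ...)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # fail fast on configuration problems, before any solving
  for (field in c("model", "expression", "manifest", "outdir")) {
    if (is.null(config[[field]])) {
      stop("config field '", field, "' is required", call. = FALSE)
    }
  }
  for (field in c("model", "expression", "manifest", "gene_annotation",
                  "reaction_annotation")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config field '", field, "': no such file: ", p, call. = FALSE)
    }
  }
  if (isTRUE(config$enrich) && is.null(config$gene_annotation)) {
    stop("enrichment requested but no gene_annotation file configured",
         call. = FALSE)
  }
  hash <- config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  out <- function(name) {
    p <- file.path(config$outdir, name)
    art[[name]] <<- p
    p
  }

  log_msg("reading inputs (config ", hash, ")")
  network <- stage("read_network", read_network(config$model))
  expr <- stage("read_expression", read_expression(config$expression))
  manifest <- stage("read_manifest", {
    mf <- read_tsv(config$manifest)
    need <- c("sample_id", "stage", "order")
    if (!all(need %in% names(mf))) {
      stop("manifest needs columns ", paste(need, collapse = ", "))
    }
    mf[order(mf$order), , drop = FALSE]
  })
  samples <- manifest$sample_id
  missing <- setdiff(samples, colnames(expr))
  if (length(missing)) {
    stop("manifest sample(s) absent from expression table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  log_msg("discretizing expression (", config$low_q * 100, "% / ",
          config$high_q * 100, "%)")
  states <- stage("discretize",
                  discretize(expr[, samples, drop = FALSE],
                             low_q = config$low_q, high_q = config$high_q))
  write_states(states, out("expression_states.tsv"), hdr)

  log_msg("extracting tissue models (iMAT, epsilon ", config$epsilon, ")")
  ids <- reaction_ids(network)
  models <- list()
  flux_matrix <- matrix(0, length(ids), length(samples),
                        dimnames = list(ids, samples))
  rstate_rows <- list()
  for (s in samples) {
    rs <- stage("reaction_states", reaction_states(network, states, s))
    rstate_rows[[s]] <- data.frame(reaction_id = ids, sample = s,
                                   state = unname(rs),
                                   stringsAsFactors = FALSE)
    fit <- stage("imat", imat(network, rs, epsilon = config$epsilon,
                              time_limit = config$time_limit,
                              activity_tol = config$activity_tol))
    if (!identical(fit$status, "optimal")) {
      stop("stage 'imat' failed: sample ", s, " ended with status ",
           fit$status, call. = FALSE)
    }
    tm <- extract_tissue_model(network, fit, s,
                               activity_tol = config$activity_tol)
    models[[s]] <- tm
    flux_matrix[, s] <- fit$fluxes[ids]
    jsonlite::write_json(
      list(tissue = s, objective = fit$objective, epsilon = fit$epsilon,
           satisfied_high = fit$satisfied_high,
           satisfied_low = fit$satisfied_low,
           active_reactions = tm$active_reactions,
           fluxes = as.list(fit$fluxes)),
      out(paste0("tissue_model_", s, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("  ", s, ": objective ", fit$objective, ", ",
            length(tm$active_reactions), " active reactions")
  }
  write_tsv(do.call(rbind, rstate_rows), out("reaction_states.tsv"), hdr)
  write_tsv(data.frame(reaction_id = ids, flux_matrix,
                       check.names = FALSE, stringsAsFactors = FALSE),
            out("flux_matrix.tsv"), hdr)

  log_msg("flux variability analysis (scope: ", config$fva_scope, ")")
  fva_tab <- stage("fva", {
    if (identical(config$fva_scope, "union")) {
      inactive_everywhere <- ids[rowSums(abs(flux_matrix) >
                                           config$activity_tol) == 0L]
      fc <- stats::setNames(
        lapply(inactive_everywhere, function(r) c(0, 0)),
        inactive_everywhere)
      fva(network, fixed_constraints = fc)
    } else {
      fva(network)
    }
  })
  write_tsv(fva_tab, out("fva.tsv"), hdr)

  log_msg("total variation across the tissue series")
  tv_tab <- stage("total_variation",
                  rank_fluctuating_reactions(flux_matrix, order = samples))
  write_tsv(tv_tab, out("total_variation.tsv"), hdr)

  # compared pairs: config$pairs as "a:b,c:d", else consecutive manifest pairs
  pairs <- stage("pairs", {
    if (is.null(config$pairs)) {
      if (length(samples) >= 2L) {
        lapply(seq_len(length(samples) - 1L),
               function(i) samples[c(i, i + 1L)])
      } else {
        list()
      }
    } else if (is.character(config$pairs) && length(config$pairs) == 1L) {
      lapply(strsplit(config$pairs, ",")[[1L]], function(p) {
        pair <- trimws(strsplit(p, ":")[[1L]])
        if (length(pair) != 2L) stop("bad pair spec: '", p, "'")
        pair
      })
    } else {
      config$pairs
    }
  })
  for (pair in pairs) {
    if (!all(pair %in% samples)) {
      stop("compared pair (", paste(pair, collapse = ", "),
           ") not in the manifest", call. = FALSE)
    }
  }

  gene_ann <- NULL
  rxn_ann <- NULL
  if (isTRUE(config$enrich)) {
    gene_ann <- stage("gene_annotation", {
      df <- read_tsv(config$gene_annotation)
      universe <- rownames(expr)
      df <- df[df$item_id %in% universe, , drop = FALSE]
      pathway_annotation(df, universe = universe)
    })
    rxn_ann <- stage("reaction_annotation", {
      if (!is.null(config$reaction_annotation)) {
        pathway_annotation(read_tsv(config$reaction_annotation),
                           universe = ids)
      } else {
        keep <- nzchar(network$reactions$subsystem)
        pathway_annotation(
          data.frame(item_id = ids[keep],
                     pathway = network$reactions$subsystem[keep],
                     stringsAsFactors = FALSE),
          universe = ids)
      }
    })
  }

  enr_rows <- list()
  for (pair in pairs) {
    a <- pair[1L]
    b <- pair[2L]
    tag <- paste0(a, "_vs_", b)
    log_msg("comparing ", a, " -> ", b)
    gfc <- stage("gene_fold_changes",
                 gene_fold_changes(expr, a, b,
                                   pseudocount = config$pseudocount,
                                   up_threshold = config$fc_up,
                                   down_threshold = config$fc_down))
    write_tsv(gfc, out(paste0("gene_fold_changes_", tag, ".tsv")), hdr)
    fch <- stage("flux_change",
                 flux_change(flux_matrix[, a], flux_matrix[, b],
                             fva_tab, threshold = config$ratio_threshold))
    write_tsv(fch, out(paste0("flux_changes_", tag, ".tsv")), hdr)
    if (isTRUE(config$enrich)) {
      sel <- list(
        gene_up = gfc$gene_id[gfc$call == "up"],
        gene_down = gfc$gene_id[gfc$call == "down"],
        flux_up = fch$reaction_id[fch$call == "up"],
        flux_down = fch$reaction_id[fch$call == "down"],
        newly_active = setdiff(models[[b]]$active_reactions,
                               models[[a]]$active_reactions))
      for (nm in names(sel)) {
        ann <- if (startsWith(nm, "gene")) gene_ann else rxn_ann
        res <- stage(paste0("enrich_", nm),
                     suppressWarnings(
                       enrich(sel[[nm]], ann, direction = nm,
                              alpha = config$alpha,
                              adjust = if (identical(config$adjust, "BH"))
                                "BH" else "none")))
        res$pair <- tag
        enr_rows[[paste(tag, nm)]] <- res
      }
    }
  }
  if (length(enr_rows)) {
    write_tsv(do.call(rbind, enr_rows), out("enrichment.tsv"), hdr)
  }

  log_msg("rate-limiting reactions")
  rl_rows <- list()
  for (s in samples) {
    rl <- stage("rate_limiting", rate_limiting(models[[s]], network))
    if (length(rl)) {
      rl_rows[[s]] <- data.frame(
        tissue = s, reaction_id = rl,
        flux = unname(flux_matrix[rl, s]),
        bound = network$reactions$upper_bound[match(rl, ids)],
        stringsAsFactors = FALSE)
    }
    if (isTRUE(config$enrich) && length(rl)) {
      res <- stage("enrich_rate_limiting",
                   enrich(rl, rxn_ann,
                          direction = paste0("rate_limiting_", s),
                          alpha = config$alpha))
      res$pair <- s
      enr_rows[[paste("rl", s)]] <- res
    }
  }
  rl_df <- if (length(rl_rows)) {
    do.call(rbind, rl_rows)
  } else {
    data.frame(tissue = character(), reaction_id = character(),
               flux = numeric(), bound = numeric())
  }
  write_tsv(rl_df, out("rate_limiting.tsv"), hdr)
  if (length(enr_rows)) {  # rewrite including rate-limiting enrichments
    write_tsv(do.call(rbind, enr_rows), out("enrichment.tsv"), hdr)
  }

  log_msg("active-set overlap and clustering")
  ov <- stage("overlap", active_set_overlap(models))
  write_tsv(data.frame(region = names(ov), count = unname(ov),
                       stringsAsFactors = FALSE),
            out("active_overlap.tsv"), hdr)
  cl <- stage("clustering",
              cluster_patterns(flux_matrix, axis = "columns",
                               metric = config$metric,
                               linkage = config$linkage))
  writeLines(c(paste0("# ", hdr), cl$newick),
             out("clustering_tissues.newick"))
  write_tsv(data.frame(merge = seq_along(cl$heights), height = cl$heights,
                       metric = cl$metric, linkage = cl$linkage,
                       stringsAsFactors = FALSE),
            out("clustering_heights.tsv"), hdr)

  run_manifest <- list(
    package = "fluxshift",
    version = as.character(utils::packageVersion("fluxshift")),
    config_hash = hash,
    seed = config$seed,
    config = config[setdiff(names(config), "pairs")],
    pairs = vapply(pairs, paste, "", collapse = ":"),
    samples = samples,
    artifacts = as.list(art))
  jsonlite::write_json(run_manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_msg("done: ", length(art), " artifacts in ", config$outdir)
  invisible(list(artifacts = art, config = config, hash = hash,
                 models = models, flux_matrix = flux_matrix,
                 fva = fva_tab, states = states,
                 enrichment = if (length(enr_rows))
                   do.call(rbind, enr_rows)))
}
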