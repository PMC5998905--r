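#' Metabolic network container
#'
#' A `metabolic_network` holds a stoichiometric model: metabolites,
#' reactions with flux bounds and gene-protein-reaction (GPR) rules,
#' subsystem (pathway) labels, and the metabolites x reactions
#' stoichiometric matrix S used by all flux computations (steady state is
#' `S %*% v == 0`). Flux bounds default to the conventional range
#' `[-1000, 1000]` for reversible reactions and `[0, 1000]` for
#' irreversible ones.
#'
#' `reactions` is a data frame in the tabular model dialect with columns
#' `reaction_id`, `equation`, `lower_bound`, `upper_bound`, `gpr`,
#' `subsystem`. Equations use `a A + b B <=> c C` (`=>` for irreversible);
#' metabolite identifiers may carry a compartment suffix such as `[c]`.
#' Missing bounds (`NA`) take the defaults above. Exchange reactions are
#' detected as single-metabolite reactions or by identifier prefix
#' (`exchange_prefix`, default `"EX_"`).
#'
#' @param reactions data frame in the tabular dialect (see Details).
#' @param metabolites optional data frame with columns `id`, `name`,
#'   `compartment`; inferred from equations when omitted.
#' @param exchange_prefix reaction-id prefix marking exchange reactions.
#' @param default_bound magnitude of the default flux bounds.
#' @return an object of class `metabolic_network`.
#' @examples
#' rxns <- data.frame(
#'   reaction_id = c("EX_a", "R1", "EX_b"),
#'   equation = c("=> A[c]", "A[c] => B[c]", "B[c] =>"),
#'   lower_bound = NA, upper_bound = NA,
#'   gpr = c("", "g1 and g2", ""), subsystem = c("", "glycolysis", ""))
#' net <- metabolic_network(rxns)
#' net
#' @export
metabolic_network <- function(reactions, metabolites = NULL,
                              exchange_prefix = "EX_",
                              default_bound = 1000) {
  req <- c("reaction_id", "equation")
  if (!all(req %in% names(reactions))) {
    stop("reactions must have columns 'reaction_id' and 'equation'",
         call. = FALSE)
  }
  n <- nrow(reactions)
  get_col <- function(name, default) {
    if (name %in% names(reactions)) reactions[[name]] else rep(default, n)
  }
  lb <- as.numeric(get_col("lower_bound", NA_real_))
  ub <- as.numeric(get_col("upper_bound", NA_real_))
  gpr <- as.character(get_col("gpr", ""))
  gpr[is.na(gpr)] <- ""
  subsystem <- as.character(get_col("subsystem", ""))
  subsystem[is.na(subsystem)] <- ""

  parsed <- lapply(seq_len(n), function(i) {
    tryCatch(parse_equation(reactions$equation[i]),
             error = function(e) {
               stop("reaction '", reactions$reaction_id[i], "' (row ", i,
                    "): ", conditionMessage(e), call. = FALSE)
             })
  })
  rev_flag <- vapply(parsed, `[[`, TRUE, "reversible")
  lb[is.na(lb)] <- ifelse(rev_flag[is.na(lb)], -default_bound, 0)
  ub[is.na(ub)] <- default_bound

  new_metabolic_network(
    ids = as.character(reactions$reaction_id),
    stoich = lapply(parsed, `[[`, "stoich"),
    lb = lb, ub = ub, gpr = gpr, subsystem = subsystem,
    metabolites = metabolites, exchange_prefix = exchange_prefix)
}

# Core validated constructor shared by the tabular and SBML paths.
new_metabolic_network <- function(ids, stoich, lb, ub, gpr, subsystem,
                                  metabolites = NULL,
                                  exchange_prefix = "EX_") {
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty reaction id", call. = FALSE)
  if (any(lb > ub)) {
    stop("lower_bound > upper_bound for reaction: ",
         paste(ids[lb > ub], collapse = ", "), call. = FALSE)
  }
  is_exch <- startsWith(ids, exchange_prefix) |
    vapply(stoich, length, 0L) == 1L
  empty <- vapply(stoich, length, 0L) == 0L
  if (any(empty & !is_exch)) {
    stop("empty stoichiometry for non-exchange reaction: ",
         paste(ids[empty & !is_exch], collapse = ", "), call. = FALSE)
  }
  met_ids <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  if (!is.null(metabolites)) {
    missing <- setdiff(met_ids, metabolites$id)
    if (length(missing)) {
      stop("metabolite(s) referenced but not declared: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    met_df <- data.frame(id = as.character(metabolites$id),
                         name = as.character(metabolites$name %||%
                                               metabolites$id),
                         compartment =
                           as.character(metabolites$compartment %||% ""),
                         stringsAsFactors = FALSE)
    if (anyDuplicated(met_df$id)) {
      stop("duplicate metabolite id", call. = FALSE)
    }
  } else {
    comp <- sub("^.*\\[([^][]*)\\]$", "\\1", met_ids)
    comp[comp == met_ids] <- ""
    met_df <- data.frame(id = met_ids, name = met_ids, compartment = comp,
                         stringsAsFactors = FALSE)
  }
  if (any(!nzchar(met_df$id))) stop("empty metabolite id", call. = FALSE)

  S <- matrix(0, nrow = nrow(met_df), ncol = length(ids),
              dimnames = list(met_df$id, ids))
  for (j in seq_along(ids)) {
    sj <- stoich[[j]]
    if (length(sj)) S[names(sj), j] <- sj
  }
  trees <- lapply(gpr, parse_gpr)
  names(trees) <- ids
  genes <- sort(unique(unlist(lapply(trees, gpr_genes), use.names = FALSE)))

  structure(list(
    reactions = data.frame(
      id = ids, lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = subsystem, is_exchange = is_exch,
      reversible = lb < 0, stringsAsFactors = FALSE),
    stoichiometry = stats::setNames(stoich, ids),
    metabolites = met_df,
    genes = genes,
    gpr_trees = trees,
    S = S,
    exchange_prefix = exchange_prefix
  ), class = "metabolic_network")
}

# "a A[c] + 2 B => C" -> list(stoich = c(`A[c]` = -1, B = -2, C = 1),
# reversible = FALSE). Either side may be empty (exchange reactions).
parse_equation <- function(eq) {
  eq <- trimws(as.character(eq))
  if (grepl("<=>", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "<=>", fixed = TRUE)[[1L]]
    reversible <- TRUE
  } else if (grepl("=>", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "=>", fixed = TRUE)[[1L]]
    reversible <- FALSE
  } else {
    stop("equation lacks '=>' or '<=>': '", eq, "'")
  }
  if (length(sides) > 2L) stop("equation has more than one arrow: '", eq, "'")
  lhs <- parse_side(if (length(sides) >= 1L) sides[1L] else "")
  rhs <- parse_side(if (length(sides) == 2L) sides[2L] else "")
  stoich <- c(-lhs, rhs)
  if (anyDuplicated(names(stoich))) {
    # metabolite on both sides: net coefficient
    stoich <- tapply(stoich, names(stoich), sum)
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  }
  stoich <- stoich[stoich != 0]
  list(stoich = stoich, reversible = reversible)
}

parse_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(side, "\\s*\\+\\s+|\\s+\\+\\s*")[[1L]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  out <- numeric(0)
  for (term in terms) {
    m <- regmatches(term,
      regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", term))[[1L]]
    if (length(m) == 0L) stop("cannot parse equation term '", term, "'")
    coef <- if (nzchar(trimws(m[2L]))) as.numeric(trimws(m[2L])) else 1
    out <- c(out, stats::setNames(coef, m[3L]))
  }
  out
}

#' Read a metabolic model file
#'
#' Reads either the tabular dialect (TSV with columns `reaction_id`,
#' `equation`, `lower_bound`, `upper_bound`, `gpr`, `subsystem`) or an SBML
#' Level 3 document with the FBC package (flux bounds through parameter
#' references, GPR rules through `fbc:geneProductAssociation`; a COBRA-style
#' `SUBSYSTEM:` line inside reaction notes is honoured when present).
#'
#' @param path model file.
#' @param dialect `"tabular"` or `"sbml"`; `NULL` guesses from the file
#'   extension (`.xml`/`.sbml` means SBML).
#' @inheritParams metabolic_network
#' @return a [metabolic_network].
#' @export
read_network <- function(path, dialect = NULL, exchange_prefix = "EX_",
                         default_bound = 1000) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else {
      "tabular"
    }
  }
  dialect <- match.arg(dialect, c("tabular", "sbml"))
  if (dialect == "sbml") {
    return(read_sbml_network(path, exchange_prefix = exchange_prefix,
                             default_bound = default_bound))
  }
  df <- read_tsv(path)
  need <- c("reaction_id", "equation", "lower_bound", "upper_bound",
            "gpr", "subsystem")
  if (!all(need %in% names(df))) {
    stop("tabular model '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  metabolic_network(df, exchange_prefix = exchange_prefix,
                    default_bound = default_bound)
}

#' Write a metabolic network in the tabular dialect
#'
#' @param network a [metabolic_network].
#' @param path output TSV path.
#' @param header optional character vector of comment lines.
#' @export
write_network <- function(network, path, header = character()) {
  stopifnot(inherits(network, "metabolic_network"))
  eqs <- vapply(network$reactions$id, function(id) {
    s <- network$stoichiometry[[id]]
    arrow <- if (network$reactions$reversible[network$reactions$id == id]) {
      "<=>"
    } else {
      "=>"
    }
    fmt <- function(v) {
      paste(vapply(names(v), function(mm) {
        coef <- abs(v[[mm]])
        if (coef == 1) mm else paste(format(coef), mm)
      }, ""), collapse = " + ")
    }
    lhs <- fmt(s[s < 0])
    rhs <- fmt(s[s > 0])
    trimws(paste(lhs, arrow, rhs))
  }, "")
  df <- data.frame(reaction_id = network$reactions$id, equation = eqs,
                   lower_bound = network$reactions$lower_bound,
                   upper_bound = network$reactions$upper_bound,
                   gpr = network$reactions$gpr,
                   subsystem = network$reactions$subsystem,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}

# --- minimal SBML L3 + FBC reader -------------------------------------------

read_sbml_network <- function(path, exchange_prefix = "EX_",
                              default_bound = 1000) {
  doc <- xml2::read_xml(path)
  find_all <- function(node, name) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  }
  attr_local <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
    if (length(hit)) at[[hit[1L]]] else NA_character_
  }

  params <- find_all(doc, "parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gp <- find_all(doc, "geneProduct")
  glabel <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp, "label")),
           vapply(gp, attr_local, "", "id"),
           xml2::xml_attr(gp, "label")),
    vapply(gp, attr_local, "", "id"))

  sp <- find_all(doc, "species")
  met_df <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE)

  gpr_from_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_local(node, "geneProduct")
      lab <- glabel[ref]
      return(if (is.na(lab)) ref else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_from_assoc, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- find_all(doc, "reaction")
  ids <- xml2::xml_attr(rx, "id")
  n <- length(ids)
  stoich <- vector("list", n)
  lb <- ub <- numeric(n)
  gpr <- subsystem <- character(n)
  for (j in seq_len(n)) {
    node <- rx[[j]]
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lbid <- attr_local(node, "lowerFluxBound")
    ubid <- attr_local(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]]
             else if (reversible) -default_bound else 0
    ub[j] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]]
             else default_bound
    s <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- find_all(xml2::xml_find_first(
        node, paste0("./*[local-name()='", side, "']")), "speciesReference")
      if (length(refs)) {
        coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        coef[is.na(coef)] <- 1
        s <- c(s, stats::setNames(sgn * coef, xml2::xml_attr(refs, "species")))
      }
    }
    if (anyDuplicated(names(s))) {
      s <- stats::setNames(as.numeric(tapply(s, names(s), sum)),
                           unique(names(s)))
    }
    stoich[[j]] <- s[s != 0]
    ga <- xml2::xml_find_first(
      node, ".//*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(ga, "xml_node")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) gpr_from_assoc(kids[[1L]]) else ""
    } else {
      ""
    }
    notes <- xml2::xml_find_first(node, ".//*[local-name()='notes']")
    subsystem[j] <- if (inherits(notes, "xml_node")) {
      m <- regmatches(xml2::xml_text(notes),
                      regexpr("SUBSYSTEM:\\s*[^\n<]*",
                              xml2::xml_text(notes)))
      if (length(m)) trimws(sub("SUBSYSTEM:\\s*", "", m)) else ""
    } else {
      ""
    }
  }
  new_metabolic_network(ids = ids, stoich = stoich, lb = lb, ub = ub,
                        gpr = gpr, subsystem = subsystem,
                        metabolites = met_df,
                        exchange_prefix = exchange_prefix)
}

# --- accessors and methods ---------------------------------------------------

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (", sum(x$reactions$is_exchange),
      " exchange, ", sum(x$reactions$reversible), " reversible), ",
      length(x$genes), " genes, ",
      length(setdiff(unique(x$reactions$subsystem), "")),
      " subsystems\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a network
#' @param network a [metabolic_network].
#' @return numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  network$S
}

#' @rdname stoichiometric_matrix
#' @export
reaction_ids <- function(network) network$reactions$id

reaction_bounds <- function(network) {
  list(lb = network$reactions$lower_bound,
       ub = network$reactions$upper_bound)
}

# short fingerprint used to check that tissue models share a network
network_fingerprint <- function(network) {
  paste0(nrow(network$reactions), ":",
         paste(network$reactions$id, collapse = ","))
}
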