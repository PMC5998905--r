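#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are annotated.
#' Computed through the survival function of [stats::phyper()], which
#' works in log space and is numerically stable.
#'
#' @param k observed overlap (successes).
#' @param n selection (draw) size.
#' @param K annotated items in the universe (category size).
#' @param N universe size.
#' @return probability in `(0, 1]`.
#' @examples
#' hypergeometric_tail(4, 5, 5, 20)  # 76/15504
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  ok <- k >= 0 & n >= k & N >= n & K <= N & K >= k
  if (!all(ok)) {
    stop("need 0 <= k <= min(n, K) and n, K <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Flat pathway annotation
#'
#' Maps items (genes or reactions) to pathway labels over a stated
#' universe. Items may carry several labels; each pathway is tested
#' independently. The universe defaults to the annotated items but should
#' normally be supplied explicitly (all model genes present in the
#' expression table for gene sets, all network reactions for reaction
#' sets).
#'
#' @param item_id character vector of item identifiers (or a data frame
#'   with columns `item_id` and `pathway`).
#' @param pathway pathway label per item.
#' @param universe character vector of all eligible items; must contain
#'   every annotated item.
#' @return object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(item_id, pathway = NULL, universe = NULL) {
  if (is.data.frame(item_id)) {
    df <- item_id
    if (!all(c("item_id", "pathway") %in% names(df))) {
      stop("annotation data frame needs columns 'item_id' and 'pathway'",
           call. = FALSE)
    }
  } else {
    df <- data.frame(item_id = as.character(item_id),
                     pathway = as.character(pathway),
                     stringsAsFactors = FALSE)
  }
  df <- unique(df[, c("item_id", "pathway")])
  if (any(!nzchar(df$pathway) | is.na(df$pathway))) {
    stop("pathway labels must be non-empty", call. = FALSE)
  }
  universe <- universe %||% unique(df$item_id)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(df$item_id, universe)
  if (length(outside)) {
    stop("annotated item(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(map = df, universe = unique(as.character(universe))),
            class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat("Pathway annotation: ", length(unique(x$map$item_id)),
      " annotated items, ", length(unique(x$map$pathway)),
      " pathways, universe ", length(x$universe), "\n", sep = "")
  invisible(x)
}

#' Hypergeometric pathway enrichment of an item set
#'
#' Tests every pathway for over-representation in a selection (for
#' example the up-regulated genes of a tissue pair, the rate-limiting
#' reactions of a tissue model, or an active-reaction set) with the
#' upper-tail hypergeometric test. Raw p-values are reported with a
#' Benjamini-Hochberg adjusted column alongside; the `significant` flag
#' uses the raw p-value against `alpha` by default, with
#' `adjust = "BH"` switching the flag to the adjusted value.
#'
#' @param selection character vector of selected item ids (must lie in the
#'   annotation universe).
#' @param annotation a [pathway_annotation].
#' @param direction free-text label carried into the result (`"up"`,
#'   `"down"`, ...).
#' @param alpha significance level.
#' @param adjust `"none"` (flag on raw p) or `"BH"` (flag on adjusted p).
#' @return data frame sorted by ascending p-value (ties by pathway label):
#'   `pathway`, `direction`, `k`, `n`, `K`, `N`, `p_value`, `adjusted_p`,
#'   `significant`.
#' @export
enrich <- function(selection, annotation, direction = "other",
                   alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  adjust <- match.arg(adjust)
  universe <- annotation$universe
  selection <- unique(as.character(selection))
  outside <- setdiff(selection, universe)
  if (length(outside)) {
    stop("selection item(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  if (!length(selection)) {
    warning("empty selection: all p-values are 1")
  }
  N <- length(universe)
  n <- length(selection)
  paths <- sort(unique(annotation$map$pathway))
  res <- lapply(paths, function(pw) {
    members <- unique(annotation$map$item_id[annotation$map$pathway == pw])
    K <- length(members)
    k <- length(intersect(selection, members))
    data.frame(pathway = pw, direction = direction, k = k, n = n, K = K,
               N = N, p_value = hypergeometric_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- if (adjust == "BH") {
    out$adjusted_p < alpha
  } else {
    out$p_value < alpha
  }
  out[order(out$p_value, out$pathway), , drop = FALSE]
}
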