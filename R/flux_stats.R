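#' Total variation of a flux series
#'
#' Sum of absolute consecutive differences of a reaction's flux across an
#' ordered series of tissue models: for fluxes `f_1, ..., f_k` the total
#' variation is `sum(|f_i - f_{i-1}|)` over the `k - 1` consecutive pairs.
#' Larger values mean a more remarkable fluctuation of that reaction across
#' the series. The statistic is order-dependent, so callers supply the
#' tissue order explicitly (the manifest order by convention).
#'
#' @param series numeric vector of fluxes in tissue order, length >= 2.
#' @return non-negative scalar; 0 iff the series is constant.
#' @examples
#' total_variation(c(5, 3, 8))  # |3-5| + |8-3| = 7
#' @export
total_variation <- function(series) {
  if (length(series) < 2L) {
    stop("total variation needs at least two values", call. = FALSE)
  }
  if (any(!is.finite(series))) stop("fluxes must be finite", call. = FALSE)
  sum(abs(diff(series)))
}

#' Rank reactions by flux fluctuation across tissues
#'
#' Computes [total_variation()] per reaction over the columns of a flux
#' matrix taken in a supplied tissue order, and ranks descending. Ties are
#' broken lexicographically by reaction id.
#'
#' @param flux_matrix reactions x tissues numeric matrix with dimnames.
#'   Reactions absent from a tissue model carry flux 0 there.
#' @param order character vector of tissue (column) names defining the
#'   series order; defaults to column order.
#' @return data frame `reaction_id`, `total_variation`, `rank`.
#' @export
rank_fluctuating_reactions <- function(flux_matrix, order = NULL) {
  order <- order %||% colnames(flux_matrix)
  if (!all(order %in% colnames(flux_matrix))) {
    stop("unknown tissue(s) in order: ",
         paste(setdiff(order, colnames(flux_matrix)), collapse = ", "),
         call. = FALSE)
  }
  m <- flux_matrix[, order, drop = FALSE]
  tv <- apply(m, 1L, total_variation)
  ord <- order(-tv, rownames(m))
  data.frame(reaction_id = rownames(m)[ord],
             total_variation = unname(tv[ord]),
             rank = seq_along(tv), stringsAsFactors = FALSE)
}

#' FVA-normalized flux-change ratio between two tissues
#'
#' Because reversible reactions can carry negative flux, a plain fold
#' change is unsuitable at the flux level. Instead the difference of
#' absolute fluxes is normalized by the reaction's flux-variability range:
#' `ratio = (|flux2| - |flux1|) / (maxflux - minflux)`. A reaction with
#' `ratio > threshold` (default 0.5) is called up-regulated, with
#' `ratio < -threshold` down-regulated, otherwise unchanged. A degenerate
#' variability range (`maxflux == minflux`, e.g. a blocked or pinned
#' reaction) yields `ratio = NA` and the call `"undefined"` — never a
#' division error.
#'
#' All arguments are vectorized over reactions.
#'
#' @param flux1,flux2 fluxes in the two compared tissue models.
#' @param minflux,maxflux flux variability range from [fva()] (an
#'   `fva_range` data frame may be passed as `minflux`, in which case
#'   `maxflux` is taken from it).
#' @param reaction_id optional reaction labels.
#' @param threshold call threshold on the ratio.
#' @return data frame of class `flux_change`: `reaction_id`, `flux1`,
#'   `flux2`, `minflux`, `maxflux`, `ratio`, `call`.
#' @examples
#' flux_change(2, 8, 0, 10)     # ratio 0.6 -> up
#' flux_change(-8, 2, -10, 10)  # ratio -0.3 -> unchanged
#' @export
flux_change <- function(flux1, flux2, minflux, maxflux = NULL,
                        reaction_id = NULL, threshold = 0.5) {
  if (inherits(minflux, "fva_range") ||
      (is.data.frame(minflux) && all(c("minflux", "maxflux") %in%
                                       names(minflux)))) {
    fva_tab <- minflux
    reaction_id <- reaction_id %||% fva_tab$reaction_id
    maxflux <- fva_tab$maxflux
    minflux <- fva_tab$minflux
  }
  k <- max(length(flux1), length(flux2), length(minflux), length(maxflux))
  flux1 <- rep_len(flux1, k)
  flux2 <- rep_len(flux2, k)
  minflux <- rep_len(minflux, k)
  maxflux <- rep_len(maxflux, k)
  stopifnot(all(is.finite(flux1)), all(is.finite(flux2)))
  rng <- maxflux - minflux
  degenerate <- abs(rng) < 1e-9
  ratio <- ifelse(degenerate, NA_real_,
                  (abs(flux2) - abs(flux1)) / rng)
  call <- ifelse(degenerate, "undefined",
                 ifelse(ratio > threshold, "up",
                        ifelse(ratio < -threshold, "down", "unchanged")))
  structure(data.frame(
    reaction_id = reaction_id %||% paste0("r", seq_len(k)),
    flux1 = flux1, flux2 = flux2, minflux = minflux, maxflux = maxflux,
    ratio = ratio, call = call, stringsAsFactors = FALSE),
    class = c("flux_change", "data.frame"))
}

#' Hierarchical clustering of flux (or expression) patterns
#'
#' Agglomerative clustering of the rows or columns of a labeled matrix,
#' by default with Euclidean distance and average linkage. Labels are
#' sorted lexicographically before computing distances so that equal-
#' distance merge order is deterministic and documented (ties resolve
#' toward the earlier label).
#'
#' @param matrix labeled numeric matrix (no missing values; reactions
#'   absent from a tissue model contribute flux 0).
#' @param axis cluster `"columns"` (tissues; default) or `"rows"`.
#' @param metric distance method passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return object of class `flux_clustering`: the `hclust` tree, leaf
#'   `labels`, merge `heights`, the `metric`/`linkage` names, and a
#'   `newick` serialization of the dendrogram.
#' @export
cluster_patterns <- function(matrix, axis = c("columns", "rows"),
                             metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(matrix) else matrix
  if (nrow(m) < 2L) {
    stop("need at least two labels on the clustered axis", call. = FALSE)
  }
  if (anyNA(m)) stop("matrix has missing values", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(list(hclust = hc, labels = hc$labels, heights = hc$height,
                 metric = metric, linkage = linkage,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "flux_clustering")
}

#' @export
print.flux_clustering <- function(x, ...) {
  cat("Hierarchical clustering of ", length(x$labels), " patterns (",
      x$metric, " distance, ", x$linkage, " linkage)\n", sep = "")
  cat("  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' @export
plot.flux_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = paste0("Flux pattern clustering (", x$metric, ", ",
                     x$linkage, ")"), ...)
  invisible(x)
}
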