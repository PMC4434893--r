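check_hyper_args <- function(N, K, n, k) {
  if (any(N < 0 | K < 0 | n < 0 | k < 0)) {
    abort("Hypergeometric arguments must be non-negative", class = "regpath_argument_error")
  }
  if (any(K > N) || any(n > N)) {
    abort("Hypergeometric arguments require K <= N and n <= N",
          class = "regpath_argument_error")
  }
  if (any(k > pmin(K, n))) {
    abort("Hypergeometric arguments require k <= min(K, n)",
          class = "regpath_argument_error")
  }
  invisible(TRUE)
}

#' Upper-tail hypergeometric probability
#'
#' Exact over-representation probability `P(X >= k)` where `X` is the number
#' of known-positive elements in a uniform draw of `n` elements from a
#' universe of `N` containing `K` positives:
#' `sum_{j = k}^{min(K, n)} C(K, j) C(N - K, n - j) / C(N, n)`.
#' Computed through the stable survival function of the hypergeometric
#' distribution (log-space internally), so values around `1e-10` and far
#' below do not underflow. The tail is inclusive; `k = 0` gives exactly 1.
#'
#' @param N Universe size.
#' @param K Number of known positives in the universe.
#' @param n Selection (draw) size.
#' @param k Number of known positives observed in the selection.
#' @return The upper-tail probability; vectorised over its arguments.
#' @seealso [hypergeom_point()], [node_set_enrichment()]
#' @examples
#' hypergeom_upper_tail(127, 27, 15, 9)
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric point probability
#'
#' `P(X = k)` for the hypergeometric distribution with the same
#' parameterisation as [hypergeom_upper_tail()]. Some published enrichment
#' figures correspond to this point mass rather than to a tail, so it is
#' exposed as an explicit convention; the upper tail remains the default
#' everywhere in the package.
#'
#' @inheritParams hypergeom_upper_tail
#' @return The point probability; vectorised.
#' @export
hypergeom_point <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  stats::dhyper(k, K, N - K, n)
}

#' Enrichment of a known set within a node selection
#'
#' Tests whether a selection of nodes (for example the members of an active
#' sub-network) over-represents a list of known disease-associated genes and
#' miRNAs, relative to a universe (for example the full curated network).
#' The known list is intersected with the universe before counting; the
#' selection must be a subset of the universe.
#'
#' @param universe Character vector: the population of node identifiers.
#' @param known Character vector of known disease-associated identifiers.
#' @param selection Character vector: the node set under test; must be a
#'   subset of `universe`.
#' @param convention `"upper"` (default) for the inclusive upper-tail
#'   probability `P(X >= k)`, or `"point"` for the point mass `P(X = k)`.
#' @return An `enrichment_result`: list with fields `N`, `K`, `n`, `k`,
#'   `p_value`, `convention`. Has [tidy()] and [glance()] methods.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' node_set_enrichment(u, known = u[1:10], selection = u[1:20])
#' @export
node_set_enrichment <- function(universe, known, selection,
                                convention = c("upper", "point")) {
  convention <- match.arg(convention)
  universe <- unique(as.character(universe))
  known <- unique(as.character(known))
  selection <- unique(as.character(selection))
  stray <- setdiff(selection, universe)
  if (length(stray) > 0) {
    abort(
      paste0("Selection contains identifiers outside the universe: ",
             paste(head(sort(stray), 10), collapse = ", "),
             if (length(stray) > 10) ", ..."),
      class = "regpath_argument_error"
    )
  }
  N <- length(universe)
  K <- length(intersect(known, universe))
  n <- length(selection)
  k <- length(intersect(known, selection))
  p <- switch(convention,
    upper = hypergeom_upper_tail(N, K, n, k),
    point = hypergeom_point(N, K, n, k)
  )
  structure(
    list(N = N, K = K, n = n, k = k, p_value = p, convention = convention),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> k = %d known of n = %d selected (universe N = %d, K = %d known)\n",
    x$k, x$n, x$N, x$K
  ))
  cat(sprintf("  %s p-value: %.4g\n",
              if (x$convention == "upper") "upper-tail P(X >= k)" else "point P(X = k)",
              x$p_value))
  invisible(x)
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble with columns `N`, `K`, `n`, `k`, `expected_k`,
#'   `fold_enrichment`, `p_value`, `convention`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  expected <- x$n * x$K / max(x$N, 1)
  tibble(
    N = x$N, K = x$K, n = x$n, k = x$k,
    expected_k = expected,
    fold_enrichment = if (expected > 0) x$k / expected else NA_real_,
    p_value = x$p_value,
    convention = x$convention
  )
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) tidy(x, ...)
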