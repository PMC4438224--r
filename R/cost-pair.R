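#' Mother/child cost pair
#'
#' All monetary quantities in the model are tracked as a pair of USD
#' amounts, one accruing to the mother's care and one to the child's, so
#' that per-case results can be reported in the mother / child / total
#' layout used throughout perinatal costing studies.
#'
#' @param mother USD amount on the maternal side.
#' @param child USD amount on the child side.
#' @return an object of class `cost_pair`: a list with elements `mother`
#'   and `child`.
#' @export
#' @examples
#' cost_pair(7790, 0)
cost_pair <- function(mother = 0, child = 0) {
  stopifnot(is.numeric(mother), length(mother) == 1L, is.finite(mother),
            is.numeric(child), length(child) == 1L, is.finite(child))
  structure(list(mother = as.numeric(mother), child = as.numeric(child)),
            class = "cost_pair")
}

#' @rdname cost_pair
#' @param x a `cost_pair`.
#' @export
is_cost_pair <- function(x) inherits(x, "cost_pair")

#' Total of a cost pair
#' @param x a `cost_pair`.
#' @return `mother + child` in USD.
#' @export
cp_total <- function(x) {
  stopifnot(is_cost_pair(x))
  x$mother + x$child
}

#' Elementwise sum of cost pairs
#' @param ... `cost_pair` objects.
#' @return a `cost_pair`.
#' @export
cp_add <- function(...) {
  pairs <- list(...)
  stopifnot(all(vapply(pairs, is_cost_pair, logical(1))))
  cost_pair(sum(vapply(pairs, `[[`, numeric(1), "mother")),
            sum(vapply(pairs, `[[`, numeric(1), "child")))
}

#' Scale a cost pair by a scalar
#' @param x a `cost_pair`.
#' @param k numeric scalar.
#' @return a `cost_pair` with both components multiplied by `k`.
#' @export
cp_scale <- function(x, k) {
  stopifnot(is_cost_pair(x), is.numeric(k), length(k) == 1L, is.finite(k))
  cost_pair(x$mother * k, x$child * k)
}

#' @export
print.cost_pair <- function(x, ...) {
  cat(sprintf("<cost_pair> mother: %s  child: %s  total: %s\n",
              fmt_usd(x$mother), fmt_usd(x$child), fmt_usd(cp_total(x))))
  invisible(x)
}
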