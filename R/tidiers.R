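#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x a `phasnet_de` object from [differential()].
#' @param ... unused.
#' @return a plain tibble (one row per tested feature).
#' @export
tidy.phasnet_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "phasnet_de")
  as_tibble(out)
}

#' One-row summary of a differential-expression result
#'
#' @param x a `phasnet_de` object.
#' @param ... unused.
#' @return tibble with the feature class, numbers tested and passing, and
#'   the thresholds applied.
#' @export
glance.phasnet_de <- function(x, ...) {
  tibble(class = x$class[1] %||% NA_character_,
         n_tested = nrow(x), n_pass = sum(x$passes),
         fc_min = attr(x, "fc_min"), fdr_max = attr(x, "fdr_max"))
}

#' Tidy an assembled network
#'
#' @param x a `phasnet_network` from [assemble_network()].
#' @param ... unused.
#' @return the triple table.
#' @export
tidy.phasnet_network <- function(x, ...) x$triples

#' One-row summary of an assembled network
#'
#' @param x a `phasnet_network`.
#' @param ... unused.
#' @export
glance.phasnet_network <- function(x, ...) {
  tibble(n_triples = nrow(x$triples),
         n_model1 = sum(x$triples$model == "model1"),
         n_model2 = sum(x$triples$model == "model2"),
         n_edges = nrow(x$edges))
}
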