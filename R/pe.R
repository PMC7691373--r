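#' Potential-energy parameters
#'
#' Tuning knobs of the graph potential energy. When a node pair has no
#' common neighbour the clustering-coefficient sum is replaced by a small
#' positive constant (default 0.1) so that such pairs can still be told
#' apart by degree and distance; pairs in different components have no
#' finite distance and receive `disconnected_value` (default 0, the
#' continuous limit of the inverse-distance factor).
#'
#' @param no_cn_constant positive stand-in for the clustering sum when the
#'   pair shares no neighbour.
#' @param disconnected_value potential energy assigned to disconnected
#'   pairs.
#' @return an object of class `pe_params`.
#' @export
pe_params <- function(no_cn_constant = 0.1, disconnected_value = 0) {
  if (!is.numeric(no_cn_constant) || no_cn_constant <= 0)
    stop_arg("`no_cn_constant` must be a positive number")
  structure(list(no_cn_constant = no_cn_constant,
                 disconnected_value = disconnected_value),
            class = "pe_params")
}

#' Potential energy of a node pair
#'
#' A gravitational analogue `m * g * h` on the projected graph: the degree
#' product plays mass, the summed clustering coefficient of the pair's
#' common neighbours plays the field strength, and the inverse shortest
#' distance plays height:
#'
#' `PE(a, b) = d_a d_b * (sum_{z in CN(a,b)} cl_z) * 1 / sd(a, b)`
#'
#' All three factors are computed on the unweighted skeleton. Pairs without
#' common neighbours use `no_cn_constant` for the middle factor, so PE still
#' separates them; adjacent pairs (`sd = 1`) are legal inputs — the score is
#' defined for every disconnected or connected node pair.
#'
#' @param pg a [project_weighted()] projection.
#' @param a,b distinct nodes of `pg`.
#' @param params a [pe_params()] object.
#' @return a non-negative score.
#' @examples
#' # degree product 3, clustering sum 0.1666, distance 2  ->  0.25
#' potential_energy_from_factors(3, 0.1666, 2)
#' @export
potential_energy <- function(pg, a, b, params = pe_params()) {
  check_pg_node(pg, a); check_pg_node(pg, b)
  if (a == b) stop_arg("potential_energy requires two distinct nodes")
  da <- length(pg$adj[[a]]); db <- length(pg$adj[[b]])
  if (da == 0L || db == 0L) return(0)
  cn <- intersect(pg$adj[[a]], pg$adj[[b]])
  cc <- clustering_all(pg)
  s <- if (length(cn)) sum(cc[cn]) else params$no_cn_constant
  sd_ab <- shortest_distance(pg, a, b)
  if (!is.finite(sd_ab)) return(params$disconnected_value)
  potential_energy_from_factors(da * db, s, sd_ab)
}

#' @rdname potential_energy
#' @param degree_product product of the two node degrees.
#' @param clustering_sum summed clustering coefficient of the common
#'   neighbours (or the no-common-neighbour constant).
#' @param distance shortest distance between the nodes (hops).
#' @export
potential_energy_from_factors <- function(degree_product, clustering_sum,
                                          distance) {
  degree_product * clustering_sum * (1 / distance)
}
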