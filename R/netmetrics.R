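#' Local clustering coefficients
#'
#' The local clustering coefficient of node i is the fraction of linked
#' pairs among the neighbours of i.  Nodes with degree < 2 have no neighbour
#' pair; their coefficient is defined as 0 (the dominant field convention,
#' which keeps the network average in \[0, 1\]).
#'
#' @param net a [tsnet].
#' @param i optional node index; when NULL all nodes are returned.
#' @return numeric vector (or scalar) of values in \[0, 1\].
#' @export
local_clustering <- function(net, i = NULL) {
  stopifnot(inherits(net, "tsnet"))
  A <- adjacency(net)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2      # triangles through each node
  ci <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  names(ci) <- net$labels
  if (is.null(i)) return(ci)
  if (!is.numeric(i) || i < 1 || i > net$n) stop("invalid node index")
  ci[[as.integer(i)]]
}

#' Network clustering coefficient
#'
#' Mean of the local clustering coefficients over all nodes.  For an
#' Erdos-Renyi network its expectation equals the edge density (see
#' [er_expected_clustering]).
#'
#' @param net a [tsnet].
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(net) mean(local_clustering(net))

#' Average shortest path length (finite-path convention)
#'
#' Mean graph distance over all unordered node pairs *including* each node
#' paired with itself (`d_ii = 0`); pairs in different components
#' (infinite distance) are excluded from both numerator and denominator.
#' Under this convention a complete graph has `L = (n-1)/(n+1)`; excluding
#' the self-pairs would multiply the value of a connected graph by exactly
#' `(n+1)/(n-1)`.  A graph with no edges returns 0 (only self-pairs remain).
#'
#' @param net a [tsnet].
#' @param include_self include self-pairs (the package convention, default
#'   TRUE); set FALSE for the excluded-self variant.
#' @return scalar >= 0.
#' @export
avg_shortest_path <- function(net, include_self = TRUE) {
  stopifnot(inherits(net, "tsnet"))
  n <- net$n
  D <- igraph::distances(as_igraph(net))
  up <- D[upper.tri(D)]
  fin <- up[is.finite(up)]
  num <- sum(fin)
  den <- length(fin) + if (include_self) n else 0
  if (den == 0) return(0)
  num / den
}

#' Number of connected components
#'
#' Isolated nodes count as components of size one.
#'
#' @param net a [tsnet].
#' @return integer in \[1, n\].
#' @export
n_components <- function(net) {
  stopifnot(inherits(net, "tsnet"))
  igraph::components(as_igraph(net))$no
}

#' Node degrees
#' @param net a [tsnet].
#' @return integer vector of length n.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "tsnet"))
  k <- integer(net$n)
  if (nrow(net$edges)) {
    t1 <- tabulate(net$edges[, 1L], nbins = net$n)
    t2 <- tabulate(net$edges[, 2L], nbins = net$n)
    k <- t1 + t2
  }
  names(k) <- net$labels
  k
}

#' Pooled empirical degree distribution
#'
#' Relative frequencies of node degrees pooled over a collection of networks
#' on the same number of nodes.
#'
#' @param nets list of [tsnet] objects, all with the same `n`.
#' @return named numeric vector of probabilities over k = 0, ..., n-1
#'   summing to 1.
#' @export
degree_distribution <- function(nets) {
  if (inherits(nets, "tsnet")) nets <- list(nets)
  ns <- vapply(nets, function(g) g$n, integer(1))
  if (length(unique(ns)) != 1L) stop("all networks must have the same number of nodes")
  n <- ns[1L]
  ks <- unlist(lapply(nets, degrees), use.names = FALSE)
  counts <- tabulate(ks + 1L, nbins = n)
  pmf <- counts / sum(counts)
  names(pmf) <- 0:(n - 1L)
  pmf
}

#' Expected clustering coefficient of an Erdos-Renyi network
#'
#' For ER networks the expected clustering coefficient equals the edge
#' density; used as the denominator of C/C_ER ratios.
#'
#' @param rho edge density in \[0, 1\].
#' @return `rho`.
#' @export
er_expected_clustering <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  rho
}

#' Full metrics record for one network
#'
#' @param net a [tsnet].
#' @return a list of class `metrics_record`: clustering coefficient `C`,
#'   average shortest path length `L` (finite-path, self-pairs included),
#'   component count `K`, `degrees`, edge density `rho`.
#' @export
network_metrics <- function(net) {
  structure(list(C = clustering_coefficient(net),
                 L = avg_shortest_path(net),
                 K = n_components(net),
                 degrees = degrees(net),
                 rho = edge_density(net)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> C = %.4f, L = %.4f, K = %d, rho = %.4f, mean k = %.2f\n",
              x$C, x$L, x$K, x$rho, mean(x$degrees)))
  invisible(x)
}

#' Write metrics records to CSV
#'
#' One row per network: id, C, L, K, rho, mean degree.
#'
#' @param records list of `metrics_record` objects (or a single one).
#' @param path output CSV path.
#' @param ids optional identifiers, default the sequence index.
#' @export
write_metrics_csv <- function(records, path, ids = NULL) {
  if (inherits(records, "metrics_record")) records <- list(records)
  if (is.null(ids)) ids <- seq_along(records)
  tab <- data.frame(
    id = ids,
    C = vapply(records, `[[`, numeric(1), "C"),
    L = vapply(records, `[[`, numeric(1), "L"),
    K = vapply(records, `[[`, numeric(1), "K"),
    rho = vapply(records, `[[`, numeric(1), "rho"),
    mean_degree = vapply(records, function(r) mean(r$degrees), numeric(1)))
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
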