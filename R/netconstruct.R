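#' Unweighted interaction network
#'
#' A `tsnet` is a simple undirected graph on `n` labelled nodes: an edge
#' matrix of unordered node pairs (i < j, 1-based) plus provenance describing
#' how the network was derived (estimator, threshold or target density,
#' seed).
#'
#' @param n number of nodes.
#' @param edges integer matrix with two columns (one row per edge) or NULL
#'   for the empty graph; self-loops and duplicate edges are rejected.
#' @param labels node labels.
#' @param provenance named list describing the construction.
#' @return an object of class `tsnet`.
#' @export
tsnet <- function(n, edges = NULL, labels = NULL, provenance = list()) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L | edges > n)) stop("edge endpoints out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    key <- (edges[, 1L] - 1) * n + edges[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]  # canonical (i, j) order
  }
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n))
  structure(list(n = n, edges = edges, labels = as.character(labels),
                 provenance = provenance),
            class = "tsnet")
}

#' @export
print.tsnet <- function(x, ...) {
  cat(sprintf("<tsnet> %d nodes, %d edges (density %.3f)\n",
              x$n, nrow(x$edges), edge_density(x)))
  invisible(x)
}

#' @rdname tsnet
#' @param net a `tsnet`.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname tsnet
#' @export
edge_density <- function(net) {
  if (net$n < 2L) return(0)
  nrow(net$edges) / (net$n * (net$n - 1) / 2)
}

#' Convert a `tsnet` to an igraph graph
#' @param net a [tsnet].
#' @return an `igraph` object with vertex names set to the node labels.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "tsnet"))
  g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$labels)
  if (nrow(net$edges)) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Dense adjacency matrix of a `tsnet`
#' @param net a [tsnet].
#' @return a 0/1 numeric matrix with the node labels as dimnames.
#' @export
adjacency <- function(net) {
  A <- matrix(0, net$n, net$n, dimnames = list(net$labels, net$labels))
  if (nrow(net$edges)) {
    A[net$edges] <- 1
    A[net$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

# upper-triangle pair list in the package's canonical order (i < j, row-major)
.pairs_upper <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i, j)
}

#' Threshold an interdependence matrix at a fixed value
#'
#' Nodes i and j are linked iff `m(i, j) > theta` (strict), the diagonal is
#' ignored.  Edge count is monotone non-increasing in `theta`.
#'
#' @param m an [interdep_matrix].
#' @param theta threshold in \[0, 1\].
#' @return a [tsnet].
#' @export
threshold_by_value <- function(m, theta) {
  stopifnot(inherits(m, "interdep_matrix"))
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]")
  n <- nrow(m$values)
  pr <- .pairs_upper(n)
  keep <- m$values[pr] > theta
  tsnet(n, pr[keep, , drop = FALSE], labels = m$labels,
        provenance = list(estimator = m$estimator, rule = "value", theta = theta))
}

#' Threshold an interdependence matrix at a fixed edge density
#'
#' Links the `m_e = round(rho_target * n(n-1)/2)` strongest pairs
#' (round-half-up).  Ties at the cut value are broken deterministically by
#' value descending, then smaller index pair first, which makes the edge sets
#' nested across densities.
#'
#' @param m an [interdep_matrix].
#' @param rho_target target edge density in \[0, 1\].
#' @return a [tsnet] whose realized density equals `m_e / (n(n-1)/2)` exactly.
#' @export
threshold_by_density <- function(m, rho_target) {
  stopifnot(inherits(m, "interdep_matrix"))
  if (!is.numeric(rho_target) || length(rho_target) != 1L ||
      rho_target < 0 || rho_target > 1)
    stop("rho_target must lie in [0, 1]")
  n <- nrow(m$values)
  pr <- .pairs_upper(n)
  npairs <- nrow(pr)
  m_e <- as.integer(floor(rho_target * npairs + 0.5))
  v <- m$values[pr]
  ord <- order(-v, pr[, 1L], pr[, 2L])  # stable: value desc, then (i, j) asc
  sel <- ord[seq_len(m_e)]
  tsnet(n, pr[sel, , drop = FALSE], labels = m$labels,
        provenance = list(estimator = m$estimator, rule = "density",
                          rho_target = rho_target, m_e = m_e))
}

#' Erdos-Renyi random networks
#'
#' Two classical flavours: `"gnp"` links every unordered pair independently
#' with probability `p`; `"fixed_links"` draws a uniformly random simple
#' graph with exactly `m_e` edges (links added between randomly chosen pairs,
#' avoiding multi-edges).
#'
#' @param n number of nodes.
#' @param mode `"gnp"` or `"fixed_links"`.
#' @param p link probability (gnp mode).
#' @param m_e number of links (fixed_links mode).
#' @param seed optional integer seed.
#' @param labels optional node labels.
#' @return a [tsnet].
#' @export
er_network <- function(n, mode = c("gnp", "fixed_links"), p = NULL, m_e = NULL,
                       seed = NULL, labels = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  pr <- if (n >= 2L) .pairs_upper(n) else matrix(integer(0), ncol = 2L)
  npairs <- nrow(pr)
  edges <- with_seed(seed, {
    if (mode == "gnp") {
      if (is.null(p) || p < 0 || p > 1) stop("gnp mode needs p in [0, 1]")
      pr[stats::runif(npairs) < p, , drop = FALSE]
    } else {
      if (is.null(m_e) || m_e < 0 || m_e > npairs)
        stop("fixed_links mode needs 0 <= m_e <= n(n-1)/2")
      pr[sample.int(npairs, as.integer(m_e)), , drop = FALSE]
    }
  })
  tsnet(n, edges, labels = labels,
        provenance = c(list(rule = "er", mode = mode, seed = seed),
                       if (mode == "gnp") list(p = p) else list(m_e = m_e)))
}

#' Write / read networks as edge-list text or GraphML
#'
#' The edge list is a TSV of two label columns preceded by a `# nodes:`
#' comment carrying the full label set (so isolated nodes round-trip
#' exactly).  GraphML goes through igraph.
#'
#' @param net a [tsnet].
#' @param path output path.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "tsnet"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(net$labels, collapse = "\t")), con)
  if (nrow(net$edges)) {
    apply(net$edges, 1L, function(e)
      writeLines(paste(net$labels[e[1L]], net$labels[e[2L]], sep = "\t"), con))
  }
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1L], "# nodes: "))
    stop("not a spurnet edge-list file (missing '# nodes:' header)")
  labels <- strsplit(sub("^# nodes: ", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  edges <- if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    cbind(match(parts[, 1L], labels), match(parts[, 2L], labels))
  } else NULL
  tsnet(length(labels), edges, labels = labels)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  labels <- igraph::vertex_attr(g, "name")
  e <- igraph::as_edgelist(g, names = FALSE)
  tsnet(igraph::vcount(g), e,
        labels = if (is.null(labels)) NULL else labels)
}
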