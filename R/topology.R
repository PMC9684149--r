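#' Adjacency matrices for gap-junction networks
#'
#' All networks in this package are simple undirected graphs represented as
#' dense binary adjacency matrices: symmetric, zero diagonal, entries in
#' \{0, 1\}.  `as_adjacency()` validates and tags a matrix;
#' `is_connected_graph()` reports whether the graph is connected (every
#' studied network is).
#'
#' @param m a square 0/1 matrix.
#' @return `as_adjacency()` returns the matrix with class
#'   `"adjacency_matrix"` and an attribute `connected`.
#' @export
as_adjacency <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(m, t(m)))) stop("adjacency must be symmetric")
  if (any(diag(m) != 0)) stop("adjacency must have zero diagonal")
  structure(m, class = c("adjacency_matrix", "matrix", "array"),
            connected = is_connected_graph(m))
}

#' @rdname as_adjacency
#' @export
is_connected_graph <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(unclass(m), mode = "undirected")
  igraph::is_connected(g)
}

#' Node degrees
#' @param adj an adjacency matrix.
#' @return Integer vector of degrees.
#' @export
degrees <- function(adj) as.integer(rowSums(unclass(adj)))

# compressed sparse row form consumed by the compiled integrator (0-based)
.adj_csr <- function(adj) {
  nb <- apply(unclass(adj) != 0, 1, which, simplify = FALSE)
  list(indptr = as.integer(c(0, cumsum(lengths(nb)))),
       indices = as.integer(unlist(nb) - 1L))
}

#' Two-dimensional lattice network
#'
#' An `L x L` square lattice with von Neumann neighborhoods (up, down,
#' left, right).  With periodic boundaries (the default, matching the
#' studied networks) every neuron has degree exactly 4; without them,
#' corner and edge nodes have smaller degree.  `L = 2` with periodic
#' boundaries is degenerate (parallel edges collapse, degree 2) and is
#' flagged with a warning.
#'
#' @param L side length (`N = L^2` nodes), `L >= 2`.
#' @param periodic logical; wrap edges around (torus)?
#' @return An adjacency matrix; nodes are numbered row-major.
#' @examples
#' a <- lattice_2d(10)
#' all(degrees(a) == 4)
#' @export
lattice_2d <- function(L, periodic = TRUE) {
  stopifnot(length(L) == 1, L == round(L), L >= 2)
  if (periodic && L == 2)
    warning("L = 2 periodic lattice is degenerate (degree 2)")
  N <- L * L
  m <- matrix(0, N, N)
  id <- function(r, c) (r %% L) * L + (c %% L) + 1L
  for (r in 0:(L - 1)) for (cc in 0:(L - 1)) {
    i <- id(r, cc)
    nb <- if (periodic) {
      c(id(r - 1, cc), id(r + 1, cc), id(r, cc - 1), id(r, cc + 1))
    } else {
      c(if (r > 0) id(r - 1, cc), if (r < L - 1) id(r + 1, cc),
        if (cc > 0) id(r, cc - 1), if (cc < L - 1) id(r, cc + 1))
    }
    m[i, nb] <- 1
  }
  m <- pmax(m, t(m))
  diag(m) <- 0
  as_adjacency(m)
}

#' Ring (regular circulant) network
#'
#' `N` nodes on a circle, each connected to its `k/2` nearest neighbors on
#' either side.  Node 1 of `ring_network(100, 4)` is adjacent to nodes 2, 3,
#' 99 and 100.
#'
#' @param N number of nodes.
#' @param k even degree, `k < N`.
#' @return An adjacency matrix.
#' @export
ring_network <- function(N, k) {
  stopifnot(N >= 3, k %% 2 == 0, k >= 2, k < N)
  m <- matrix(0, N, N)
  for (d in seq_len(k / 2)) {
    i <- seq_len(N)
    j <- (i - 1 + d) %% N + 1
    m[cbind(i, j)] <- 1
    m[cbind(j, i)] <- 1
  }
  as_adjacency(m)
}

#' Add random long-range connections
#'
#' For each node in index order, adds `per_node` new edges from that node to
#' uniformly chosen non-adjacent targets (never itself, never duplicating an
#' edge).  Adds exactly `N * per_node` edges, raising the mean degree by
#' `2 * per_node`.  No minimum-distance constraint is imposed: any currently
#' non-adjacent node counts as "long range".
#'
#' @param base an adjacency matrix.
#' @param per_node new connections per node.
#' @return An adjacency matrix.  Uses the R RNG; seed with [set.seed()].
#' @export
add_random_long_range <- function(base, per_node = 1) {
  stopifnot(per_node >= 0, per_node == round(per_node))
  m <- unclass(base)
  N <- nrow(m)
  for (i in seq_len(N)) {
    for (rep in seq_len(per_node)) {
      candidates <- which(m[i, ] == 0 & seq_len(N) != i)
      if (length(candidates) == 0)
        stop("node ", i, " is saturated; no long-range candidate left")
      j <- candidates[[sample.int(length(candidates), 1)]]
      m[i, j] <- 1
      m[j, i] <- 1
    }
  }
  as_adjacency(m)
}

#' Ring with controlled connection distance
#'
#' A `ring_network(N, 4)` plus, for every node, one edge to each of the two
#' nodes at circular distance `3 + CR`.  All degrees equal 6 for every `CR`;
#' only the length of the added connections changes.  `CR = 0` adds the
#' distance-3 neighbors and is edge-identical to `ring_network(N, 6)`
#' (node 1 gains nodes 4 and 98 for `N = 100`); `CR = 1` adds nodes 5
#' and 97, and so on.
#'
#' @param N number of nodes.
#' @param CR connection distance offset, `CR >= 0` with `3 + CR <= N / 2`.
#' @return An adjacency matrix.
#' @export
ring_with_cr <- function(N, CR) {
  stopifnot(CR >= 0, CR == round(CR))
  if (3 + CR > N / 2)
    stop("CR too large: added edges would wrap onto existing neighbors")
  m <- unclass(ring_network(N, 4))
  d <- 3 + CR
  i <- seq_len(N)
  j <- (i - 1 + d) %% N + 1
  m[cbind(i, j)] <- 1
  m[cbind(j, i)] <- 1
  as_adjacency(m)
}

#' Watts-Strogatz small-world network
#'
#' The standard one-endpoint rewiring procedure: starting from
#' `ring_network(N, k)`, each edge (visited as (node, clockwise neighbor)
#' pairs in increasing distance order) is rewired with probability `p` by
#' moving its far endpoint to a uniformly chosen node that is neither the
#' source, nor already adjacent to it.  Edge count (and thus mean degree)
#' is conserved.
#'
#' @param N number of nodes.
#' @param k even base degree, `k < N`.
#' @param p rewiring probability in \[0, 1\].
#' @return An adjacency matrix.  Uses the R RNG; seed with [set.seed()].
#' @export
watts_strogatz <- function(N, k, p) {
  stopifnot(p >= 0, p <= 1)
  m <- unclass(ring_network(N, k))
  for (d in seq_len(k / 2)) {
    for (i in seq_len(N)) {
      j <- (i - 1 + d) %% N + 1
      if (m[i, j] == 1 && stats::runif(1) < p) {
        candidates <- which(m[i, ] == 0 & seq_len(N) != i)
        if (length(candidates) == 0) next  # saturated node: keep the edge
        jnew <- candidates[[sample.int(length(candidates), 1)]]
        m[i, j] <- 0; m[j, i] <- 0
        m[i, jnew] <- 1; m[jnew, i] <- 1
      }
    }
  }
  as_adjacency(m)
}

#' Node coordinates for field-potential synthesis
#'
#' Geometric embeddings used by [lfp()]: ring nodes sit equally spaced on
#' the unit circle, lattice nodes on the integer grid (row-major, matching
#' [lattice_2d()] numbering).
#'
#' @param type `"ring"` or `"lattice"`.
#' @param N number of nodes (ring) .
#' @param L lattice side length.
#' @return A two-column matrix of coordinates.
#' @export
node_coordinates <- function(type = c("ring", "lattice"), N = NULL,
                             L = NULL) {
  type <- match.arg(type)
  if (type == "ring") {
    stopifnot(!is.null(N))
    th <- 2 * pi * (seq_len(N) - 1) / N
    cbind(x = cos(th), y = sin(th))
  } else {
    stopifnot(!is.null(L))
    # row-major: node 1 = (row 0, col 0), node 2 = (row 0, col 1), ...
    cbind(x = rep(0:(L - 1), each = L), y = rep(0:(L - 1), times = L))
  }
}

#' Edge-list serialization
#'
#' Writes each undirected edge once as two 1-based node indices per line
#' (whitespace separated); `read_edge_list()` reconstructs the adjacency.
#'
#' @param adj an adjacency matrix.
#' @param file path.
#' @param n number of nodes (needed on read since isolated tail nodes are
#'   otherwise unrecoverable; defaults to the largest index seen).
#' @return `read_edge_list()` returns an adjacency matrix.
#' @export
write_edge_list <- function(adj, file) {
  m <- unclass(adj)
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  utils::write.table(idx[order(idx[, 1], idx[, 2]), , drop = FALSE], file,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(file, n = NULL) {
  e <- as.matrix(utils::read.table(file))
  if (is.null(n)) n <- max(e)
  m <- matrix(0, n, n)
  m[e] <- 1
  m[e[, 2:1, drop = FALSE]] <- 1
  as_adjacency(m)
}
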