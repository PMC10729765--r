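# Accept a wpli_connectivity, a plain symmetric matrix, or anything
# coercible; validates the weighted-network invariants.
as_weight_matrix <- function(net) {
  w <- if (inherits(net, "wpli_connectivity")) net$weights else as.matrix(net)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-10) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  diag(w) <- 0
  w
}

#' Average degree (strength) of a weighted network
#'
#' `(1/N) * sum_ij w_ij` over ordered pairs — for a symmetric zero-diagonal
#' matrix this is the mean node strength.
#'
#' @param net A `wpli_connectivity` or a symmetric non-negative weight
#'   matrix with zero diagonal.
#' @return Scalar average degree.
#' @examples
#' w <- matrix(0.5, 4, 4); diag(w) <- 0
#' average_degree(w)  # 1.5
#' @export
average_degree <- function(net) {
  w <- as_weight_matrix(net)
  sum(w) / nrow(w)
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the weighted clustering coefficient computed on
#' weights normalized by the matrix maximum: for node `i`,
#' `C_i = sum_{j,k} (w_ij w_ik w_jk)^(1/3) / (k_i (k_i - 1))` where `k_i`
#' counts nonzero neighbors (the geometric-mean-of-triangles convention of
#' the Brain Connectivity Toolbox). Nodes with fewer than two neighbors
#' contribute 0. With `weighted = FALSE` the binary clustering coefficient
#' of the graph thresholded at `threshold` is returned instead.
#'
#' @inheritParams average_degree
#' @param weighted Use the weighted definition (default) or the binary one.
#' @param threshold Binarization threshold when `weighted = FALSE`.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, weighted = TRUE, threshold = 0) {
  w <- as_weight_matrix(net)
  n <- nrow(w)
  if (n < 3L) return(0)
  if (!weighted) {
    a <- (w > threshold) * 1
    k <- rowSums(a)
    tri <- diag(a %*% a %*% a)  # 2 * triangles per node
    ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    return(mean(ci))
  }
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  wr <- wn^(1 / 3)
  cyc <- diag(wr %*% wr %*% wr)  # weighted 2x triangle intensity per node
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  mean(ci)
}

#' All-pairs shortest-path lengths of a weighted network
#'
#' Edge lengths are the inverse weights (`1/w_ij` for `w_ij > 0`, no edge
#' otherwise); distances are Dijkstra shortest paths from every node.
#' Disconnected pairs get `Inf`; the diagonal is 0.
#'
#' @inheritParams average_degree
#' @return Symmetric matrix of shortest-path lengths.
#' @export
distance_matrix <- function(net) {
  w <- as_weight_matrix(net)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered node pairs,
#' `(1/(N(N-1))) * sum_{i != j} l_ij`. If any pair is disconnected the
#' result is `Inf` and a warning is emitted; `finite_pairs = TRUE` averages
#' the finite pairs only instead.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param finite_pairs Average only finite (connected) pairs.
#' @return Scalar path length (possibly `Inf`).
#' @export
characteristic_path_length <- function(dm, finite_pairs = FALSE) {
  if (nrow(dm) < 2L) stop("need at least two nodes", call. = FALSE)
  off <- dm[row(dm) != col(dm)]
  if (any(is.infinite(off))) {
    if (finite_pairs) {
      fin <- off[is.finite(off)]
      if (length(fin) == 0) return(Inf)
      return(mean(fin))
    }
    warning("network is disconnected; characteristic path length is Inf")
    return(Inf)
  }
  mean(off)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered pairs,
#' `(1/(N(N-1))) * sum_{i != j} 1/l_ij`, with `1/Inf = 0` so disconnected
#' pairs contribute zero efficiency.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(dm) {
  if (nrow(dm) < 2L) stop("need at least two nodes", call. = FALSE)
  off <- dm[row(dm) != col(dm)]
  inv <- ifelse(is.infinite(off), 0, 1 / off)
  mean(inv)
}

#' All four network properties of one weighted network
#'
#' Bundles [average_degree()], [clustering_coefficient()],
#' [characteristic_path_length()] and [global_efficiency()].
#'
#' @inheritParams average_degree
#' @param finite_pairs Passed to [characteristic_path_length()].
#' @return One-row tibble with columns `D`, `CC`, `CPL`, `GE`.
#' @examples
#' w <- matrix(0.5, 4, 4); diag(w) <- 0
#' network_metrics(w)  # D = 1.5, CC = 1, CPL = 2, GE = 0.5
#' @export
network_metrics <- function(net, finite_pairs = FALSE) {
  w <- as_weight_matrix(net)
  dm <- distance_matrix(w)
  tibble::tibble(
    D = average_degree(w),
    CC = clustering_coefficient(w),
    CPL = characteristic_path_length(dm, finite_pairs = finite_pairs),
    GE = global_efficiency(dm)
  )
}
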