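#' Configuration for the diffusion map
#'
#' @param k Neighbor count for the kNN similarity graph (default 10).
#' @param n_variables Number m of non-trivial diffusion variables to retain;
#'   must satisfy 1 <= m <= N - 2 for N genomes.
#' @param weight_mode `"inverse_distance"` (w = 1/d, default) or
#'   `"gaussian"` (w = exp(-d^2 / sigma^2) with sigma = median kNN distance).
#' @param allow_disconnected If `FALSE` (default) a disconnected neighbor
#'   graph is an error; if `TRUE`, extra near-zero eigenvectors are kept and
#'   flagged as connected-component indicators.
#' @param tol Numerical tolerance for zero-eigenvalue and residual checks.
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(k = 10L, n_variables = 2L,
                             weight_mode = c("inverse_distance", "gaussian"),
                             allow_disconnected = FALSE, tol = 1e-8) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(k >= 1L, n_variables >= 1L, tol > 0)
  structure(list(k = as.integer(k), n_variables = as.integer(n_variables),
                 weight_mode = weight_mode,
                 allow_disconnected = isTRUE(allow_disconnected), tol = tol),
            class = "diffusion_config")
}

#' Build the k-nearest-neighbor similarity graph over genomes
#'
#' Rows of the trait matrix are compared by Euclidean distance; each genome
#' is linked to its k nearest neighbors with a weight that decreases in
#' distance (1/d by default), and the directed kNN relation is symmetrized
#' by union (w_ij = max(w_ij, w_ji)). Ties among equidistant candidate
#' neighbors are broken by input row order.
#'
#' @param T A `trait_matrix` (or any numeric matrix with unique rows and
#'   genome row names).
#' @param config A [diffusion_config()].
#' @return A `neighbor_graph`: list with `node_ids` and the symmetric
#'   nonnegative `weights` matrix (zero diagonal).
#' @export
knn_graph <- function(T, config = diffusion_config()) {
  m <- unclass(as.matrix(T))
  n <- nrow(m)
  k <- config$k
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of genomes (%d)", k, n))
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    ids <- rownames(m)
    stop(sprintf(paste0("identical trait rows found (e.g. '%s' and '%s'); ",
                        "deduplicate genomes first and re-expand afterwards"),
                 ids[dup[1L, 1L]], ids[dup[1L, 2L]]))
  }
  # k nearest per row, excluding self; order() is stable => input-order ties
  nn_d <- matrix(0, n, k)
  nn_i <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ord <- order(di)[seq_len(k)]
    nn_i[i, ] <- ord
    nn_d[i, ] <- di[ord]
  }
  w <- matrix(0, n, n, dimnames = dimnames(d))
  if (config$weight_mode == "inverse_distance") {
    wts <- 1 / nn_d
  } else {
    sigma <- stats::median(nn_d)
    wts <- exp(-(nn_d^2) / sigma^2)
  }
  for (i in seq_len(n)) w[i, nn_i[i, ]] <- wts[i, ]
  w <- pmax(w, t(w)) # union symmetrization
  diag(w) <- 0
  structure(list(node_ids = rownames(m), weights = w), class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d undirected edges\n",
              length(x$node_ids), sum(x$weights > 0) / 2))
  invisible(x)
}

#' Row-normalized graph Laplacian
#'
#' Returns L = I - D^-1 W for weighted adjacency W with degree matrix
#' D = diag(row sums). Every row of L sums to zero; eigenvalues are real
#' (L is conjugate to a symmetric matrix) and lie in \[0, 2\].
#'
#' @param G A `neighbor_graph`.
#' @return An N x N matrix with node ids as dimnames.
#' @export
row_normalized_laplacian <- function(G) {
  w <- G$weights
  deg <- rowSums(w)
  if (any(deg <= 0)) {
    stop(sprintf("isolated node(s) with zero degree: %s",
                 paste(G$node_ids[deg <= 0], collapse = ", ")))
  }
  L <- diag(nrow(w)) - w / deg
  dimnames(L) <- dimnames(w)
  L
}

#' Diffusion variables from the row-normalized Laplacian
#'
#' Computes the m + 1 smallest eigenpairs of L = I - D^-1 W through its
#' symmetric conjugate L_sym = I - D^-1/2 W D^-1/2 (which shares the
#' spectrum), back-transforms eigenvectors by D^-1/2, drops the trivial
#' zero-eigenvalue mode, and returns variables 1..m ordered by ascending
#' eigenvalue. Each variable is unit-norm with the sign fixed so that its
#' largest-magnitude entry is negative, making results bit-reproducible;
#' extremal clusters then sit at low (negative) values.
#'
#' @param L Laplacian from [row_normalized_laplacian()].
#' @param G The `neighbor_graph` the Laplacian was built from (supplies the
#'   degree vector for the symmetric conjugate).
#' @param config A [diffusion_config()]; `n_variables` is clamped to N - 2.
#' @return A `diffusion_result` with fields `eigenvalues` (length m + 1,
#'   ascending, first ~0), `variables` (N x m matrix, genome rows),
#'   `genome_ids`, `localization` (per-variable inverse participation
#'   ratio), and `component_indicator` (logical, only with
#'   `allow_disconnected = TRUE`).
#' @export
diffusion_eigs <- function(L, G, config = diffusion_config()) {
  deg <- rowSums(G$weights)
  n <- nrow(L)
  m <- min(config$n_variables, n - 2L)
  tol <- config$tol
  dhalf <- sqrt(deg)
  lsym <- diag(n) - (G$weights / dhalf) / rep(dhalf, each = n)
  lsym <- (lsym + t(lsym)) / 2
  es <- eigen(lsym, symmetric = TRUE)
  ord <- rev(seq_len(n)) # eigen() returns descending; we want ascending
  lambda <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  n_zero <- sum(lambda < tol)
  if (n_zero > 1L && !config$allow_disconnected) {
    stop("graph disconnected (multiple ~zero eigenvalues); increase k or set allow_disconnected = TRUE")
  }
  keep <- seq(2L, m + 1L)
  V <- U[, keep, drop = FALSE] / dhalf # back-transform u -> D^-1/2 u
  V <- apply(V, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] > 0) v <- -v
    v
  })
  rownames(V) <- G$node_ids
  colnames(V) <- paste0("v", seq_len(ncol(V)))
  res <- structure(list(
    eigenvalues = lambda[seq_len(m + 1L)],
    variables = V,
    genome_ids = G$node_ids,
    localization = apply(V, 2L, localization_score),
    component_indicator = if (config$allow_disconnected) lambda[keep] < tol else NULL
  ), class = "diffusion_result")
  resid <- vapply(seq_len(ncol(V)), function(j) {
    max(abs(L %*% V[, j] - lambda[j + 1L] * V[, j]))
  }, numeric(1))
  if (lambda[1L] > tol || any(resid > tol * 10)) {
    stop("eigendecomposition failed residual/zero-eigenvalue checks")
  }
  res
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> %d genomes, %d variables; lambda_1..3 (non-trivial): %s\n",
              length(x$genome_ids), ncol(x$variables),
              paste(signif(x$eigenvalues[2:min(4, length(x$eigenvalues))], 4), collapse = ", ")))
  invisible(x)
}

#' One-call diffusion map pipeline
#'
#' Convenience wrapper: [knn_graph()] then [row_normalized_laplacian()] then
#' [diffusion_eigs()].
#'
#' @inheritParams knn_graph
#' @param ... Passed to [diffusion_config()] when `config` is not given.
#' @param config Optional pre-built configuration.
#' @return A `diffusion_result`.
#' @export
diffusion_map <- function(T, ..., config = NULL) {
  if (is.null(config)) config <- diffusion_config(...)
  G <- knn_graph(T, config)
  L <- row_normalized_laplacian(G)
  diffusion_eigs(L, G, config)
}

#' Inverse participation ratio of a diffusion variable
#'
#' For a unit-norm entry vector v, IPR = sum(v^4) ranges over (1/N, 1\]:
#' a delta vector scores 1, a flat vector scores 1/N. High values flag
#' "localized" variables whose weight concentrates on a small genome subset
#' (a discrete cluster of unique capabilities).
#'
#' @param v Numeric entry vector (unit norm; renormalized defensively).
#' @return IPR as a single number.
#' @export
localization_score <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero vector has no localization score")
  v <- v / nrm
  sum(v^4)
}

#' Pairwise diffusion distances between genomes
#'
#' Euclidean distance over the retained diffusion-variable entries, either
#' unweighted (`flat`) or with coordinate l scaled by 1/lambda_l
#' (`inverse_eigenvalue`, emphasizing slow diffusive modes).
#'
#' @param R A `diffusion_result`.
#' @param weighting `"flat"` (default) or `"inverse_eigenvalue"`.
#' @return Symmetric N x N distance matrix with genome-id dimnames.
#' @export
diffusion_distance <- function(R, weighting = c("flat", "inverse_eigenvalue")) {
  weighting <- match.arg(weighting)
  V <- R$variables
  if (weighting == "inverse_eigenvalue") {
    V <- V / rep(R$eigenvalues[-1L], each = nrow(V))
  }
  as.matrix(stats::dist(V, method = "euclidean"))
}

#' Extremal taxa along a diffusion variable
#'
#' The n genomes with the most negative and the n with the most positive
#' entries; ties on the entry value are broken by genome id (lexicographic).
#'
#' @param R A `diffusion_result`.
#' @param variable_index Variable to inspect (1-based).
#' @param n Number of taxa per sign (default 10); must not exceed N / 2.
#' @return List with `negative_ids` (ascending by entry) and `positive_ids`
#'   (descending by entry).
#' @export
extremal_taxa <- function(R, variable_index, n = 10L) {
  stopifnot(variable_index >= 1L, variable_index <= ncol(R$variables))
  N <- length(R$genome_ids)
  if (n > N / 2) stop(sprintf("n = %d exceeds N/2 = %g", n, N / 2))
  v <- R$variables[, variable_index]
  ids <- R$genome_ids
  neg <- ids[order(v, ids)][seq_len(n)]
  pos <- ids[order(-v, ids)][seq_len(n)]
  list(negative_ids = neg, positive_ids = pos)
}
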