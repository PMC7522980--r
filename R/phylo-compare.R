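#' Parse a Newick tree
#'
#' Thin validated wrapper over [ape::read.tree()]: requires unique leaf
#' labels and nonnegative branch lengths.
#'
#' @param text Newick string, or `file` a path (give exactly one).
#' @param file Optional path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  stopifnot(xor(is.null(text), is.null(file)))
  tree <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file = file),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) stop("invalid Newick: could not parse tree")
  if (is.null(tree$edge.length)) stop("invalid Newick: branch lengths are required")
  if (anyDuplicated(tree$tip.label)) stop("invalid Newick: duplicate leaf labels")
  if (any(tree$edge.length < 0)) stop("invalid Newick: negative branch lengths")
  tree
}

#' Cophenetic (patristic) distance matrix for a set of leaves
#'
#' Entry (i, j) is the total branch length on the path between leaves i and
#' j, via [ape::cophenetic.phylo()], returned in the requested leaf order.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param leaf_order Leaf labels to include, in the desired row/column
#'   order; defaults to all tips in tree order.
#' @return Symmetric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree, leaf_order = tree$tip.label) {
  missing <- setdiff(leaf_order, tree$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("leaves not in tree: %s", paste(missing, collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)
  D[leaf_order, leaf_order, drop = FALSE]
}

condensed_upper <- function(D) D[upper.tri(D)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the condensed upper-triangle entries, with a
#' permutation null built by jointly permuting the rows and columns of the
#' second matrix. One-sided p (positive association) by default, matching
#' the directional question "are metabolically similar genomes also
#' phylogenetically close"; `alternative = "two.sided"` doubles the smaller
#' tail. Uses the add-one estimator, so p >= 1 / (n_perm + 1).
#'
#' @param D1,D2 Symmetric distance matrices with zero diagonals, same
#'   dimension and item order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result`: list with `r`, `p`, `n_perm`, `n_items`,
#'   `alternative`.
#' @export
mantel <- function(D1, D2, n_perm = 999L, seed = 1L,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices must have identical dimensions")
  n <- nrow(D1)
  x <- condensed_upper(D1)
  y <- condensed_upper(D2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: a condensed distance vector is constant")
  }
  r <- stats::cor(x, y)
  null_r <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, condensed_upper(D2[p, p]))
  }, numeric(1)))
  p_greater <- (1 + sum(null_r >= r)) / (1 + n_perm)
  p <- if (alternative == "greater") {
    p_greater
  } else {
    p_less <- (1 + sum(null_r <= r)) / (1 + n_perm)
    min(1, 2 * min(p_greater, p_less))
  }
  structure(list(r = r, p = p, n_perm = as.integer(n_perm), n_items = n,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
              x$r, x$p, x$alternative, x$n_perm, x$n_items))
  invisible(x)
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n_perm = x$n_perm,
                 n_items = x$n_items, alternative = x$alternative)
}

#' @rdname tidy.mantel_result
#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' Align a diffusion result and a tree on shared genome ids
#'
#' Intersects genome ids with tree leaves and returns matched diffusion and
#' cophenetic distance matrices. Ids present on only one side are an error
#' unless `partial = TRUE`, which subsets to the intersection but still
#' names the unmatched ids in a message — silent subsetting is never done.
#'
#' @param R A `diffusion_result`.
#' @param tree An [ape::phylo].
#' @param weighting Passed to [diffusion_distance()].
#' @param partial Allow subsetting to the id intersection.
#' @return List with `diffusion` and `cophenetic` matrices in identical
#'   order, plus `ids`.
#' @export
align_distances <- function(R, tree, weighting = "flat", partial = FALSE) {
  shared <- intersect(R$genome_ids, tree$tip.label)
  unmatched <- c(setdiff(R$genome_ids, tree$tip.label),
                 setdiff(tree$tip.label, R$genome_ids))
  if (length(unmatched) > 0L) {
    msg <- sprintf("%d id(s) not shared between diffusion result and tree: %s",
                   length(unmatched), paste(utils::head(unmatched, 10L), collapse = ", "))
    if (!partial) stop(msg, "; set partial = TRUE to subset to the intersection")
    message(msg)
  }
  if (length(shared) < 3L) stop("fewer than 3 shared ids")
  Dm <- diffusion_distance(R, weighting)[shared, shared]
  Dp <- cophenetic_matrix(tree, shared)
  list(diffusion = Dm, cophenetic = Dp, ids = shared)
}
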