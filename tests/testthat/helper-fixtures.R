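# Shared fixtures, built once per test run. Sizes follow the generators'
# study conditions (tens of genomes, hundreds of traits) so the whole suite
# stays fast while every planted structure is recoverable.

write_edgelist <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# three tiny hand-checkable networks
toy_networks <- function() {
  list(metabolic_network("g1", rbind(c("A", "B"))),
       metabolic_network("g2", rbind(c("A", "B"), c("B", "C"))),
       metabolic_network("g3", rbind(c("B", "A"))))
}

# 3-node unit-weight path graph g1 - g2 - g3
path_graph <- function() {
  w <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  structure(list(node_ids = paste0("g", 1:3), weights = w), class = "neighbor_graph")
}

# planted two-cluster fixture (criterion-level study conditions)
two_cluster_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_clustered_traits(list(c(10, 15), c(10, 15)),
                                    n_core_traits = 20, flip_prob = 0.02,
                                    force_unique = TRUE, seed = 3)
    }
    val
  }
})

branching_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_branching_traits(n_branches = 3L, genomes_per_branch = 15L,
                                    traits_per_step = 4L, n_core_traits = 20L)
    }
    val
  }
})

# disjoint-membership niche table: 2 * n_variables niches, 10 genomes each
disjoint_niches <- function(n_variables = 20L, n_extremal = 10L) {
  nn <- 2L * n_variables
  tibble::tibble(
    niche_id = paste0("v", rep(seq_len(n_variables), each = 2), c("-", "+")),
    variable_index = rep(seq_len(n_variables), each = 2),
    sign = rep(c("negative", "positive"), n_variables),
    genome_ids = split(sprintf("g%04d", seq_len(nn * n_extremal)),
                       rep(seq_len(nn), each = n_extremal)))
}

# brute-force pairwise Euclidean distances (independent oracle)
brute_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  d
}

# brute-force Pearson over explicitly enumerated unordered pairs
brute_pair_cor <- function(D1, D2) {
  n <- nrow(D1)
  x <- c(); y <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- c(x, D1[i, j]); y <- c(y, D2[i, j])
  }
  stats::cor(x, y)
}
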