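test_that("kNN graph reproduces hand-computed weights and breaks ties by input order", {
  T <- as_trait_matrix(matrix(c(1, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE,
                              dimnames = list(paste0("g", 1:3), c("a", "b"))))
  G <- knn_graph(T, diffusion_config(k = 1))
  # d(g1,g2) = d(g2,g3) = 1, d(g1,g3) = sqrt(2); g2's tie {g1, g3} -> g1
  expect_equal(G$weights["g1", "g2"], 1.0)
  expect_equal(G$weights["g2", "g3"], 1.0)
  expect_equal(G$weights["g1", "g3"], 0)
  expect_identical(G$weights, t(G$weights))
  expect_true(all(diag(G$weights) == 0))
})

test_that("kNN graph rejects duplicate rows and oversized k", {
  m <- rbind(g1 = c(1L, 0L), g2 = c(1L, 0L), g3 = c(0L, 1L))
  colnames(m) <- c("a", "b")
  expect_error(knn_graph(as_trait_matrix(m), diffusion_config(k = 1)), "deduplicate")
  cc <- two_cluster_fixture()
  expect_error(knn_graph(cc$traits, diffusion_config(k = nrow(cc$traits))), "smaller")
})

test_that("graph weights are symmetric with zero diagonal on random inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rbinom(30 * 40, 1, 0.3), 30, 40,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("t%02d", 1:40)))
    m <- m[!duplicated(m), ]
    rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    for (mode in c("inverse_distance", "gaussian")) {
      G <- knn_graph(as_trait_matrix(m), diffusion_config(k = 4, weight_mode = mode))
      expect_identical(G$weights, t(G$weights))
      expect_true(all(diag(G$weights) == 0))
      expect_true(all(rowSums(G$weights > 0) >= 4))
      expect_true(all(G$weights >= 0))
    }
  }
})

test_that("row-normalized Laplacian matches 2x2 and 3x3 closed forms", {
  G2 <- structure(list(node_ids = c("a", "b"),
                       weights = matrix(c(0, 1, 1, 0), 2,
                                        dimnames = list(c("a", "b"), c("a", "b")))),
                  class = "neighbor_graph")
  L2 <- row_normalized_laplacian(G2)
  expect_equal(unname(L2), rbind(c(1, -1), c(-1, 1)))
  expect_equal(sort(eigen(L2)$values), c(0, 2), tolerance = 1e-8)

  L3 <- row_normalized_laplacian(path_graph())
  expect_equal(unname(L3), rbind(c(1, -1, 0), c(-0.5, 1, -0.5), c(0, -1, 1)))
  expect_equal(sort(eigen(L3)$values), c(0, 1, 2), tolerance = 1e-8)
  expect_lt(max(abs(rowSums(L3))), 1e-12)

  Giso <- structure(list(node_ids = c("a", "b"),
                         weights = matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
                    class = "neighbor_graph")
  expect_error(row_normalized_laplacian(Giso), "isolated")
})

test_that("path-graph eigenvector matches the exact (1, 0, -1)/sqrt(2) solution", {
  G <- path_graph()
  L <- row_normalized_laplacian(G)
  R <- diffusion_eigs(L, G, diffusion_config(k = 1, n_variables = 1))
  expect_lt(abs(R$eigenvalues[1]), 1e-8)
  expect_equal(R$eigenvalues[2], 1, tolerance = 1e-8)
  v <- R$variables[, 1]
  expect_equal(abs(v), c(g1 = 1, g2 = 0, g3 = 1) / sqrt(2), tolerance = 1e-8)
  expect_lt(v[which.max(abs(v))], 0) # sign convention
})

test_that("disconnected graphs error unless explicitly allowed", {
  w <- matrix(0, 4, 4, dimnames = rep(list(paste0("g", 1:4)), 2))
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  G <- structure(list(node_ids = paste0("g", 1:4), weights = w), class = "neighbor_graph")
  L <- row_normalized_laplacian(G)
  expect_error(diffusion_eigs(L, G, diffusion_config(k = 1, n_variables = 2)),
               "disconnected")
  R <- diffusion_eigs(L, G, diffusion_config(k = 1, n_variables = 2,
                                             allow_disconnected = TRUE))
  expect_true(R$component_indicator[1])
})

test_that("spectral contract holds on a clustered fixture", {
  cc <- two_cluster_fixture()
  G <- knn_graph(cc$traits, diffusion_config(k = 10))
  L <- row_normalized_laplacian(G)
  R <- diffusion_eigs(L, G, diffusion_config(k = 10, n_variables = 8))
  expect_lt(abs(R$eigenvalues[1]), 1e-8)
  expect_true(all(diff(R$eigenvalues) >= -1e-12))
  expect_true(all(R$eigenvalues > -1e-8 & R$eigenvalues < 2 + 1e-8))
  for (j in seq_len(ncol(R$variables))) {
    resid <- max(abs(L %*% R$variables[, j] - R$eigenvalues[j + 1] * R$variables[, j]))
    expect_lt(resid, 1e-8)
    expect_equal(sum(R$variables[, j]^2), 1, tolerance = 1e-10)
  }
})

test_that("pipeline is deterministic: identical input gives bit-identical results", {
  cc <- two_cluster_fixture()
  R1 <- diffusion_map(cc$traits, k = 10, n_variables = 5, allow_disconnected = TRUE)
  R2 <- diffusion_map(cc$traits, k = 10, n_variables = 5, allow_disconnected = TRUE)
  expect_identical(R1, R2)
})

test_that("localization score matches closed forms and flags planted clusters", {
  expect_equal(localization_score(c(1, 0, 0, 0)), 1.0)
  expect_equal(localization_score(rep(1 / 2, 4)), 0.25) # flat: 1/N
  expect_error(localization_score(c(0, 0)), "zero")

  # a small unique-trait cluster yields a more localized variable than a
  # matched unstructured control
  small <- make_clustered_traits(list(c(4, 25), c(26, 5)), n_core_traits = 20,
                                 flip_prob = 0.02, force_unique = TRUE, seed = 11)
  Rs <- diffusion_map(small$traits, k = 10, n_variables = 6, allow_disconnected = TRUE)
  set.seed(12)
  ctrl <- matrix(rbinom(30 * ncol(small$traits), 1, mean(small$traits)), 30,
                 dimnames = list(sprintf("c%02d", 1:30), colnames(small$traits)))
  ctrl <- ctrl[!duplicated(ctrl), ]
  Rc <- diffusion_map(as_trait_matrix(ctrl), k = 10, n_variables = 6,
                      allow_disconnected = TRUE)
  expect_gt(max(Rs$localization), max(Rc$localization))
})

test_that("diffusion distances match the brute-force oracle and axioms", {
  cc <- two_cluster_fixture()
  R <- diffusion_map(cc$traits, k = 10, n_variables = 5, allow_disconnected = TRUE)
  D <- diffusion_distance(R, "flat")
  expect_equal(D, brute_dist(R$variables), tolerance = 1e-12)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  # inverse-eigenvalue mode equals brute force on scaled coordinates
  Dw <- diffusion_distance(R, "inverse_eigenvalue")
  V <- R$variables / rep(R$eigenvalues[-1], each = nrow(R$variables))
  expect_equal(Dw, brute_dist(V), tolerance = 1e-12)

  # m = 1 two-point example
  R1 <- list(eigenvalues = c(0, 0.5),
             variables = matrix(c(-0.5, 0.5), 2, 1,
                                dimnames = list(c("a", "b"), "v1")),
             genome_ids = c("a", "b"))
  class(R1) <- "diffusion_result"
  expect_equal(diffusion_distance(R1, "flat")["a", "b"], 1.0)
})

test_that("extremal taxa are ordered by entry with lexicographic tie-breaks", {
  mk <- function(entries, ids) {
    structure(list(eigenvalues = c(0, 0.1),
                   variables = matrix(entries, ncol = 1, dimnames = list(ids, "v1")),
                   genome_ids = ids), class = "diffusion_result")
  }
  R <- mk(c(-0.9, -0.1, 0.0, 0.2, 0.8), paste0("g", 1:5))
  expect_equal(extremal_taxa(R, 1, 1), list(negative_ids = "g1", positive_ids = "g5"))
  expect_equal(extremal_taxa(R, 1, 2),
               list(negative_ids = c("g1", "g2"), positive_ids = c("g5", "g4")))
  expect_error(extremal_taxa(R, 1, 3), "N/2")

  # two-way tie at -0.9 between g2 and g1: lexicographic order wins
  Rt <- mk(c(-0.9, -0.9, 0.0, 0.2, 0.8), c("g2", "g1", "g3", "g4", "g5"))
  expect_equal(extremal_taxa(Rt, 1, 2)$negative_ids, c("g1", "g2"))
})

test_that("planted two-cluster structure is recovered identically for k in {5, 10, 15}", {
  cc <- two_cluster_fixture()
  assignments <- lapply(c(5, 10, 15), function(k) {
    R <- diffusion_map(cc$traits, k = k, n_variables = 3, allow_disconnected = TRUE)
    # the separating variable: all of cluster1 strictly one side of cluster2
    for (j in 1:3) {
      v <- R$variables[, j]
      a <- v[cc$labels == "cluster1"]; b <- v[cc$labels == "cluster2"]
      if (max(a) < min(b) || max(b) < min(a)) {
        side <- v < mean(range(v))
        if (!side[1]) side <- !side # canonicalize: first genome's side is TRUE
        return(side)
      }
    }
    NULL
  })
  expect_false(any(vapply(assignments, is.null, TRUE)))
  expect_equal(assignments[[1]], assignments[[2]])
  expect_equal(assignments[[2]], assignments[[3]])
})

test_that("diffusion variables order branch genomes monotonically by step", {
  br <- branching_fixture()
  R <- diffusion_map(br$traits, k = 5, n_variables = 10)
  for (b in sort(unique(br$positions$branch[br$positions$branch > 0]))) {
    sel <- br$positions$branch == b
    rho <- apply(R$variables[sel, , drop = FALSE], 2, function(v) {
      suppressWarnings(stats::cor(v, br$positions$step[sel], method = "spearman"))
    })
    expect_gt(max(abs(rho)), 0.9)
  }
})

test_that("tidy and glance expose variables and spectra as tibbles", {
  cc <- two_cluster_fixture()
  R <- diffusion_map(cc$traits, k = 10, n_variables = 4, allow_disconnected = TRUE)
  td <- tidy(R)
  expect_equal(nrow(td), 20 * 4)
  expect_equal(sort(unique(td$variable)), 1:4)
  gl <- glance(R)
  expect_equal(gl$eigenvalue, unname(R$eigenvalues[-1]))
  expect_s3_class(autoplot(R, labels = cc$labels), "ggplot")
  expect_s3_class(plot_eigenvalues(R), "ggplot")
})
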