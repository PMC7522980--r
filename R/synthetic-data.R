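#' Planted-cluster binary trait matrix
#'
#' Emulates a niche space of discrete clusters: every genome carries
#' `n_core_traits` shared core traits; each cluster's members additionally
#' carry a block of traits unique to that cluster; background genomes carry
#' only the core. Each bit is then flipped independently with probability
#' `flip_prob`. Pure function of its arguments and the seed.
#'
#' @param clusters List of `c(n_genomes, n_unique_traits)` pairs (sizes >= 2).
#' @param n_core_traits Traits shared by every genome (default 20).
#' @param n_background_genomes Core-only genomes (default 0).
#' @param flip_prob Independent bit-flip probability in \[0, 0.5) (default 0).
#' @param force_unique Add one private always-on trait per genome so that
#'   rows are distinct even at `flip_prob = 0` (the diffusion step rejects
#'   duplicate rows).
#' @param seed Integer seed.
#' @return List with `traits` (a `trait_matrix`) and `labels` (character
#'   vector: `"cluster<i>"` or `"background"`, aligned with rows).
#' @export
make_clustered_traits <- function(clusters, n_core_traits = 20L,
                                  n_background_genomes = 0L, flip_prob = 0,
                                  force_unique = FALSE, seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob < 0.5, length(clusters) >= 1L)
  sizes <- vapply(clusters, `[`, numeric(1), 1L)
  uniq <- vapply(clusters, `[`, numeric(1), 2L)
  stopifnot(all(sizes >= 2L), all(uniq >= 1L))
  n <- sum(sizes) + n_background_genomes
  if (n < 4L) stop("need at least 4 genomes in total")
  labels <- c(rep(paste0("cluster", seq_along(sizes)), sizes),
              rep("background", n_background_genomes))
  ids <- sprintf("g%03d", seq_len(n))
  core <- matrix(1L, n, n_core_traits,
                 dimnames = list(ids, sprintf("core_%03d", seq_len(n_core_traits))))
  blocks <- lapply(seq_along(sizes), function(b) {
    m <- matrix(0L, n, uniq[b],
                dimnames = list(ids, sprintf("clu%d_%03d", b, seq_len(uniq[b]))))
    m[labels == paste0("cluster", b), ] <- 1L
    m
  })
  vals <- do.call(cbind, c(list(core), blocks))
  vals <- withr::with_seed(seed, {
    flips <- matrix(stats::runif(length(vals)) < flip_prob, nrow(vals))
    v <- abs(vals - flips)
    storage.mode(v) <- "integer"
    v
  })
  if (force_unique) {
    priv <- diag(1L, n)
    dimnames(priv) <- list(ids, sprintf("priv_%03d", seq_len(n)))
    vals <- cbind(vals, priv)
  }
  list(traits = new_trait_matrix(vals), labels = labels)
}

#' Branching-manifold binary trait matrix
#'
#' Emulates quasi one-dimensional branches rising from a common core: one
#' shared root genome carries only the `n_core_traits` core; the genome at
#' step s of branch b additionally carries the first `s * traits_per_step`
#' of that branch's cumulative trait sequence, so within-branch Hamming
#' distance between steps s and t is exactly `|s - t| * traits_per_step`.
#'
#' @param n_branches Number of branches.
#' @param genomes_per_branch Steps per branch (step 1 .. this value).
#' @param traits_per_step Traits gained per step along a branch.
#' @param n_core_traits Shared core traits.
#' @param seed Integer seed (kept for interface symmetry; the construction
#'   is deterministic).
#' @return List with `traits` (a `trait_matrix`) and `positions` (tibble:
#'   genome_id, branch, step; the root has branch 0, step 0).
#' @export
make_branching_traits <- function(n_branches = 3L, genomes_per_branch = 15L,
                                  traits_per_step = 4L, n_core_traits = 20L,
                                  seed = 1L) {
  stopifnot(n_branches >= 1L, genomes_per_branch >= 1L, traits_per_step >= 1L,
            n_core_traits >= 1L)
  pos <- rbind(
    data.frame(branch = 0L, step = 0L),
    expand.grid(step = seq_len(genomes_per_branch), branch = seq_len(n_branches))[, 2:1]
  )
  pos$genome_id <- sprintf("b%d_s%02d", pos$branch, pos$step)
  n <- nrow(pos)
  core <- matrix(1L, n, n_core_traits,
                 dimnames = list(pos$genome_id, sprintf("core_%03d", seq_len(n_core_traits))))
  per_branch <- lapply(seq_len(n_branches), function(b) {
    ntr <- genomes_per_branch * traits_per_step
    m <- matrix(0L, n, ntr,
                dimnames = list(pos$genome_id, sprintf("br%d_%03d", b, seq_len(ntr))))
    on_b <- which(pos$branch == b)
    for (i in on_b) m[i, seq_len(pos$step[i] * traits_per_step)] <- 1L
    m
  })
  vals <- do.call(cbind, c(list(core), per_branch))
  list(traits = new_trait_matrix(vals),
       positions = tibble::as_tibble(pos[, c("genome_id", "branch", "step")]))
}

#' Random Yule (pure-birth) tree
#'
#' Starting from two lineages, a uniformly chosen active lineage splits
#' after each exponential waiting time (unit mean per lineage, i.e. total
#' rate = number of active lineages) until `n_leaves` lineages exist; the
#' final waiting period is appended to every pendant edge, so all branch
#' lengths are positive.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param seed Integer seed.
#' @return An [ape::phylo] binary rooted tree with leaves `t1..tN`.
#' @export
make_random_tree <- function(n_leaves, seed = 1L) {
  if (n_leaves < 3L) stop("need at least 3 leaves")
  withr::with_seed(seed, {
    # grow a node table forward in time; active nodes are current tips
    max_nodes <- 2L * n_leaves - 1L
    kids <- vector("list", max_nodes)
    birth <- numeric(max_nodes)
    len <- numeric(max_nodes)
    kids[[1L]] <- c(2L, 3L) # root splits at time 0
    active <- c(2L, 3L)
    node_count <- 3L
    t_now <- 0
    while (length(active) < n_leaves) {
      t_now <- t_now + stats::rexp(1L, rate = length(active))
      i <- sample.int(length(active), 1L)
      v <- active[i]
      len[v] <- t_now - birth[v]
      kids[[v]] <- c(node_count + 1L, node_count + 2L)
      birth[node_count + 1:2] <- t_now
      active <- c(active[-i], node_count + 1L, node_count + 2L)
      node_count <- node_count + 2L
    }
    t_now <- t_now + stats::rexp(1L, rate = length(active))
    len[active] <- t_now - birth[active]
    leaf_label <- character(max_nodes)
    leaf_label[sort(active)] <- paste0("t", seq_len(n_leaves))
    nwk <- function(v) {
      if (is.null(kids[[v]])) return(sprintf("%s:%.10g", leaf_label[v], len[v]))
      sprintf("(%s,%s):%.10g", nwk(kids[[v]][1L]), nwk(kids[[v]][2L]), len[v])
    }
    text <- sprintf("(%s,%s);", nwk(2L), nwk(3L))
    parse_newick(text = text)
  })
}

#' Two-state Markov trait evolution on a tree
#'
#' Each trait evolves independently along the tree as a two-state
#' continuous-time Markov chain: absent -> present at `gain_rate` and
#' present -> absent at `loss_rate` per unit branch length. The root state
#' is drawn Bernoulli(`root_presence_prob`); leaf states form the trait
#' matrix. Over a branch of length t with total rate q = gain + loss, the
#' transition probabilities follow the standard closed form, e.g.
#' P(0 -> 1) = (gain / q) (1 - exp(-q t)).
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param n_traits Number of independent traits.
#' @param gain_rate,loss_rate Nonnegative transition rates.
#' @param root_presence_prob Probability a trait is present at the root.
#' @param seed Integer seed.
#' @return A `trait_matrix` (leaves x traits, tree tip order).
#' @export
simulate_traits_on_tree <- function(tree, n_traits, gain_rate = 0.5,
                                    loss_rate = 0.5, root_presence_prob = 0.5,
                                    seed = 1L) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, is.finite(gain_rate), is.finite(loss_rate),
            root_presence_prob >= 0, root_presence_prob <= 1, n_traits >= 1L)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  q <- gain_rate + loss_rate
  # preorder (cladewise) edge traversal so parent states exist before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr$edge
  elen <- tr$edge.length
  withr::with_seed(seed, {
    state <- matrix(NA_integer_, ntip + tree$Nnode, n_traits)
    state[root, ] <- as.integer(stats::runif(n_traits) < root_presence_prob)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      s <- state[par, ]
      if (q == 0) {
        state[child, ] <- s
      } else {
        pe <- 1 - exp(-q * elen[e])
        p1 <- ifelse(s == 1L, 1 - (loss_rate / q) * pe, (gain_rate / q) * pe)
        state[child, ] <- as.integer(stats::runif(n_traits) < p1)
      }
    }
    m <- state[seq_len(ntip), , drop = FALSE]
    dimnames(m) <- list(tree$tip.label, sprintf("trait_%05d", seq_len(n_traits)))
    new_trait_matrix(m)
  })
}

#' Niche-structured synthetic communities with a match table
#'
#' For each ecosystem, draws `n_samples_per_ecosystem` community censuses:
#' every niche is occupied independently with that ecosystem's per-niche
#' probability, by including the pseudo-taxon of one randomly chosen member
#' genome. The match table links each pseudo-taxon (`"asv_<genome>"`) to its
#' genome at `match_identity` percent identity.
#'
#' @param niches Tibble from [build_niches()].
#' @param ecosystem_profiles Named list: ecosystem label -> numeric vector of
#'   occupancy probabilities (length `nrow(niches)`, or length 1 recycled).
#' @param n_samples_per_ecosystem Samples per ecosystem (default 20).
#' @param match_identity Percent identity reported for every pseudo-taxon
#'   (default 99).
#' @param seed Integer seed.
#' @return List with `censuses` (tibble: sample_id, ecosystem_label, taxa
#'   list column) and `matches` (tibble: taxon_id, genome_id, pct_identity).
#' @export
make_communities <- function(niches, ecosystem_profiles,
                             n_samples_per_ecosystem = 20L,
                             match_identity = 99, seed = 1L) {
  stopifnot(length(ecosystem_profiles) >= 1L, !is.null(names(ecosystem_profiles)))
  probs <- lapply(ecosystem_profiles, function(p) {
    p <- rep_len(p, nrow(niches))
    stopifnot(all(p >= 0 & p <= 1))
    p
  })
  if (all(unlist(probs) == 0)) {
    stop("all occupancy probabilities are zero: censuses would be empty")
  }
  genomes <- sort(unique(unlist(niches$genome_ids)))
  matches <- tibble::tibble(taxon_id = paste0("asv_", genomes),
                            genome_id = genomes, pct_identity = match_identity)
  censuses <- withr::with_seed(seed, {
    rows <- list()
    for (eco in names(probs)) {
      for (s in seq_len(n_samples_per_ecosystem)) {
        occ <- stats::runif(nrow(niches)) < probs[[eco]]
        taxa <- unique(vapply(which(occ), function(i) {
          paste0("asv_", sample(niches$genome_ids[[i]], 1L))
        }, character(1)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sprintf("%s_s%03d", eco, s),
          ecosystem_label = eco, taxa = list(taxa))
      }
    }
    dplyr::bind_rows(rows)
  })
  empty <- lengths(censuses$taxa) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d chance-empty sample(s)", sum(empty)))
    censuses <- censuses[!empty, ]
  }
  list(censuses = censuses, matches = matches)
}
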