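#' Metabolite membership sets across genomes
#'
#' Maps each metabolite (network node) to the set of genomes whose network
#' contains it, dropping degenerate sets outside `[min_size, max_size]`:
#' sets near 0 or N carry no ranking information.
#'
#' @param networks List of `metabolic_network` objects.
#' @param min_size Minimum genomes per retained metabolite (default 5).
#' @param max_size Maximum genomes per retained metabolite (default N - 5).
#' @return Named list: metabolite id -> character vector of genome ids.
#' @export
metabolite_sets <- function(networks, min_size = 5L, max_size = length(networks) - 5L) {
  stopifnot(length(networks) >= 1L)
  long <- lapply(networks, function(n) {
    if (length(n$metabolites) == 0L) return(NULL)
    data.frame(metabolite = n$metabolites, genome_id = n$genome_id)
  })
  long <- do.call(rbind, long)
  if (is.null(long)) return(list())
  sets <- split(long$genome_id, long$metabolite)
  sets[lengths(sets) >= min_size & lengths(sets) <= max_size]
}

#' Running-sum enrichment score
#'
#' Classic GSEA statistic: walking down a genome ranking, the running sum
#' rises by `|stat|^exponent / sum_members |stat|^exponent` at member genomes
#' and falls by `1 / (N - |S|)` otherwise; ES is the signed extreme deviation
#' (the maximum if it dominates in magnitude, else the minimum).
#'
#' @param ranked_genomes Genome ids, already ranked (descending stat).
#' @param stats Per-genome ranking statistic, aligned with `ranked_genomes`.
#' @param member_set Genome ids in the set; proper nonempty subset.
#' @param exponent Weighting exponent (0 = unweighted Kolmogorov-Smirnov
#'   walk, 1 = stat-weighted as in fgsea).
#' @return ES in \[-1, 1\].
#' @export
running_sum_es <- function(ranked_genomes, stats, member_set, exponent = 1) {
  N <- length(ranked_genomes)
  hit <- ranked_genomes %in% member_set
  nh <- sum(hit)
  if (nh == 0L || nh == N) stop("member set must be a proper nonempty subset of the ranking")
  w <- abs(stats)^exponent
  denom <- sum(w[hit])
  if (denom == 0) { # all member stats zero: fall back to unweighted hits
    inc <- hit / nh
  } else {
    inc <- ifelse(hit, w / denom, 0)
  }
  steps <- inc - (!hit) / (N - nh)
  rs <- cumsum(steps)
  hi <- max(rs)
  lo <- min(rs)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Permutation p-value for an enrichment score
#'
#' Builds the null from `n_perm` random genome sets of the same size and
#' returns the sign-matched add-one estimator
#' p = (1 + #\{null ES at least as extreme, same direction\}) / (1 + n_perm).
#'
#' @inheritParams running_sum_es
#' @param n_perm Number of random sets (>= 99).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `es` and `p`.
#' @export
permutation_p <- function(ranked_genomes, stats, member_set, n_perm = 999L,
                          seed = 1L, exponent = 1) {
  stopifnot(n_perm >= 99L)
  es <- running_sum_es(ranked_genomes, stats, member_set, exponent)
  nh <- sum(ranked_genomes %in% member_set)
  N <- length(ranked_genomes)
  null_es <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    running_sum_es(ranked_genomes, stats, sample(ranked_genomes, nh), exponent)
  }, numeric(1)))
  extreme <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
  list(es = es, p = (1 + extreme) / (1 + n_perm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with the input validated
#' to lie in (0, 1\]; values are returned in input order.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Metabolite enrichment along one diffusion variable
#'
#' Ranks genomes by the variable's entries (descending), scores every
#' metabolite set with the running-sum statistic and a seeded permutation
#' p-value, and adjusts p across all metabolites tested for this variable
#' (Benjamini-Hochberg). Metabolites with adjusted p below `alpha` are
#' flagged significant.
#'
#' @param R A `diffusion_result`.
#' @param sets Output of [metabolite_sets()].
#' @param variable_index Which diffusion variable to test.
#' @param n_perm Permutations per metabolite (default 999).
#' @param seed Integer seed.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param exponent Running-sum weighting exponent (default 1).
#' @return An `enrichment_table` tibble with columns metabolite_id,
#'   variable_index, es, p, p_adj, set_size, significant; sorted by p_adj
#'   then metabolite_id.
#' @export
enrich_variable <- function(R, sets, variable_index, n_perm = 999L, seed = 1L,
                            alpha = 0.05, exponent = 1) {
  stopifnot(variable_index >= 1L, variable_index <= ncol(R$variables),
            length(sets) >= 1L)
  v <- R$variables[, variable_index]
  ord <- order(-v, R$genome_ids)
  ranked <- R$genome_ids[ord]
  stats <- v[ord]
  # one derived sub-seed per metabolite, stable under set order
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, length(sets)))
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], ranked)
    pr <- permutation_p(ranked, stats, members, n_perm, seeds[i], exponent)
    tibble::tibble(metabolite_id = names(sets)[i], variable_index = variable_index,
                   es = pr$es, p = pr$p, set_size = length(members))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- dplyr::arrange(out, .data$p_adj, .data$metabolite_id)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' @method glance enrichment_table
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble::tibble(n_metabolites = nrow(x), n_significant = sum(x$significant),
                 min_p_adj = min(x$p_adj), variable_index = x$variable_index[1L])
}
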