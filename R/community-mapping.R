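#' Filter a taxon-to-genome match table by percent identity
#'
#' Keeps rows at or above the threshold (inclusive, "97% or greater").
#'
#' @param matches Tibble/data frame with columns taxon_id, genome_id,
#'   pct_identity (0-100).
#' @param threshold Minimum percent identity retained (default 97).
#' @return Filtered tibble.
#' @export
filter_matches <- function(matches, threshold = 97) {
  stopifnot(all(c("taxon_id", "genome_id", "pct_identity") %in% names(matches)),
            all(matches$pct_identity >= 0 & matches$pct_identity <= 100))
  dplyr::filter(tibble::as_tibble(matches), .data$pct_identity >= threshold)
}

#' Define extremal-strategy niches from a diffusion result
#'
#' A niche is the set of `n_extremal` genomes at one sign of one diffusion
#' variable; the first `n_variables` variables give `2 * n_variables`
#' niches (with the defaults, 50 variables x 10 genomes x 2 signs = 100
#' extremal metabolic strategies). Niche ids are `"v{index}+"` / `"v{index}-"`.
#'
#' @param R A `diffusion_result` with at least `n_variables` variables.
#' @param n_variables Number of leading variables (default 50).
#' @param n_extremal Genomes per extremum (default 10).
#' @return Tibble with columns niche_id, variable_index, sign, genome_ids
#'   (list column of length-`n_extremal` character vectors).
#' @export
build_niches <- function(R, n_variables = 50L, n_extremal = 10L) {
  if (ncol(R$variables) < n_variables) {
    stop(sprintf("diffusion result has %d variables; %d requested",
                 ncol(R$variables), n_variables))
  }
  rows <- lapply(seq_len(n_variables), function(i) {
    ex <- extremal_taxa(R, i, n_extremal)
    tibble::tibble(
      niche_id = paste0("v", i, c("-", "+")),
      variable_index = i,
      sign = c("negative", "positive"),
      genome_ids = list(ex$negative_ids, ex$positive_ids))
  })
  dplyr::bind_rows(rows)
}

#' Niche occupancy vector for one community census
#'
#' A niche is occupied iff at least one taxon in the census maps (via the
#' pre-filtered match table) to one of the niche's extremal genomes;
#' abundances are ignored and unmatched taxa contribute nothing.
#'
#' @param census List or one-row tibble with fields `sample_id`,
#'   `ecosystem_label`, `taxa` (character vector of taxon ids).
#' @param matches Match table already passed through [filter_matches()].
#' @param niches Tibble from [build_niches()].
#' @return Named integer 0/1 vector over `niches$niche_id`.
#' @export
niche_occupancy <- function(census, matches, niches) {
  taxa <- if (is.list(census$taxa)) census$taxa[[1L]] else census$taxa
  genomes <- unique(matches$genome_id[matches$taxon_id %in% taxa])
  occ <- vapply(niches$genome_ids, function(g) as.integer(any(g %in% genomes)),
                integer(1))
  names(occ) <- niches$niche_id
  occ
}

#' Read community censuses from long-format TSV
#'
#' @param path TSV with columns sample_id, ecosystem_label, taxon_id.
#' @return Nested tibble: one row per sample with a `taxa` list column.
#' @export
read_censuses <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("sample_id", "ecosystem_label", "taxon_id") %in% names(df)))
  tibble::as_tibble(df) |>
    dplyr::group_by(.data$sample_id, .data$ecosystem_label) |>
    dplyr::summarise(taxa = list(unique(.data$taxon_id)), .groups = "drop")
}

#' Per-ecosystem metabolic fingerprint
#'
#' For each ecosystem label, the proportion of its samples whose community
#' occupies each extremal niche.
#'
#' @param censuses Tibble with columns sample_id, ecosystem_label, taxa
#'   (list column), one row per sample.
#' @param matches Pre-filtered match table.
#' @param niches Tibble from [build_niches()].
#' @return A `fingerprint`: numeric matrix, ecosystem labels x niche ids,
#'   entries in \[0, 1\].
#' @export
ecosystem_fingerprint <- function(censuses, matches, niches) {
  stopifnot(nrow(censuses) >= 1L, !anyDuplicated(censuses$sample_id))
  occ <- t(vapply(seq_len(nrow(censuses)),
                  function(i) niche_occupancy(censuses[i, ], matches, niches),
                  integer(nrow(niches))))
  labs <- censuses$ecosystem_label
  F <- rowsum(occ, labs) / as.vector(table(labs)[sort(unique(labs))])
  colnames(F) <- niches$niche_id
  structure(F, class = c("fingerprint", class(F)))
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d ecosystems x %d niches (mean occupancy %.3f)\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Tidy a fingerprint into long format
#'
#' @param x A `fingerprint`.
#' @param ... Unused.
#' @return Tibble with ecosystem_label, niche_id, proportion.
#' @method tidy fingerprint
#' @export
tidy.fingerprint <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "ecosystem_label") |>
    tidyr::pivot_longer(-"ecosystem_label", names_to = "niche_id",
                        values_to = "proportion")
}

#' Ward clustering of ecosystem fingerprints
#'
#' Agglomerative clustering of fingerprint rows under Euclidean distance
#' with Ward's minimum-variance criterion ([stats::hclust()],
#' `method = "ward.D2"`); deterministic given input order.
#'
#' @param F A `fingerprint` (or numeric matrix) with >= 2 rows.
#' @return An [stats::hclust] object.
#' @export
ward_clustering <- function(F) {
  if (nrow(F) < 2L) stop("need at least 2 ecosystem rows to cluster")
  stats::hclust(stats::dist(unclass(F), method = "euclidean"), method = "ward.D2")
}

#' Cut a Ward tree at the top split
#'
#' @param hc An [stats::hclust] from [ward_clustering()].
#' @return Named integer vector of group labels (1/2) from `cutree(k = 2)`.
#' @export
top_split <- function(hc) stats::cutree(hc, k = 2L)
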