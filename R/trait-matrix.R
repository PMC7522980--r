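#' Read a per-genome metabolic network from a two-column edge list
#'
#' Parses a tab-separated edge list in which every non-comment line names one
#' directed substrate -> product reaction edge. Nodes are metabolite
#' identifiers; duplicate lines collapse to a single edge.
#'
#' @param path Path to a TSV file with two columns: substrate, product.
#'   Lines starting with `#` and blank lines are ignored.
#' @param genome_id Non-empty string identifying the genome.
#' @return A `metabolic_network` object: a list with `genome_id`,
#'   `metabolites` (character vector of node ids) and `edges` (two-column
#'   character matrix of substrate/product pairs, duplicates removed).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "A\tB", "B\tC"), f)
#' net <- read_network_edgelist(f, "g1")
#' nrow(net$edges)  # 2
#' @export
read_network_edgelist <- function(path, genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warning(sprintf("empty edge list for genome '%s'", genome_id))
    return(new_metabolic_network(genome_id, character(), empty_edges()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("malformed edge list '%s': expected 2 tab-separated fields at line %d, found %d",
                 path, lineno[bad], nf[bad]))
  }
  m <- do.call(rbind, parts)
  m <- unique(m)
  colnames(m) <- c("substrate", "product")
  new_metabolic_network(genome_id, sort(unique(c(m))), m)
}

empty_edges <- function() {
  matrix(character(), ncol = 2L, dimnames = list(NULL, c("substrate", "product")))
}

new_metabolic_network <- function(genome_id, metabolites, edges) {
  structure(list(genome_id = genome_id, metabolites = metabolites, edges = edges),
            class = "metabolic_network")
}

#' Construct a metabolic network in memory
#'
#' Convenience constructor used by the generators and tests; enforces the
#' same invariants as [read_network_edgelist()].
#'
#' @param genome_id Non-empty genome identifier.
#' @param edges Two-column character matrix or data frame (substrate, product);
#'   duplicates are collapsed.
#' @return A `metabolic_network`.
#' @export
metabolic_network <- function(genome_id, edges) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    return(new_metabolic_network(genome_id, character(), empty_edges()))
  }
  stopifnot(ncol(edges) == 2L)
  mode(edges) <- "character"
  edges <- unique(edges)
  colnames(edges) <- c("substrate", "product")
  new_metabolic_network(genome_id, sort(unique(c(edges))), edges)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s: %d metabolites, %d directed edges\n",
              x$genome_id, length(x$metabolites), nrow(x$edges)))
  invisible(x)
}

#' Read a directory of per-genome edge lists
#'
#' Each `*.tsv` file holds one genome's network; the filename stem is the
#' genome id.
#'
#' @param dir Directory containing `*.tsv` edge lists.
#' @return List of `metabolic_network` objects, ordered by filename.
#' @export
read_networks_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no .tsv edge lists found in '%s'", dir))
  ids <- sub("\\.tsv$", "", basename(files))
  unname(Map(read_network_edgelist, files, ids))
}

#' Read many networks from a single long-format TSV
#'
#' @param path TSV with three columns: genome_id, substrate, product.
#'   `#`-comment lines ignored.
#' @return List of `metabolic_network` objects in order of first appearance.
#' @export
read_networks_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", col.names = c("genome_id", "substrate", "product"))
  ids <- unique(df$genome_id)
  lapply(ids, function(g) metabolic_network(g, as.matrix(df[df$genome_id == g, 2:3])))
}

trait_label <- function(substrate, product) paste0(substrate, "->", product)

#' Assemble the binary genome x trait matrix
#'
#' Traits are the unique directed substrate -> product edges observed across
#' all input networks, labelled `"substrate->product"` and ordered
#' lexicographically; entry (i, j) is 1 iff genome i's network contains
#' trait j's edge. Row order preserves input order.
#'
#' @param networks List of `metabolic_network` objects with unique genome ids
#'   (at least two).
#' @return A `trait_matrix`: an integer 0/1 matrix with genome ids as row
#'   names and trait labels as column names.
#' @export
build_trait_matrix <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2L)
  ids <- vapply(networks, function(n) n$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate genome_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  per_genome <- lapply(networks, function(n) {
    if (nrow(n$edges) == 0L) character() else trait_label(n$edges[, 1L], n$edges[, 2L])
  })
  traits <- sort(unique(unlist(per_genome)))
  vals <- matrix(0L, nrow = length(ids), ncol = length(traits),
                 dimnames = list(ids, traits))
  for (i in seq_along(per_genome)) vals[i, per_genome[[i]]] <- 1L
  new_trait_matrix(vals)
}

new_trait_matrix <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)))
  storage.mode(m) <- "integer"
  class(m) <- c("trait_matrix", class(m))
  m
}

#' Coerce a 0/1 matrix with dimnames to a trait_matrix
#'
#' @param m Binary matrix with genome row names and trait column names.
#' @return A `trait_matrix`.
#' @export
as_trait_matrix <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)),
            !anyDuplicated(rownames(m)), !anyDuplicated(colnames(m)))
  new_trait_matrix(as.matrix(m))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d genomes x %d traits (density %.3f)\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Drop traits constant across all genomes
#'
#' Removes columns whose entries are identical for every genome. Pairwise
#' Euclidean row distances are unchanged, since constant coordinates
#' contribute nothing to any squared difference.
#'
#' @param T A `trait_matrix`.
#' @return The `trait_matrix` restricted to variable traits.
#' @export
drop_constant_traits <- function(T) {
  stopifnot(inherits(T, "trait_matrix"))
  keep <- column_varies(T) # TRUE where column varies
  if (!any(keep)) stop("no variable traits: all columns are constant")
  if (all(keep)) return(T)
  new_trait_matrix(T[, keep, drop = FALSE])
}

column_varies <- function(m) colSums(m != rep(m[1L, ], each = nrow(m))) > 0L

#' Write a trait matrix as TSV
#'
#' Header row holds trait names; the first column, `genome_id`, holds row ids.
#'
#' @param T A `trait_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(T, path) {
  stopifnot(inherits(T, "trait_matrix"))
  df <- data.frame(genome_id = rownames(T), unclass(T), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait matrix written by [write_trait_matrix()]
#'
#' @param path TSV path.
#' @return A `trait_matrix`.
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c(genome_id = "character"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$genome_id
  new_trait_matrix(m)
}

#' Tidy a trait matrix into long format
#'
#' @param x A `trait_matrix`.
#' @param ... Unused.
#' @return Tibble with columns genome_id, trait, present.
#' @method tidy trait_matrix
#' @export
tidy.trait_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "genome_id") |>
    tidyr::pivot_longer(-"genome_id", names_to = "trait", values_to = "present")
}
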