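#' Enumerate the genotype space of g-gene genomes over a pool of L genes
#'
#' A genotype is an unordered set of `g` distinct toxin/antitoxin gene labels
#' drawn from a pool of `L` (labels are the integers `0..L-1`). Genotypes are
#' stored canonically as sorted tuples in lexicographic order, so the space
#' has exactly `K = choose(L, g)` members: for doubleton genomes (g = 2)
#' `K = L(L-1)/2`.
#'
#' @param L pool size: number of distinct toxin/antitoxin gene pairs (>= g).
#' @param g genes per genome, 2 or 3.
#' @return An object of class `genotype_space` with elements `L`, `g`, `K`,
#'   `genotypes` (a `K x g` integer matrix of sorted gene labels, one row per
#'   genotype), and `membership` (a `K x L` binary matrix whose row k has
#'   ones exactly at the genes of genotype k).
#' @examples
#' sp <- build_space(4, 2)
#' sp$K            # 6
#' sp$genotypes[1, ] # genes 0 and 1
#' @export
build_space <- function(L, g = 2) {
  if (!is.numeric(L) || length(L) != 1 || L != round(L))
    stop("`L` must be a single integer")
  if (!g %in% c(2, 3)) stop("`g` must be 2 or 3")
  if (L < g) stop("`L` must be at least `g`")
  L <- as.integer(L); g <- as.integer(g)
  genotypes <- t(utils::combn(0:(L - 1L), g))
  storage.mode(genotypes) <- "integer"
  K <- nrow(genotypes)
  membership <- matrix(0L, K, L)
  for (j in seq_len(g)) membership[cbind(seq_len(K), genotypes[, j] + 1L)] <- 1L
  # flat lookup from the sorted tuple's mixed-radix code to 0-based index,
  # shared with the C++ core
  idx_lookup <- rep.int(-1L, L^g)
  code <- genotypes[, 1]
  for (j in 2:g) code <- code * L + genotypes[, j]
  idx_lookup[code + 1L] <- seq_len(K) - 1L
  structure(list(L = L, g = g, K = K, genotypes = genotypes,
                 membership = membership, idx_lookup = idx_lookup),
            class = "genotype_space")
}

#' @export
print.genotype_space <- function(x, ...) {
  cat(sprintf("genotype_space: L = %d genes, g = %d per genome, K = %d genotypes\n",
              x$L, x$g, x$K))
  invisible(x)
}

#' Position of a genotype in the canonical order
#'
#' @param space a [build_space()] object.
#' @param tuple integer vector of `g` distinct gene labels (any order).
#' @return 1-based index into `space$genotypes`, or `NA` if the tuple is not
#'   a valid genotype.
#' @export
index_of <- function(space, tuple) {
  stopifnot(inherits(space, "genotype_space"))
  if (length(tuple) != space$g) return(NA_integer_)
  tuple <- sort(as.integer(tuple))
  if (any(tuple < 0L) || any(tuple >= space$L)) return(NA_integer_)
  code <- tuple[1]
  for (j in 2:space$g) code <- code * space$L + tuple[j]
  k <- space$idx_lookup[code + 1L]
  if (k < 0L) NA_integer_ else k + 1L
}

#' Gene abundances induced by genotype abundances
#'
#' The abundance of gene `l` is the summed population size of every genotype
#' carrying `l`; total gene abundance is therefore exactly `g` times total
#' genotype abundance.
#'
#' @param space a [build_space()] object.
#' @param counts nonnegative numeric vector of length `K`.
#' @return numeric vector of length `L` (position `l + 1` is gene label `l`).
#' @export
gene_abundances <- function(space, counts) {
  stopifnot(inherits(space, "genotype_space"))
  if (length(counts) != space$K)
    stop(sprintf("`counts` must have length K = %d", space$K))
  if (any(counts < 0)) stop("`counts` must be nonnegative")
  as.vector(crossprod(space$membership, counts))
}

#' Genotype produced by a single-gene horizontal transfer
#'
#' One HGT event replaces the gene in `replaced_slot` of the recipient
#' genotype with `incoming_gene`. Events that would duplicate a gene already
#' present in another slot, or that reproduce the recipient unchanged, are
#' no-ops and return `NULL`.
#'
#' Gene labels are 0-based (`0..L-1`); `replaced_slot` is a 1-based position
#' into the recipient tuple, following R indexing convention.
#'
#' @param recipient sorted integer tuple of `g` distinct gene labels.
#' @param incoming_gene gene label to insert.
#' @param replaced_slot which slot of `recipient` to overwrite (1..g).
#' @return sorted integer tuple of the product genotype, or `NULL` for a
#'   no-op event.
#' @examples
#' hgt_product(c(2, 3), 1, 1)  # recipient CD gains B in place of C -> BD
#' hgt_product(c(0, 1), 0, 2)  # duplicate gene -> NULL
#' @export
hgt_product <- function(recipient, incoming_gene, replaced_slot) {
  g <- length(recipient)
  if (is.unsorted(recipient, strictly = TRUE))
    stop("`recipient` must be a sorted tuple of distinct genes")
  if (length(replaced_slot) != 1 || replaced_slot < 1 || replaced_slot > g)
    stop("`replaced_slot` out of range")
  if (incoming_gene %in% recipient[-replaced_slot]) return(NULL) # duplicate
  if (recipient[replaced_slot] == incoming_gene) return(NULL)    # identity
  out <- recipient
  out[replaced_slot] <- as.integer(incoming_gene)
  sort(out)
}

#' Phage-bacteria interaction matrix
#'
#' In `matched` mode phage genotype k infects only bacterial genotype k (the
#' one-phage-one-bacterium default: a bacterium carrying toxins A,B is only
#' infected by a phage carrying antitoxins a,b). In `random_sparse` mode each
#' entry is independently 1 with probability `density`, after which any empty
#' row or column is repaired by adding one uniformly placed entry, so every
#' bacterium has at least one predator and every phage at least one host.
#'
#' @param space a [build_space()] object.
#' @param mode `"matched"` or `"random_sparse"`.
#' @param density expected fraction of nonzero entries (random_sparse only),
#'   in (0, 1].
#' @param seed RNG seed used to draw the sparse matrix (recorded in the
#'   result).
#' @return object of class `interaction_matrix`: list with `mode`, `density`,
#'   `seed`, `K`, and `M` (a `K x K` 0/1 matrix, or `NULL` in matched mode,
#'   which stands for the identity).
#' @export
build_interaction <- function(space, mode = c("matched", "random_sparse"),
                              density = NULL, seed = NULL) {
  stopifnot(inherits(space, "genotype_space"))
  mode <- match.arg(mode)
  K <- space$K
  M <- NULL
  if (mode == "random_sparse") {
    if (is.null(density) || density <= 0 || density > 1)
      stop("`density` must be in (0, 1] for random_sparse mode")
    if (!is.null(seed)) set.seed(seed)
    M <- matrix(as.numeric(runif(K * K) < density), K, K)
    for (i in which(rowSums(M) == 0)) M[i, sample.int(K, 1)] <- 1
    for (j in which(colSums(M) == 0)) M[sample.int(K, 1), j] <- 1
  }
  structure(list(mode = mode, density = density, seed = seed, K = K, M = M),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  if (x$mode == "matched")
    cat(sprintf("interaction_matrix: matched (identity), K = %d\n", x$K))
  else
    cat(sprintf("interaction_matrix: random_sparse, K = %d, density = %g, realized = %.4f\n",
                x$K, x$density, mean(x$M)))
  invisible(x)
}

#' Serialize a genotype space to a two-column delimited table
#'
#' Columns: 0-based genotype index, comma-joined gene labels.
#' @param space a [build_space()] object.
#' @param path file to write.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "genotype_space"))
  genes <- apply(space$genotypes, 1, paste, collapse = ",")
  write.table(data.frame(index = seq_len(space$K) - 1L, genes = genes),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an interaction matrix as a coordinate list plus JSON header
#'
#' Writes `<path>` as a TSV of (row, col) 0-based nonzero coordinates and
#' `<path>.json` holding mode/density/seed/K.
#' @param im an [build_interaction()] object.
#' @param path file to write.
#' @export
write_interaction <- function(im, path) {
  stopifnot(inherits(im, "interaction_matrix"))
  if (im$mode == "matched") {
    coords <- data.frame(row = seq_len(im$K) - 1L, col = seq_len(im$K) - 1L)
  } else {
    w <- which(im$M != 0, arr.ind = TRUE)
    coords <- data.frame(row = w[, 1] - 1L, col = w[, 2] - 1L)
  }
  write.table(coords, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(mode = im$mode, density = im$density,
                            seed = im$seed, K = im$K),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
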