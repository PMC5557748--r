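# The community phenotype: raw pairwise sequence distances, the OTU
# similarity matrix Z, and the similarity-sensitive Hill diversity
# qD^Z(p) of each sample.

#' Raw pairwise distances between aligned sequences
#'
#' Distance = proportion of differing nucleotides over comparable aligned
#' positions ("raw" model of molecular evolution: no substitution-rate
#' assumptions). Positions where both sequences have a gap, or where
#' either has an N, are excluded from the denominator; a gap aligned to a
#' base counts as a difference.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
raw_distances <- function(seqs) {
  seqs <- validate_aligned_seqs(seqs)
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  gap <- mat == "-"
  nn <- mat == "N"
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comparable <- !(gap[i, ] & gap[j, ]) & !nn[i, ] & !nn[j, ]
      nc <- sum(comparable)
      if (nc == 0L)
        stop_symh2(sprintf("no comparable positions between %s and %s",
                           names(seqs)[i], names(seqs)[j]))
      d[i, j] <- d[j, i] <- sum(mat[i, comparable] != mat[j, comparable]) / nc
    }
  }
  d
}

#' Similarity matrix Z from a distance matrix
#'
#' `Z = 1 - d` elementwise; Z has unit diagonal and entries in `[0, 1]`,
#' encoding the genetic similarity of each pair of OTUs.
#'
#' @param d Symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @return Similarity matrix Z.
#' @export
similarity_from_distances <- function(d) {
  if (!is.matrix(d) || any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop_symh2("distance matrix entries must lie in [0, 1]")
  if (any(abs(d - t(d)) > 1e-12) || any(abs(diag(d)) > 1e-12))
    stop_symh2("distance matrix must be symmetric with zero diagonal")
  1 - d
}

#' Similarity-sensitive diversity of order q (Leinster-Cobbold qD^Z)
#'
#' The effective number of species of a community with relative abundance
#' vector p, accounting for between-species similarity Z:
#' \deqn{^qD^Z(p) = \left(\sum_{i: p_i>0} p_i \, ((Zp)_i)^{q-1}\right)^{1/(1-q)}}
#' with the continuous limits \eqn{D = \exp(-\sum p_i \log (Zp)_i)} at
#' q = 1 and \eqn{D = 1 / \max_i (Zp)_i} at q = Inf, sums restricted to
#' the support of p. With Z the identity this is the classical Hill
#' number of order q; with Z all-ones every community has diversity 1.
#'
#' @param p Non-negative relative abundance vector summing to 1.
#' @param Z Similarity matrix (unit diagonal, entries in `[0, 1]`).
#' @param q Diversity order, `q >= 0` (q = 0 emphasises rare species,
#'   large q the dominant ones); `Inf` allowed.
#' @return Diversity D, a scalar in `[1, length of support]`.
#' @export
leinster_cobbold <- function(p, Z, q = 1) {
  if (any(p < 0)) stop_symh2("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop_symh2("relative abundances must sum to 1")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop_symh2("q must be a single number >= 0")
  if (!is.matrix(Z) || nrow(Z) != length(p) || ncol(Z) != length(p))
    stop_symh2("Z must be a square matrix matching p")
  zp <- as.vector(Z %*% p)
  s <- p > 0
  if (any(zp[s] <= 0))
    stop_symh2("(Zp) must be positive on the support of p")
  ps <- p[s]
  zs <- zp[s]
  if (is.infinite(q)) {
    1 / max(zs)
  } else if (q == 1) {
    exp(-sum(ps * log(zs)))
  } else {
    sum(ps * zs^(q - 1))^(1 / (1 - q))
  }
}

#' Per-sample diversity phenotypes
#'
#' Renormalizes each sample's (variance-normalized) abundance column to
#' sum to 1 and evaluates the similarity-sensitive diversity at order q.
#' The result is the scalar host phenotype used for heritability
#' estimation.
#'
#' @param norm Abundance matrix (OTUs x samples); rows must match Z.
#' @param Z Similarity matrix over the same OTUs.
#' @param q Diversity order (default 1).
#' @return data.frame: sample_id, q, D.
#' @export
diversity_phenotypes <- function(norm, Z, q = 1) {
  if (!is.matrix(norm) || nrow(norm) != nrow(Z))
    stop_symh2("abundance matrix rows must match the similarity matrix")
  if (!is.null(rownames(norm)) && !is.null(rownames(Z)) &&
      !identical(rownames(norm), rownames(Z)))
    stop_symh2("OTU order of abundance matrix and Z disagree")
  tot <- colSums(norm)
  if (any(tot <= 0))
    stop_symh2(sprintf("sample(s) with zero total abundance: %s",
                       paste(colnames(norm)[tot <= 0], collapse = ", ")))
  D <- vapply(seq_len(ncol(norm)), function(j) {
    leinster_cobbold(norm[, j] / tot[j], Z, q)
  }, numeric(1))
  data.frame(sample_id = colnames(norm), q = q, D = D,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Diversity profile over several orders q
#'
#' @param norm Abundance matrix (OTUs x samples).
#' @param Z Similarity matrix.
#' @param q Vector of orders (default `c(0, 0.5, 1, 2, Inf)`).
#' @return data.frame stacking [diversity_phenotypes()] over the orders.
#' @export
diversity_profile <- function(norm, Z, q = c(0, 0.5, 1, 2, Inf)) {
  do.call(rbind, lapply(q, function(qq) diversity_phenotypes(norm, Z, qq)))
}

#' Write per-sample diversity traits to TSV
#' @param traits data.frame from [diversity_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square distance (or similarity) matrix to TSV
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
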