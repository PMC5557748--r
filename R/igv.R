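# Intragenomic-variant (IGV) handling. ITS-2 is a multicopy marker, so
# distinct sequence copies within one genome can masquerade as separate
# OTUs. The three-step procedure: (1) candidate groups from OTUs that
# cluster closely on an average-linkage dendrogram of raw distances;
# (2) keep members whose normalized abundances are strongly correlated
# (|r| in [0.8, 1]) across samples; (3) collapse each group into its
# most abundant member and re-estimate heritability.

#' Candidate IGV groups from a distance dendrogram
#'
#' Average-linkage hierarchical clustering of the raw distance matrix,
#' cut at `cut_height`; clusters of two or more OTUs are candidates.
#' The default cut (0.03) mirrors the 97% OTU-identity convention.
#'
#' @param d Symmetric raw distance matrix.
#' @param cut_height Dendrogram cut height in (0, 1).
#' @return List of character vectors of otu_ids (possibly empty).
#' @export
igv_candidate_groups <- function(d, cut_height = 0.03) {
  if (cut_height <= 0 || cut_height >= 1)
    stop_symh2("cut_height must lie in (0, 1)")
  if (nrow(d) < 2L) return(list())
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # guard against floating-point non-monotonicity in merge heights,
  # which cutree rejects
  hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  groups <- split(names(cl), cl)
  unname(groups[lengths(groups) >= 2L])
}

# largest subset whose members are pairwise flagged in `ok` (exact search;
# groups are small). Ties broken toward the lexicographically first subset.
largest_mutual_subset <- function(ids, ok) {
  n <- length(ids)
  for (size in seq(n, 2L)) {
    combs <- utils::combn(seq_len(n), size, simplify = FALSE)
    for (cc in combs) {
      sub <- ok[cc, cc, drop = FALSE]
      if (all(sub[upper.tri(sub)])) return(ids[cc])
    }
  }
  NULL
}

#' Correlation filter for candidate IGV groups
#'
#' Within each candidate group, the Pearson (or Spearman) correlation of
#' normalized abundances across samples is computed for every pair;
#' members are reduced to the largest subset whose pairwise correlations
#' all satisfy `|r|` within `r_band` (strong negative correlations count:
#' reciprocal amplification of variants). Groups reduced below two
#' members are dropped. Pairs involving a zero-variance OTU have
#' undefined r and are excluded.
#'
#' @param groups List of candidate groups ([igv_candidate_groups()]).
#' @param norm Normalized abundance matrix (OTUs x samples).
#' @param r_band Absolute-correlation band, default `c(0.8, 1)`.
#' @param method Correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return Object of class `"igv_groups"`: list with `groups` (list of
#'   member id vectors), `representative` (per group, the member with the
#'   highest total abundance; ties to the lexicographically smallest id),
#'   and `correlations` (per group matrix).
#' @export
igv_correlation_filter <- function(groups, norm, r_band = c(0.8, 1),
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  kept <- list(); reps <- character(0); cors <- list()
  for (g in groups) {
    miss <- setdiff(g, rownames(norm))
    if (length(miss))
      stop_symh2(sprintf("group member(s) absent from abundance table: %s",
                         paste(miss, collapse = ", ")))
    x <- t(norm[g, , drop = FALSE])
    sds <- apply(x, 2L, stats::sd)
    r <- suppressWarnings(stats::cor(x, method = method))
    ok <- is.finite(r) & abs(r) >= r_band[1L] & abs(r) <= r_band[2L]
    ok[sds == 0, ] <- FALSE; ok[, sds == 0] <- FALSE
    diag(ok) <- TRUE
    sub <- largest_mutual_subset(g, ok)
    if (!is.null(sub)) {
      kept <- c(kept, list(sub))
      tot <- rowSums(norm[sub, , drop = FALSE])
      best <- sub[tot == max(tot)]
      reps <- c(reps, sort(best)[1L])
      cors <- c(cors, list(r[sub, sub, drop = FALSE]))
    }
  }
  structure(list(groups = kept, representative = reps, correlations = cors),
            class = "igv_groups")
}

#' Collapse IGV groups in a count table and sequence set
#'
#' Member counts are summed into the representative's row; the other
#' members' rows and sequences are removed. Per-sample totals are
#' conserved exactly.
#'
#' @param counts Counts matrix (OTUs x samples).
#' @param seqs Named aligned sequences matching the counts rows.
#' @param igv An `"igv_groups"` object (or list of id vectors).
#' @return List with collapsed `counts` and `seqs`.
#' @export
igv_collapse <- function(counts, seqs, igv) {
  groups <- if (inherits(igv, "igv_groups")) igv$groups else igv
  if (length(groups) == 0L) return(list(counts = counts, seqs = seqs))
  members <- unlist(groups)
  if (anyDuplicated(members))
    stop_symh2("IGV groups overlap")
  reps <- if (inherits(igv, "igv_groups")) igv$representative else
    vapply(groups, function(g) {
      tot <- rowSums(counts[g, , drop = FALSE])
      sort(g[tot == max(tot)])[1L]
    }, character(1))
  drop <- character(0)
  for (k in seq_along(groups)) {
    g <- groups[[k]]; rep_id <- reps[k]
    counts[rep_id, ] <- colSums(counts[g, , drop = FALSE])
    drop <- c(drop, setdiff(g, rep_id))
  }
  keep <- setdiff(rownames(counts), drop)
  list(counts = counts[keep, , drop = FALSE], seqs = seqs[keep])
}

#' Heritability with and without IGV collapsing
#'
#' Runs the diversity -> animal model chain twice on the same inputs and
#' seed — once raw and once after collapsing the supplied IGV groups —
#' and reports both posteriors and the difference in the h2 mode.
#' Perfectly co-inherited variants are expected to shift h2 only
#' marginally, since they are shared within genomes and contribute
#' little between-family variance.
#'
#' @param counts Counts matrix.
#' @param seqs Aligned sequences.
#' @param igv An `"igv_groups"` object.
#' @param individual Named character vector mapping sample ids (columns
#'   of `counts`) to the pedigree individuals to model; samples not
#'   listed (e.g. parents) contribute to normalization but not to the
#'   animal model.
#' @param A Additive relationship matrix.
#' @param q Diversity order.
#' @param settings [mcmc_settings()]; use a fixed seed for comparability.
#' @return List of class `"igv_h2_comparison"`: `raw`, `collapsed`
#'   (both `"h2_posterior"`), `h2_shift`, `n_otus_raw`, `n_otus_collapsed`.
#' @export
h2_with_and_without_collapse <- function(counts, seqs, igv, individual, A,
                                         q = 1, settings = mcmc_settings()) {
  miss <- setdiff(names(individual), colnames(counts))
  if (is.null(names(individual)) || length(miss))
    stop_symh2("individual must be named by sample ids present in the count table")
  run <- function(cts, sqs) {
    norm <- normalize_counts(cts)
    Z <- similarity_from_distances(raw_distances(sqs))
    traits <- diversity_phenotypes(norm, Z, q)
    y <- traits$D[match(names(individual), traits$sample_id)]
    gibbs_animal_model(model_spec(y, individual), A, settings)
  }
  fit_raw <- run(counts, seqs)
  col <- igv_collapse(counts, seqs, igv)
  fit_col <- run(col$counts, col$seqs)
  structure(list(raw = fit_raw, collapsed = fit_col,
                 h2_shift = fit_col$h2_mode - fit_raw$h2_mode,
                 n_otus_raw = nrow(counts),
                 n_otus_collapsed = nrow(col$counts)),
            class = "igv_h2_comparison")
}
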