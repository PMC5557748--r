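# Variance normalization of OTU counts via negative-binomial-style
# median-of-ratios size factors, and classification of OTUs by
# normalized abundance (principal/background) and ubiquity
# (core/common/rare).

#' Estimate per-sample size factors (median-of-ratios)
#'
#' The size factor of a sample is the median, over reference OTUs, of the
#' ratio of its count to that OTU's geometric mean across samples; factors
#' are rescaled so their geometric mean is exactly 1. Reference OTUs are
#' those observed in every sample. Sparse amplicon tables may have no such
#' OTU; with `fallback = TRUE` (default) the geometric means are then
#' computed over positive entries only ("positive-counts" fallback) and the
#' median is taken over OTUs with a positive count in the sample.
#'
#' @param counts Counts matrix (OTUs x samples), at least two samples.
#' @param fallback Use the positive-counts fallback when no OTU is observed
#'   in all samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  # accepts already-normalized (non-integer) tables too, so that
  # re-estimation after normalization is well-defined (and returns 1s)
  if (!is.matrix(counts) || !is.numeric(counts) || any(counts < 0) ||
      any(!is.finite(counts)))
    stop_symh2("count table must be a non-negative numeric matrix")
  if (any(colSums(counts) == 0))
    stop_symh2(sprintf("sample(s) with zero total counts: %s",
                       paste(colnames(counts)[colSums(counts) == 0],
                             collapse = ", ")))
  if (ncol(counts) < 2L)
    stop_symh2("size-factor estimation needs at least two samples")
  all_pos <- rowSums(counts == 0) == 0L
  if (any(all_pos)) {
    geo <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    sf <- apply(counts[all_pos, , drop = FALSE], 2L, function(col) {
      stats::median(col / geo)
    })
  } else if (fallback) {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    geo <- exp(rowMeans(lc, na.rm = TRUE))
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      pos <- counts[, j] > 0
      stats::median(counts[pos, j] / geo[pos])
    }, numeric(1))
    names(sf) <- colnames(counts)
  } else {
    stop_symh2(paste("no OTU observed in all samples; enable the",
                     "positive-counts fallback (fallback = TRUE)"))
  }
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Variance-normalize counts by size factors
#'
#' @param counts Counts matrix (OTUs x samples).
#' @param sf Positive size factors, one per sample (in column order).
#' @return Matrix of normalized abundances, `counts[, j] / sf[j]`, with a
#'   `"size_factors"` attribute.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  counts <- validate_count_table(counts)
  if (length(sf) != ncol(counts))
    stop_symh2("need one size factor per sample")
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_symh2("size factors must be positive and finite")
  norm <- sweep(counts, 2L, sf, "/")
  attr(norm, "size_factors") <- stats::setNames(sf, colnames(counts))
  norm
}

#' Classify OTUs as principal or background by normalized abundance
#'
#' An OTU is background when its share of the dataset-wide total
#' normalized abundance is strictly below `threshold` (default 0.01%);
#' otherwise principal. With `per_sample = TRUE` the share is computed
#' within each sample and an OTU is principal if it reaches the threshold
#' in at least one sample.
#'
#' @param norm Normalized abundance matrix (OTUs x samples).
#' @param threshold Fraction in (0, 1); default `1e-4` (0.01%).
#' @param per_sample Classify on per-sample rather than dataset-wide shares.
#' @return Named factor with levels `principal`, `background`.
#' @export
classify_abundance <- function(norm, threshold = 1e-4, per_sample = FALSE) {
  if (!is.matrix(norm) || !is.numeric(norm) || length(norm) == 0L)
    stop_symh2("normalized table must be a non-empty numeric matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop_symh2("threshold must lie strictly inside (0, 1)")
  if (per_sample) {
    rel <- sweep(norm, 2L, colSums(norm), "/")
    background <- apply(rel, 1L, max) < threshold
  } else {
    rel <- rowSums(norm) / sum(norm)
    background <- rel < threshold
  }
  out <- factor(ifelse(background, "background", "principal"),
                levels = c("principal", "background"))
  names(out) <- rownames(norm)
  out
}

#' Classify OTUs by ubiquity (core/common/rare)
#'
#' Presence fraction f = share of samples with a nonzero count: core when
#' f > 0.75, rare when f < 0.25, common otherwise (boundaries fall to
#' common).
#'
#' @param counts Counts matrix (OTUs x samples).
#' @return Named factor with levels `core`, `common`, `rare`.
#' @export
classify_ubiquity <- function(counts) {
  if (!is.matrix(counts) || length(counts) == 0L)
    stop_symh2("count table must be a non-empty matrix")
  f <- rowMeans(counts > 0)
  cls <- ifelse(f > 0.75, "core", ifelse(f < 0.25, "rare", "common"))
  out <- factor(cls, levels = c("core", "common", "rare"))
  names(out) <- rownames(counts)
  out
}

#' Full OTU classification report
#'
#' @param counts Counts matrix.
#' @param norm Normalized matrix (defaults to size-factor normalization).
#' @param threshold Abundance threshold passed to [classify_abundance()].
#' @return data.frame: otu_id, abundance_class, ubiquity_class,
#'   total_relative_abundance, presence_fraction.
#' @export
classify_otus <- function(counts, norm = normalize_counts(counts),
                          threshold = 1e-4) {
  data.frame(
    otu_id = rownames(counts),
    abundance_class = as.character(classify_abundance(norm, threshold)),
    ubiquity_class = as.character(classify_ubiquity(counts)),
    total_relative_abundance = rowSums(norm) / sum(norm),
    presence_fraction = rowMeans(counts > 0),
    stringsAsFactors = FALSE
  )
}

#' Write a classification report as TSV
#' @param cls data.frame from [classify_otus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  utils::write.table(cls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
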