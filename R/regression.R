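# Trait-based heritability by parent-offspring regression: offspring
# trait on family midparent value (h2 = slope) or on the dam's value
# (h2 = 2 * slope, single shared parent).

h2_regression_result <- function(mode, fit, n, factor) {
  co <- summary(fit)$coefficients
  slope <- unname(co[2L, 1L]); se <- unname(co[2L, 2L])
  h2 <- factor * slope
  warnings <- character(0)
  if (h2 < 0 || h2 > 1)
    warnings <- sprintf("h2 estimate %.4f outside [0, 1]; reported raw", h2)
  structure(list(mode = mode, slope = slope, se_slope = se,
                 intercept = unname(co[1L, 1L]), n = n, h2 = h2,
                 warnings = warnings),
            class = "h2_regression")
}

#' Midparent-offspring regression heritability
#'
#' Ordinary least squares of individual offspring trait values on their
#' family's midparent value (the mean of the dam's and sire's traits);
#' the slope is the narrow-sense heritability. With
#' `family_means = TRUE`, family-mean offspring values are regressed
#' instead.
#'
#' @param offspring data.frame with columns `family` and `trait`.
#' @param parent_traits data.frame with columns `family`, `dam_trait`,
#'   `sire_trait` (one row per family).
#' @param family_means Regress family means rather than individuals.
#' @return Object of class `"h2_regression"` with slope, SE, and
#'   `h2 = slope`.
#' @export
midparent_regression <- function(offspring, parent_traits,
                                 family_means = FALSE) {
  need <- c("family", "dam_trait", "sire_trait")
  if (!all(need %in% names(parent_traits)))
    stop_symh2("parent_traits needs columns family, dam_trait, sire_trait")
  if (!all(c("family", "trait") %in% names(offspring)))
    stop_symh2("offspring needs columns family, trait")
  if (nrow(parent_traits) < 3L)
    stop_symh2("need at least 3 families for midparent regression")
  miss <- setdiff(offspring$family, parent_traits$family)
  if (length(miss))
    stop_symh2(sprintf("no parental traits for family(s): %s",
                       paste(unique(miss), collapse = ", ")))
  mid <- (parent_traits$dam_trait + parent_traits$sire_trait) / 2
  names(mid) <- parent_traits$family
  if (stats::var(mid) == 0)
    stop_symh2("midparent values have zero variance")
  if (family_means) {
    yv <- tapply(offspring$trait, offspring$family, mean)
    xv <- mid[names(yv)]
  } else {
    yv <- offspring$trait
    xv <- mid[as.character(offspring$family)]
  }
  fit <- stats::lm(yv ~ xv)
  h2_regression_result("midparent", fit, length(yv), 1)
}

#' Single-parent (dam) regression heritability
#'
#' OLS of offspring trait on the dam's trait; because only one parent is
#' observed the heritability is twice the slope.
#'
#' @param offspring data.frame with columns `dam` and `trait`.
#' @param dam_traits Named numeric vector of dam trait values.
#' @return Object of class `"h2_regression"` with `h2 = 2 * slope`.
#' @export
single_parent_regression <- function(offspring, dam_traits) {
  if (!all(c("dam", "trait") %in% names(offspring)))
    stop_symh2("offspring needs columns dam, trait")
  miss <- setdiff(offspring$dam, names(dam_traits))
  if (length(miss))
    stop_symh2(sprintf("no trait value for dam(s): %s",
                       paste(unique(miss), collapse = ", ")))
  if (length(unique(offspring$dam)) < 3L)
    stop_symh2("need at least 3 dams for single-parent regression")
  xv <- dam_traits[as.character(offspring$dam)]
  if (stats::var(xv) == 0)
    stop_symh2("dam trait values have zero variance")
  fit <- stats::lm(offspring$trait ~ xv)
  h2_regression_result("single_parent", fit, nrow(offspring), 2)
}

#' @export
print.h2_regression <- function(x, ...) {
  cat(sprintf("%s regression: slope %.4f (SE %.4f), n = %d, h2 = %.4f\n",
              x$mode, x$slope, x$se_slope, x$n, x$h2))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}
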