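# End-to-end orchestration: normalize -> classify -> distances ->
# diversity -> pedigree -> animal model + regression -> optional IGV
# re-run, with a machine-readable JSON report.

#' Default pipeline configuration
#'
#' @return Named list of defaults; input paths are `NULL` and must be
#'   supplied.
#' @export
default_pipeline_config <- function() {
  list(counts = NULL, fasta = NULL, pedigree = NULL, metadata = NULL,
       q = 1, abundance_threshold = 1e-4,
       n_iter = 60000L, burn_in = 0.1, thin = 25L, seed = 1L,
       prior_shape = 0.001, prior_rate = 0.001,
       regression = "auto", family_means = FALSE,
       igv_enabled = FALSE, igv_cut_height = 0.03, igv_r_lo = 0.8,
       igv_r_hi = 1.0, out_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks every threshold;
#' violations are reported all at once. Accepts a YAML/JSON file path or
#' a list.
#'
#' @param config Path to a YAML (or JSON) config file, or a named list.
#' @return Validated config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_symh2(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$q) && cfg$q >= 0, "q must be >= 0")
  chk(cfg$abundance_threshold > 0 && cfg$abundance_threshold < 1,
      "abundance_threshold must lie in (0, 1)")
  chk(cfg$burn_in >= 0 && cfg$burn_in < 1, "burn_in must lie in [0, 1)")
  chk(cfg$thin >= 1, "thin must be >= 1")
  chk(cfg$n_iter >= 10, "n_iter too small")
  chk(cfg$prior_shape > 0 && cfg$prior_rate > 0, "prior parameters must be positive")
  chk(cfg$igv_cut_height > 0 && cfg$igv_cut_height < 1,
      "igv_cut_height must lie in (0, 1)")
  chk(cfg$igv_r_lo >= 0 && cfg$igv_r_hi <= 1 && cfg$igv_r_lo < cfg$igv_r_hi,
      "igv correlation band must satisfy 0 <= lo < hi <= 1")
  chk(cfg$regression %in% c("auto", "midparent", "single_parent", "none"),
      "regression must be auto, midparent, single_parent or none")
  if (length(problems))
    stop_symh2(paste0("invalid configuration:\n  - ",
                      paste(problems, collapse = "\n  - ")))
  cfg
}

#' Run the full heritability pipeline
#'
#' Reads the four standard inputs, variance-normalizes and classifies the
#' OTU table, computes the similarity-sensitive diversity phenotype,
#' builds the relationship matrix, estimates h2 by the Bayesian animal
#' model (offspring records; maternal-environment model compared by DIC
#' when more than one dam is present) and by parent-offspring regression,
#' optionally repeats the analysis with intragenomic variants collapsed,
#' and returns (and optionally writes) a structured report. The JSON
#' report layout is described by the schema shipped at
#' `system.file("schema", "report-schema.json", package = "symh2")`.
#'
#' @param config See [validate_config()]; `counts`, `fasta`, `pedigree`
#'   and `metadata` paths are required.
#' @return List of class `"study_report"`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  for (f in c("counts", "fasta", "pedigree", "metadata"))
    if (is.null(cfg[[f]])) stop_symh2(sprintf("config is missing input path '%s'", f))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_symh2(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  counts <- stage("read_counts", read_count_table(cfg$counts))
  seqs <- stage("read_fasta", read_aligned_fasta(cfg$fasta))
  if (!identical(sort(names(seqs)), sort(rownames(counts))))
    stop_symh2("[stage read_fasta] FASTA ids do not match count table otu_ids")
  seqs <- seqs[rownames(counts)]
  ped <- stage("read_pedigree", read_pedigree(cfg$pedigree))
  meta <- stage("read_metadata", read_sample_metadata(cfg$metadata, counts, ped))

  norm <- stage("normalize", normalize_counts(counts))
  cls <- stage("classify", classify_otus(counts, norm, cfg$abundance_threshold))
  d <- stage("distances", raw_distances(seqs))
  Z <- similarity_from_distances(d)
  traits <- stage("diversity", diversity_phenotypes(norm, Z, cfg$q))
  traits$individual_id <- meta$individual_id[match(traits$sample_id, meta$sample_id)]

  A <- stage("pedigree", additive_relationship_matrix(ped))
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  is_offspring <- !(is.na(ped$sire) & is.na(ped$dam))
  off <- traits[traits$individual_id %in% ped$id[is_offspring], , drop = FALSE]
  if (nrow(off) < 3L) stop_symh2("[stage animal_model] fewer than 3 phenotyped offspring")

  prior <- ig_prior(cfg$prior_shape, cfg$prior_rate)
  settings <- mcmc_settings(cfg$n_iter, cfg$burn_in, cfg$thin,
                            seed = derive_seed(cfg$seed, "gibbs"))
  dams_of <- ped$dam[match(off$individual_id, ped$id)]
  spec <- model_spec(off$D, off$individual_id, fixed = NULL, prior = prior)
  fit <- stage("animal_model", gibbs_animal_model(spec, A, settings))
  maternal_cmp <- NULL
  if (length(unique(dams_of[!is.na(dams_of)])) >= 2L && !anyNA(dams_of)) {
    specm <- model_spec(off$D, off$individual_id, maternal_group = dams_of,
                        prior = prior)
    maternal_cmp <- stage("maternal_comparison",
                          compare_maternal_models(specm, A, settings))
  }

  # regression: midparent when both parents are phenotyped, else dam-only
  trait_of <- stats::setNames(traits$D, traits$individual_id)
  regression <- NULL
  mode <- cfg$regression
  off_ped <- ped[match(off$individual_id, ped$id), ]
  both_known <- all(!is.na(off_ped$sire) & !is.na(off_ped$dam)) &&
    all(c(off_ped$sire, off_ped$dam) %in% names(trait_of))
  dam_known <- all(!is.na(off_ped$dam)) && all(off_ped$dam %in% names(trait_of))
  if (mode == "auto") mode <- if (both_known) "midparent" else
    if (dam_known) "single_parent" else "none"
  if (mode == "midparent") {
    fam <- paste0(off_ped$sire, "x", off_ped$dam)
    pt <- unique(data.frame(family = fam, dam_trait = trait_of[off_ped$dam],
                            sire_trait = trait_of[off_ped$sire],
                            stringsAsFactors = FALSE))
    regression <- stage("regression",
                        midparent_regression(
                          data.frame(family = fam, trait = off$D),
                          pt, family_means = cfg$family_means))
  } else if (mode == "single_parent") {
    regression <- stage("regression",
                        single_parent_regression(
                          data.frame(dam = off_ped$dam, trait = off$D),
                          trait_of[unique(off_ped$dam)]))
  }

  igv_block <- NULL
  if (isTRUE(cfg$igv_enabled)) {
    cand <- stage("igv", igv_candidate_groups(d, cfg$igv_cut_height))
    igv <- stage("igv", igv_correlation_filter(cand, norm,
                                               c(cfg$igv_r_lo, cfg$igv_r_hi)))
    igv_block <- stage("igv", h2_with_and_without_collapse(
      counts, seqs, igv, stats::setNames(off$individual_id, off$sample_id),
      A, q = cfg$q, settings = settings))
  }

  report <- structure(list(
    traits = traits, classification = cls,
    h2_bayes = list(mode = fit$h2_mode, mean = fit$h2_mean, sd = fit$h2_sd,
                    ci95 = unname(fit$ci95), dic = fit$dic,
                    n_retained = fit$n_retained,
                    dic_maternal = if (!is.null(maternal_cmp))
                      maternal_cmp$maternal$dic,
                    delta_dic = if (!is.null(maternal_cmp))
                      maternal_cmp$delta_dic,
                    maternal_selected = if (!is.null(maternal_cmp))
                      maternal_cmp$selected),
    h2_regression = if (!is.null(regression))
      regression[c("mode", "slope", "se_slope", "intercept", "n", "h2",
                   "warnings")],
    igv = if (!is.null(igv_block))
      list(n_otus_raw = igv_block$n_otus_raw,
           n_otus_collapsed = igv_block$n_otus_collapsed,
           h2_raw = igv_block$raw$h2_mode,
           h2_collapsed = igv_block$collapsed$h2_mode,
           h2_shift = igv_block$h2_shift),
    provenance = list(q = cfg$q, seed = cfg$seed,
                      abundance_threshold = cfg$abundance_threshold,
                      prior = c(shape = cfg$prior_shape, rate = cfg$prior_rate),
                      mcmc = list(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                                  thin = cfg$thin))),
    class = "study_report")
  attr(report, "fit") <- fit
  attr(report, "maternal_comparison") <- maternal_cmp

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(norm, file.path(cfg$out_dir, "normalized.tsv"),
                       sep = "\t", quote = FALSE)
    write_classification(cls, file.path(cfg$out_dir, "classification.tsv"))
    write_traits(traits, file.path(cfg$out_dir, "traits.tsv"))
    write_square_matrix(A, file.path(cfg$out_dir, "amatrix.tsv"))
    write_chains(fit, file.path(cfg$out_dir, "chains.tsv"))
    rep2 <- report
    rep2$traits <- NULL; rep2$classification <- NULL
    jsonlite::write_json(unclass(rep2),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 6, null = "null")
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Symbiont community heritability report\n")
  cat(sprintf("  samples: %d, OTUs: %d (q = %g)\n", nrow(x$traits),
              nrow(x$classification), x$provenance$q))
  cat(sprintf("  Bayesian h2: mode %.3f, mean %.3f, 95%% CI [%.3f, %.3f]\n",
              x$h2_bayes$mode, x$h2_bayes$mean, x$h2_bayes$ci95[1L],
              x$h2_bayes$ci95[2L]))
  if (!is.null(x$h2_regression))
    cat(sprintf("  %s regression h2: %.3f (slope %.3f)\n",
                x$h2_regression$mode, x$h2_regression$h2, x$h2_regression$slope))
  if (!is.null(x$h2_bayes$delta_dic))
    cat(sprintf("  maternal model DIC delta: %.2f (selected: %s)\n",
                x$h2_bayes$delta_dic, x$h2_bayes$maternal_selected))
  if (!is.null(x$igv))
    cat(sprintf("  IGV: %d -> %d OTUs, h2 shift %.4f\n", x$igv$n_otus_raw,
                x$igv$n_otus_collapsed, x$igv$h2_shift))
  invisible(x)
}
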