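# Synthetic study generator: pedigree designs, an infinitesimal-model
# heritable latent trait, clade-structured aligned sequences, and sparse
# OTU count tables whose community evenness — and hence the diversity
# phenotype — is driven by the latent trait. All ground truth is
# recorded so recovery can be tested end-to-end.

#' Simulate a pedigree design
#'
#' `"half_diallel"`: crosses among `n_parents` excluding self-crosses
#' (undirected pairs), `n_families` of them with `offspring_per_family`
#' offspring each. `"maternal_only"`: `n_parents` dams with
#' `offspring_per_family` eggs each (sire unknown).
#'
#' @param design `"half_diallel"` or `"maternal_only"`.
#' @param n_parents Number of parents (half-diallel) or dams.
#' @param n_families Number of crosses (half-diallel only; defaults to all
#'   possible pairs).
#' @param offspring_per_family Offspring (or eggs) per family; scalar or
#'   vector.
#' @param seed Integer seed; identical seeds give identical pedigrees.
#' @return A [pedigree()].
#' @export
simulate_pedigree_design <- function(design = c("half_diallel", "maternal_only"),
                                     n_parents = 4L, n_families = NULL,
                                     offspring_per_family = 10L, seed = 1L) {
  design <- match.arg(design)
  set.seed(seed)
  parents <- sprintf("P%02d", seq_len(n_parents))
  if (design == "maternal_only") {
    return(build_maternal_pedigree(parents,
                                   rep_len(offspring_per_family, n_parents)))
  }
  pairs <- t(utils::combn(parents, 2L))
  max_fam <- nrow(pairs)
  n_families <- n_families %||% max_fam
  if (n_families > max_fam)
    stop_symh2(sprintf(
      "infeasible design: %d families requested but only %d non-self pairs of %d parents",
      n_families, max_fam, n_parents))
  use <- pairs[sample.int(max_fam, n_families), , drop = FALSE]
  use <- use[order(use[, 1L], use[, 2L]), , drop = FALSE]
  build_diallel_pedigree(parents, use,
                         rep_len(offspring_per_family, n_families))
}

#' Simulate a heritable latent trait over a pedigree
#'
#' Infinitesimal model: founder breeding values ~ N(0, sigma2_A);
#' offspring with both parents known get the parental mean plus a
#' Mendelian deviation ~ N(0, 0.5 sigma2_A); a single known parent
#' contributes half its value with deviation variance 0.75 sigma2_A.
#' Each dam with offspring contributes a shared maternal-environment
#' effect ~ N(0, m2 * (sigma2_A + sigma2_e)) to her offspring. The trait
#' is `mu + a + m + N(0, sigma2_e)`.
#'
#' @param ped A [pedigree()].
#' @param sigma2_A Additive genetic variance.
#' @param sigma2_e Residual variance.
#' @param m2 Maternal-environment variance as a fraction of the
#'   phenotypic variance (default 0).
#' @param mu Trait mean.
#' @param seed Integer seed.
#' @return List of class `"sim_trait"`: `trait` and `breeding_value`
#'   (named vectors over the pedigree), and `truth` (list with
#'   `h2 = sigma2_A / (sigma2_A + sigma2_e)` and all inputs).
#' @export
simulate_trait <- function(ped, sigma2_A = 0.3, sigma2_e = 0.7, m2 = 0,
                           mu = 0, seed = 1L) {
  if (sigma2_A < 0 || sigma2_e < 0 || m2 < 0)
    stop_symh2("variances must be non-negative")
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  a <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      a[i] <- stats::rnorm(1L, 0, sqrt(sigma2_A))
    } else if (!is.na(s) && !is.na(d)) {
      a[i] <- 0.5 * (a[s] + a[d]) + stats::rnorm(1L, 0, sqrt(0.5 * sigma2_A))
    } else {
      p <- if (is.na(s)) d else s
      a[i] <- 0.5 * a[p] + stats::rnorm(1L, 0, sqrt(0.75 * sigma2_A))
    }
  }
  sigma2_P <- sigma2_A + sigma2_e
  m <- numeric(n)
  if (m2 > 0) {
    dams <- unique(ped$dam[!is.na(ped$dam)])
    me <- stats::rnorm(length(dams), 0, sqrt(m2 * sigma2_P))
    names(me) <- dams
    has_dam <- !is.na(ped$dam)
    m[has_dam] <- me[ped$dam[has_dam]]
  }
  trait <- mu + a + m + stats::rnorm(n, 0, sqrt(sigma2_e))
  names(trait) <- names(a) <- ped$id
  structure(list(
    trait = trait, breeding_value = a,
    truth = list(h2 = sigma2_A / (sigma2_A + sigma2_e),
                 sigma2_A = sigma2_A, sigma2_e = sigma2_e, m2 = m2,
                 mu = mu, seed = seed)), class = "sim_trait")
}

mutate_positions <- function(seq_chars, k) {
  L <- length(seq_chars)
  pos <- sample.int(L, k)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(bases, seq_chars[p]), 1L)
  }
  seq_chars
}

#' Simulate clade-structured aligned sequences
#'
#' A random root sequence spawns `n_clades` ancestors, each mutated at
#' `between_clade_divergence / 2` of the positions (so ancestor pairs
#' differ at roughly the between-clade level); each OTU is its clade
#' ancestor mutated at `within_clade_divergence` of positions (pairs
#' within a clade then differ at roughly twice that). OTUs are assigned
#' to clades round-robin.
#'
#' @param n_otus Number of OTUs.
#' @param length Alignment length (default 300).
#' @param n_clades Number of clades (default 3, echoing clades A/C/D).
#' @param within_clade_divergence Expected OTU-to-ancestor distance.
#' @param between_clade_divergence Expected ancestor-to-ancestor distance.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences; names carry the
#'   clade as `OTU<i>_c<clade>`.
#' @export
simulate_sequences <- function(n_otus, length = 300L, n_clades = 3L,
                               within_clade_divergence = 0.01,
                               between_clade_divergence = 0.2, seed = 1L) {
  if (within_clade_divergence <= 0 && between_clade_divergence <= 0)
    stop_symh2("divergences must be positive")
  if (within_clade_divergence >= between_clade_divergence)
    stop_symh2("within-clade divergence must be below between-clade divergence")
  if (between_clade_divergence >= 1)
    stop_symh2("divergence must lie in (0, 1)")
  k_b <- round(between_clade_divergence / 2 * length)
  k_w <- round(within_clade_divergence * length)
  if (k_b < 1L)
    stop_symh2("alignment too short to realize the requested divergence")
  set.seed(seed)
  root <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  ancestors <- lapply(seq_len(n_clades), function(cl) mutate_positions(root, k_b))
  clade <- rep_len(seq_len(n_clades), n_otus)
  seqs <- vapply(seq_len(n_otus), function(i) {
    paste(mutate_positions(ancestors[[clade[i]]], k_w), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("OTU%03d_c%d", seq_len(n_otus), clade)
  seqs
}

#' Community evenness implied by a latent trait value
#'
#' Logistic map from the latent trait to the common ratio of the
#' geometric abundance series of the principal OTUs: higher trait gives a
#' ratio closer to 1, a more even community, and a higher diversity
#' phenotype. Strictly increasing in the trait.
#'
#' @param latent Latent trait value(s), on a roughly unit-variance scale.
#' @param lo,hi Range of the geometric ratio (defaults 0.35-0.95).
#' @param scale Logistic steepness (default 1).
#' @return Evenness ratio(s) in `(lo, hi)`.
#' @export
evenness_from_latent <- function(latent, lo = 0.35, hi = 0.95, scale = 1) {
  lo + (hi - lo) * stats::plogis(scale * latent)
}

#' Simulate sparse OTU counts driven by a latent trait
#'
#' Each sample's expected community is a geometric series over the
#' principal OTUs with ratio [evenness_from_latent()] of its latent
#' value, plus a long tail of background OTUs each holding an expected
#' share below 0.01% and present only in a random minority of samples
#' (per-OTU inclusion rates drawn from 0.05-0.25). Counts are negative
#' binomial (variance `mu + dispersion * mu^2`) around library-size-
#' scaled expectations; library sizes are lognormal around
#' `library_size_mean`.
#'
#' @param latent Named vector of latent trait values (names = sample ids).
#' @param seqs Aligned sequences; the first `n_principal` OTUs are the
#'   principal pool, the next `n_background` the background pool.
#' @param n_principal,n_background Pool sizes (must sum to
#'   `length(seqs)`).
#' @param library_size_mean Mean sequencing depth per sample.
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param background_share Expected per-OTU background share (default
#'   5e-5, below the 0.01% principal threshold).
#' @param seed Integer seed.
#' @return Counts matrix (OTUs x samples).
#' @export
simulate_community_counts <- function(latent, seqs, n_principal = 8L,
                                      n_background = 60L,
                                      library_size_mean = 20000,
                                      nb_dispersion = 0.02,
                                      background_share = 5e-5, seed = 1L) {
  if (any(!is.finite(latent))) stop_symh2("latent values must be finite")
  if (n_principal + n_background != length(seqs))
    stop_symh2("n_principal + n_background must equal the number of sequences")
  set.seed(seed)
  n_s <- length(latent)
  otus <- names(seqs)
  bg_mass <- n_background * background_share
  if (library_size_mean * background_share < 0.2)
    warning("library size too small to resolve background OTUs reliably")
  inclusion <- stats::runif(n_background, 0.05, 0.25)
  libs <- stats::rlnorm(n_s, log(library_size_mean) - 0.045, 0.3)
  counts <- matrix(0, length(seqs), n_s, dimnames = list(otus, names(latent)))
  ranks <- seq_len(n_principal) - 1L
  for (j in seq_len(n_s)) {
    ev <- evenness_from_latent(latent[j])
    shares <- ev^ranks
    shares <- shares / sum(shares) * (1 - bg_mass)
    present <- stats::runif(n_background) < inclusion
    bg <- ifelse(present, background_share, 0)
    mu <- c(shares, bg) * libs[j]
    counts[, j] <- if (nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    else stats::rpois(length(mu), mu)
    if (sum(counts[, j]) == 0) counts[1L, j] <- 1
  }
  counts
}

#' Simulate a complete synthetic heritability study
#'
#' Chains the generators: pedigree design, heritable latent trait over
#' every individual, clade-structured sequences, and per-individual OTU
#' count samples (one sample per individual, parents included so
#' regression estimators have parental phenotypes). Per-stage seeds are
#' derived from the master seed via [derive_seed()].
#'
#' @param config List overriding any of the documented defaults (see
#'   [default_study_config()]).
#' @param dir Optional directory; when given, counts TSV, aligned FASTA,
#'   pedigree CSV, metadata CSV and a truth JSON are written there.
#' @return List of class `"sim_study"`: `counts`, `seqs`, `ped`,
#'   `metadata`, `latent` (the per-individual latent trait),
#'   `truth`, `config`, and `files` when written.
#' @export
simulate_study <- function(config = list(), dir = NULL) {
  cfg <- utils::modifyList(default_study_config(), config)
  unknown <- setdiff(names(config), names(default_study_config()))
  if (length(unknown))
    stop_symh2(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  ped <- simulate_pedigree_design(cfg$design, cfg$n_parents, cfg$n_families,
                                  cfg$offspring_per_family,
                                  seed = derive_seed(cfg$seed, "pedigree"))
  sim <- simulate_trait(ped, cfg$sigma2_A, cfg$sigma2_e, cfg$m2,
                        seed = derive_seed(cfg$seed, "trait"))
  seqs <- simulate_sequences(cfg$n_principal + cfg$n_background,
                             length = cfg$seq_length, n_clades = cfg$n_clades,
                             within_clade_divergence = cfg$within_clade_divergence,
                             between_clade_divergence = cfg$between_clade_divergence,
                             seed = derive_seed(cfg$seed, "sequences"))
  latent <- sim$trait
  names(latent) <- paste0("S_", ped$id)
  counts <- simulate_community_counts(latent, seqs, cfg$n_principal,
                                      cfg$n_background, cfg$library_size_mean,
                                      cfg$nb_dispersion,
                                      seed = derive_seed(cfg$seed, "counts"))
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  metadata <- data.frame(
    sample_id = paste0("S_", ped$id),
    individual_id = ped$id,
    life_stage = ifelse(is_founder, "adult",
                        if (cfg$design == "maternal_only") "egg" else "juvenile"),
    group_id = ifelse(is_founder, ped$id,
                      ifelse(is.na(ped$sire), ped$dam,
                             paste0(ped$sire, "x", ped$dam))),
    cohort = cfg$cohort,
    stringsAsFactors = FALSE)
  truth <- c(sim$truth[setdiff(names(sim$truth), "seed")],
             list(design = cfg$design, seed = cfg$seed,
                  n_principal = cfg$n_principal,
                  n_background = cfg$n_background,
                  n_clades = cfg$n_clades,
                  library_size_mean = cfg$library_size_mean,
                  nb_dispersion = cfg$nb_dispersion))
  out <- structure(list(counts = counts, seqs = seqs, ped = ped,
                        metadata = metadata, latent = sim$trait,
                        breeding_value = sim$breeding_value,
                        truth = truth, config = cfg), class = "sim_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      counts = write_count_table(counts, file.path(dir, "counts.tsv")),
      fasta = write_aligned_fasta(seqs, file.path(dir, "otus.fasta")),
      pedigree = write_pedigree(ped, file.path(dir, "pedigree.csv")),
      metadata = write_sample_metadata(metadata, file.path(dir, "metadata.csv")),
      truth = {
        p <- file.path(dir, "truth.json")
        jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
        p
      })
    out$files <- files
  }
  out
}

#' Default synthetic-study configuration
#'
#' The defaults emulate the half-diallel study template: 8 parents, 20
#' crosses of 10 offspring, true h2 = 0.3 on a unit phenotypic-variance
#' scale, 8 principal plus 60 background OTUs over 3 clades, lognormal
#' library sizes around 20,000 reads and NB dispersion 0.02.
#'
#' @return Named list of defaults.
#' @export
default_study_config <- function() {
  list(design = "half_diallel", n_parents = 8L, n_families = 20L,
       offspring_per_family = 10L, sigma2_A = 0.3, sigma2_e = 0.7, m2 = 0,
       n_principal = 8L, n_background = 60L, seq_length = 300L,
       n_clades = 3L, within_clade_divergence = 0.01,
       between_clade_divergence = 0.2, library_size_mean = 20000,
       nb_dispersion = 0.02, cohort = "2013", seed = 1L)
}
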