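test_that("pedigree designs are reproducible and feasibility-checked", {
  expect_error(simulate_pedigree_design("half_diallel", 4, 7, 1, seed = 1),
               "infeasible")
  p1 <- simulate_pedigree_design("half_diallel", 4, 6, 2, seed = 3)
  p2 <- simulate_pedigree_design("half_diallel", 4, 6, 2, seed = 3)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4L + 6L * 2L)

  pm <- simulate_pedigree_design("maternal_only", 9,
                                 offspring_per_family = 11, seed = 1)
  expect_equal(sum(!is.na(pm$dam)), 99L)  # 9 dams x 11 phenotyped eggs
})

test_that("trait generator has the infinitesimal-model moments", {
  # sigma2_A = 0: offspring variance is sigma2_e
  ped <- build_maternal_pedigree(sprintf("D%d", 1:10), 100L)
  sim0 <- simulate_trait(ped, 0, 1, seed = 4)
  off <- ped$id[!is.na(ped$dam)]
  v <- var(sim0$trait[off])
  expect_gt(v, 0.9); expect_lt(v, 1.1)

  # founder breeding values have variance sigma2_A
  ped_f <- pedigree(sprintf("F%03d", 1:800))
  simf <- simulate_trait(ped_f, 0.5, 0.5, seed = 5)
  expect_lt(abs(var(simf$breeding_value) - 0.5), 0.08)

  # full-sib trait covariance ~ 0.5 sigma2_A
  parents <- c("S", "D")
  ped_fs <- pedigree(c(parents, sprintf("O%04d", 1:4000)),
                     c(NA, NA, rep("S", 4000)), c(NA, NA, rep("D", 4000)))
  sim <- simulate_trait(ped_fs, 0.6, 0.4, seed = 6)
  off_tr <- sim$trait[-(1:2)]
  # conditional on parents, sib covariance comes through the shared
  # parental mean: estimate around the family mean structure instead
  a_mid <- 0.5 * (sim$breeding_value["S"] + sim$breeding_value["D"])
  resid <- off_tr - a_mid
  expect_lt(abs(var(resid) - (0.5 * 0.6 + 0.4)), 0.05)
  expect_equal(sim$truth$h2, 0.6, tolerance = 1e-12)
})

test_that("simulated sequences realize the requested divergences", {
  seqs <- simulate_sequences(30, length = 300, n_clades = 3,
                             within_clade_divergence = 0.01,
                             between_clade_divergence = 0.2, seed = 7)
  expect_identical(simulate_sequences(30, length = 300, n_clades = 3,
                                      within_clade_divergence = 0.01,
                                      between_clade_divergence = 0.2, seed = 7),
                   seqs)
  d <- raw_distances(seqs)
  clade <- sub(".*_c", "", names(seqs))
  same <- outer(clade, clade, "==") & upper.tri(d)
  diff <- !outer(clade, clade, "==") & upper.tri(d)
  expect_lt(abs(mean(d[diff]) - 0.2), 0.05)
  expect_lt(mean(d[same]), 0.05)
  expect_error(simulate_sequences(10, 300, 3, 0.3, 0.2), "below")

  # within = 0: identical sequences within each clade
  seqs0 <- simulate_sequences(6, length = 300, n_clades = 2,
                              within_clade_divergence = 0,
                              between_clade_divergence = 0.2, seed = 1)
  d0 <- raw_distances(seqs0)
  cl <- sub(".*_c", "", names(seqs0))
  expect_equal(max(d0[outer(cl, cl, "==")]), 0)
})

test_that("community counts are sparse, trait-driven, and reproducible", {
  set.seed(1)
  lat <- setNames(rnorm(200), sprintf("s%03d", 1:200))
  seqs <- simulate_sequences(68, length = 300, seed = 2)
  cts <- simulate_community_counts(lat, seqs, 8, 60, seed = 3)
  expect_identical(simulate_community_counts(lat, seqs, 8, 60, seed = 3), cts)
  expect_true(all(colSums(cts) > 0))

  # background OTUs hold < 0.01% expected share and are present in a
  # minority of samples
  bg <- cts[9:68, ]
  expect_lt(sum(bg) / sum(cts), 0.005)
  expect_lt(max(rowMeans(bg > 0)), 0.5)

  # generator fidelity: diversity phenotype tracks the latent trait
  norm <- normalize_counts(cts)
  Z <- similarity_from_distances(raw_distances(seqs))
  D <- diversity_phenotypes(norm, Z, 1)$D
  expect_gte(cor(lat, D, method = "spearman"), 0.8)

  # dispersion -> 0 with a large library converges to expected shares
  lat1 <- c(s1 = 0.3)
  cts_big <- simulate_community_counts(lat1, seqs, 8, 60,
                                       library_size_mean = 2e6,
                                       nb_dispersion = 0, seed = 4)
  ev <- evenness_from_latent(0.3)
  shares <- ev^(0:7); shares <- shares / sum(shares) * (1 - 60 * 5e-5)
  obs <- cts_big[1:8, 1] / sum(cts_big[, 1])
  expect_lt(sum(abs(obs - shares)), 0.01)
})

test_that("evenness map is strictly increasing in the latent trait", {
  x <- seq(-4, 4, length.out = 200)
  expect_true(all(diff(evenness_from_latent(x)) > 0))
})

test_that("full studies write consistent bundles with recorded truth", {
  dir <- tempfile("study")
  st <- simulate_study(list(seed = 11, n_parents = 4L, n_families = 5L,
                            offspring_per_family = 3L), dir = dir)
  expect_true(all(file.exists(unlist(st$files))))
  # pipeline-ready: re-read inputs and validate cross-references
  counts <- read_count_table(st$files$counts)
  seqs <- read_aligned_fasta(st$files$fasta)
  ped <- read_pedigree(st$files$pedigree)
  meta <- read_sample_metadata(st$files$metadata, counts, ped)
  expect_equal(counts, st$counts)
  expect_setequal(names(seqs), rownames(counts))
  truth <- jsonlite::read_json(st$files$truth)
  expect_equal(truth$h2, st$truth$sigma2_A / (st$truth$sigma2_A + st$truth$sigma2_e),
               tolerance = 1e-12)
  # different seeds: same schema, different counts
  st2 <- simulate_study(list(seed = 12, n_parents = 4L, n_families = 5L,
                             offspring_per_family = 3L))
  expect_equal(dim(st2$counts), dim(st$counts))
  expect_false(identical(st2$counts, st$counts))
  expect_error(simulate_study(list(bogus_key = 1)), "unknown config key")
})
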