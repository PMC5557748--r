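test_that("raw distances count differing positions with the documented gap/N rules", {
  expect_equal(raw_distances(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(raw_distances(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # gap vs base is a difference
  expect_equal(raw_distances(c(a = "AC-T", b = "ACGT"))["a", "b"], 0.25)
  # both-gap and N positions are excluded from the denominator
  expect_equal(raw_distances(c(a = "AC--", b = "AC-A"))["a", "b"], 1 / 3)
  expect_equal(raw_distances(c(a = "ACNT", b = "ACGA"))["a", "b"], 1 / 3)
  expect_error(raw_distances(c(a = "NN--", b = "--NN")), "no comparable positions")
})

test_that("raw distances match ape's raw model on gap-free alignments", {
  skip_if_not_installed("ape")
  seqs <- simulate_sequences(15, length = 200, seed = 4)
  ours <- raw_distances(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(unname(ours), unname(ref[rownames(ours), colnames(ours)]),
               tolerance = 1e-12)
})

test_that("similarity matrix is 1 - distance with unit diagonal", {
  d <- matrix(c(0, 0.25, 0.25, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  Z <- similarity_from_distances(d)
  expect_equal(Z["a", "b"], 0.75)
  expect_equal(diag(Z), c(a = 1, b = 1))
  expect_true(isSymmetric(Z))
  expect_error(similarity_from_distances(d + 2), "\\[0, 1\\]")
})

test_that("qD^Z reproduces classical limits", {
  # identity Z: Hill numbers
  Z4 <- diag(4)
  expect_equal(leinster_cobbold(rep(0.25, 4), Z4, 0), 4)           # richness
  expect_equal(leinster_cobbold(c(0.5, 0.5, 0, 0), Z4, 2), 2)      # inv Simpson
  # all-ones Z: a single effective species whatever p and q
  Z1 <- matrix(1, 4, 4)
  for (q in c(0, 0.5, 1, 2, Inf)) {
    expect_equal(leinster_cobbold(c(0.7, 0.1, 0.15, 0.05), Z1, q), 1,
                 tolerance = 1e-12)
  }
  # single-OTU support
  expect_equal(leinster_cobbold(c(1, 0, 0, 0), Z4, 2), 1)
})

test_that("qD^Z with identity Z matches independent Shannon/Simpson computations", {
  skip_if_not_installed("vegan")
  set.seed(10)
  for (r in 1:5) {
    p <- rgamma(8, 1); p <- p / sum(p)
    Z <- diag(8)
    expect_equal(leinster_cobbold(p, Z, 1),
                 exp(vegan::diversity(p, index = "shannon")), tolerance = 1e-9)
    expect_equal(leinster_cobbold(p, Z, 2),
                 vegan::diversity(p, index = "invsimpson"), tolerance = 1e-9)
  }
})

test_that("qD^Z equals the brute-force defining sum and is continuous at q = 1", {
  p <- c(0.6, 0.3, 0.1)
  Z <- matrix(0.9, 3, 3); diag(Z) <- 1
  for (q in c(0, 0.5, 2, 5, Inf)) {
    expect_equal(leinster_cobbold(p, Z, q), oracle_qdz(p, Z, q),
                 tolerance = 1e-12)
  }
  d1 <- leinster_cobbold(p, Z, 1)
  expect_equal(d1, oracle_qdz(p, Z, 1), tolerance = 1e-12)
  expect_lt(abs(leinster_cobbold(p, Z, 1 + 1e-6) - d1), 1e-4)
  expect_lt(abs(leinster_cobbold(p, Z, 1 - 1e-6) - d1), 1e-4)
  expect_true(leinster_cobbold(p, Z, 1 - 1e-6) >= d1)
  expect_true(leinster_cobbold(p, Z, 1 + 1e-6) <= d1)
})

test_that("diversity is non-increasing in q and bounded by support size", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(3:12, 1)
    p <- rgamma(n, 0.5); p[sample(n, 1)] <- 0; p <- p / sum(p)
    d <- raw_distances(simulate_sequences(n, length = 150, seed = r))
    Z <- similarity_from_distances(d)
    qs <- c(0, 0.5, 1, 2, 4, Inf)
    Dv <- vapply(qs, function(q) leinster_cobbold(p, Z, q), numeric(1))
    expect_true(all(diff(Dv) <= 1e-9))
    expect_true(all(Dv >= 1 - 1e-12))
    expect_true(all(Dv <= sum(p > 0) + 1e-9))
  }
})

test_that("merging identical OTUs leaves diversity unchanged", {
  set.seed(5)
  seqs <- simulate_sequences(6, length = 150, seed = 5)
  seqs <- c(seqs, dup = unname(seqs[2]))  # exact duplicate of OTU 2
  Z <- similarity_from_distances(raw_distances(seqs))
  p <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1)
  p_merged <- c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1)
  Zm <- Z[1:6, 1:6]
  for (q in c(0.5, 1, 2)) {
    expect_equal(leinster_cobbold(p, Z, q),
                 leinster_cobbold(p_merged, Zm, q), tolerance = 1e-9)
  }
})

test_that("per-sample phenotypes match scalar evaluation and duplicate samples", {
  st <- simulate_study(list(seed = 6, n_parents = 4L, n_families = 5L,
                            offspring_per_family = 4L, n_principal = 6L,
                            n_background = 20L))
  norm <- normalize_counts(st$counts)
  Z <- similarity_from_distances(raw_distances(st$seqs))
  tr <- diversity_phenotypes(norm, Z, q = 1)
  for (j in sample(ncol(norm), 5)) {
    p <- norm[, j] / sum(norm[, j])
    expect_equal(tr$D[j], leinster_cobbold(p, Z, 1), tolerance = 1e-12)
  }
  # duplicating a sample duplicates its trait value
  norm2 <- cbind(norm, dup = norm[, 1])
  colnames(norm2) <- c(colnames(norm), "dup")
  tr2 <- diversity_phenotypes(norm2, Z, q = 1)
  expect_equal(tr2$D[ncol(norm2)], tr$D[1])
  # axis mismatch errors
  expect_error(diversity_phenotypes(norm[-1, , drop = FALSE], Z), "match")
})
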