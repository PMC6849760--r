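# Composition statistics: rarefaction, Bray-Curtis, PCoA, PERMANOVA.

test_that("filter_and_rarefy enforces the read-count boundary and even depth", {
  cnt <- rbind(a = c(500, 499), b = c(600, 400), c = c(999, 0),
               d = c(3000, 1000))
  out <- filter_and_rarefy(cnt, min_reads = 1000, depth = 1000, seed = 2)
  expect_setequal(rownames(out), c("b", "d"))  # 999 dropped, 1000 kept
  expect_true(all(rowSums(out) == 1000))
  # rarefying a row to its own sum leaves it untouched
  expect_equal(out["b", ], cnt["b", ])
  expect_error(filter_and_rarefy(cnt, min_reads = 5000), "below min_reads")
  expect_error(filter_and_rarefy(cnt, depth = 2000), "exceeds")
  expect_error(filter_and_rarefy(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  # seeded: reproducible draws
  o1 <- filter_and_rarefy(cnt, depth = 800, seed = 7)
  o2 <- filter_and_rarefy(cnt, depth = 800, seed = 7)
  expect_identical(o1, o2)
})

test_that("rarefaction subsamples without replacement", {
  row <- c(10, 0, 5, 2000)
  out <- filter_and_rarefy(rbind(r = row, s = c(0, 0, 0, 3000)),
                           min_reads = 1000, depth = 1500, seed = 1)
  expect_true(all(out["r", ] <= row))  # can never exceed the original counts
  expect_equal(sum(out["r", ]), 1500)
})

test_that("bray_curtis: hand values and metric properties", {
  cnt <- rbind(u = c(1, 2), v = c(2, 1), w = c(0, 3), z = c(1, 2))
  d <- bray_curtis(cnt)
  expect_equal(d["u", "v"], 1 / 3)          # hand computation: 2/6
  expect_equal(d["u", "z"], 0)              # identical samples
  disjoint <- bray_curtis(rbind(p = c(5, 0), q = c(0, 7)))
  expect_equal(disjoint["p", "q"], 1)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # invariant to taxon column order
  d2 <- bray_curtis(cnt[, 2:1])
  expect_equal(d, d2)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "empty")
})

test_that("pcoa exactly embeds Euclidean configurations", {
  set.seed(4)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec, d, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(ord$percent_variance), 100)
  # equilateral triangle: two equal positive eigenvalues
  tri <- matrix(1, 3, 3) - diag(3)
  e <- pcoa(tri)$eigenvalues
  expect_equal(e[1], e[2], tolerance = 1e-12)
  expect_equal(e[3], 0, tolerance = 1e-12)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("pcoa agrees with classical scaling on Bray-Curtis data", {
  set.seed(12)
  cnt <- matrix(rpois(6 * 10, 30), 6, 10,
                dimnames = list(paste0("s", 1:6), NULL))
  d <- bray_curtis(cnt)
  ord <- pcoa(d)
  ref <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  expect_equal(abs(ord$coordinates[, 1:2]), abs(ref$points),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_length(ord$eigenvalues, 6)  # full spectrum reported, none dropped
})

test_that("permanova matches an exhaustive enumeration on a 6-sample toy", {
  cnt <- rbind(a1 = c(10, 1, 0), a2 = c(9, 2, 1), a3 = c(11, 1, 1),
               b1 = c(1, 9, 2), b2 = c(2, 10, 1), b3 = c(0, 11, 2))
  fac <- data.frame(g = rep(c("a", "b"), each = 3))
  d <- bray_curtis(cnt)
  pm <- permanova(d, fac, n_perm = 9999, seed = 5)
  # exhaustive oracle: all 720 orderings of the labels
  G <- phytomet:::.gower_centre(d)
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  H <- X %*% solve(crossprod(X), t(X))
  Fstat <- function(Gm) {
    ss1 <- sum(H * Gm) - sum(Gm) / 6
    ssr <- sum(diag(Gm)) - ss1 - sum(Gm) / 6
    (ss1 / 1) / (ssr / 4)
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  F_obs <- Fstat(G)
  F_all <- apply(perms, 1, function(idx) Fstat(G[idx, idx]))
  p_exact <- mean(F_all >= F_obs - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(pm$p_value[1] - p_exact), max(3 * se, 1e-3))
  expect_equal(pm$pseudo_F[1], F_obs)
})

test_that("permanova R2 partition sums to one and separation floors p", {
  cfg <- sim_config(n_cells = 10, seed = 2)
  tab <- simulate_asv_table(cfg, separation = 6, concentration = 500)
  rare <- filter_and_rarefy(tab$counts, seed = 3)
  pm <- permanova(bray_curtis(rare), tab$sample_meta, n_perm = 999,
                  seed = 3)
  expect_equal(sum(pm$partial_R2), 1)
  # perfectly separated groups: minimal attainable p = 1/(1+n_perm)
  expect_equal(pm$p_value[pm$term == "mesocosm_treatment"], 1 / 1000)
  expect_error(permanova(bray_curtis(rare),
                         data.frame(x = rep("same", nrow(rare))),
                         n_perm = 9), "fewer than 2")
  # aliased factors are reported by name
  ali <- tab$sample_meta
  ali$copy <- ali$mesocosm_treatment
  expect_error(permanova(bray_curtis(rare), ali, n_perm = 9), "aliased")
})

test_that("null labels give approximately uniform PERMANOVA p-values", {
  set.seed(30)
  ps <- replicate(40, {
    cnt <- matrix(rpois(8 * 6, 25), 8, 6,
                  dimnames = list(paste0("s", 1:8), NULL))
    fac <- data.frame(g = sample(rep(c("x", "y"), 4)))
    permanova(bray_curtis(cnt), fac, n_perm = 99,
              seed = sample.int(1e6, 1))$p_value[1]
  })
  expect_gt(mean(ps), 0.25)   # not systematically small
  expect_gt(mean(ps < 0.25), 0.05)  # nor systematically large
})
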