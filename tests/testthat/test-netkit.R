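block_expr <- function(n_per = 40, n_samp = 12, n_noise = 0, seed = 3) {
  withr::with_seed(seed, {
    base1 <- stats::rnorm(n_samp)
    base2 <- stats::rnorm(n_samp)
    x <- rbind(
      t(replicate(n_per, base1 + stats::rnorm(n_samp, 0, 0.05))),
      t(replicate(n_per, base2 + stats::rnorm(n_samp, 0, 0.05))),
      if (n_noise > 0) matrix(stats::rnorm(n_noise * n_samp), n_noise))
    rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
    x
  })
}

test_that("pick_soft_threshold honours its contract", {
  # hub model: cor(i, j) = w_i * w_j with heavy-tailed loadings gives a
  # power-law-like degree distribution
  withr::with_seed(2, {
    n <- 300; s <- 12
    w <- stats::runif(n)^0.25 * sample(c(1, -1), n, TRUE)
    h <- stats::rnorm(s)
    x <- t(vapply(w, function(wi) wi * h + sqrt(1 - wi^2) * stats::rnorm(s),
                  numeric(s)))
    rownames(x) <- sprintf("g%03d", seq_len(n))
  })
  # candidate list of length 1 -> that power
  expect_identical(as.numeric(pick_soft_threshold(x, candidate_powers = 7)), 7)
  p <- pick_soft_threshold(x)
  fits <- attr(p, "fits")
  # the power-law fixture reaches a good scale-free fit at the chosen power
  expect_gte(fits$rsq[fits$power == as.numeric(p)], 0.8)
  # selection rule: smallest candidate reaching the cut, else max R^2
  ok <- which(!is.na(fits$rsq) & fits$rsq >= 0.8)
  want <- if (length(ok)) fits$power[min(ok)] else
    fits$power[which.max(fits$rsq)]
  expect_identical(as.numeric(p), want)
  # permuted, signal-free data falls back to the max-R^2 rule without crash
  withr::with_seed(5, {
    xp <- t(apply(x, 1, sample))
    p0 <- pick_soft_threshold(xp)
    f0 <- attr(p0, "fits")
    if (all(f0$rsq < 0.8, na.rm = TRUE))
      expect_identical(as.numeric(p0), f0$power[which.max(f0$rsq)])
  })
})

test_that("detect_modules recovers planted blocks and rejects noise", {
  x <- carballoc:::standardize_rows(block_expr(40, 12, 0))
  ms <- detect_modules(x, power = 6, min_module_size = 10)
  expect_s3_class(ms, "module_set")
  expect_identical(max(ms$labels), 2L)
  truth <- rep(1:2, each = 40)
  expect_identical(adjusted_rand_index(ms$labels, truth), 1)

  withr::with_seed(8, {
    noise <- carballoc:::standardize_rows(matrix(stats::rnorm(200 * 12), 200))
    rownames(noise) <- sprintf("n%03d", 1:200)
  })
  ms0 <- detect_modules(noise, power = 6, min_module_size = 30)
  expect_identical(unique(unname(ms0$labels)), 0L)

  # fewer genes than min_module_size -> single unassigned module
  tiny <- detect_modules(noise[1:5, ], power = 6, min_module_size = 30)
  expect_identical(unname(tiny$labels), rep(0L, 5))
})

test_that("detect_modules is invariant to gene order up to relabeling", {
  x <- carballoc:::standardize_rows(block_expr(30, 12, 20, seed = 13))
  ms1 <- detect_modules(x, power = 6, min_module_size = 10)
  withr::with_seed(1, perm <- sample(nrow(x)))
  ms2 <- detect_modules(x[perm, ], power = 6, min_module_size = 10)
  expect_identical(
    adjusted_rand_index(ms1$labels[rownames(x)[perm]], ms2$labels), 1)
})

test_that("module_eigengene handles the degenerate and closed-form cases", {
  x <- matrix(c(1, 3, 2, 5, 4, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  eg <- module_eigengene(x, c(g1 = 1L))
  std <- as.numeric(scale(as.numeric(x)))
  expect_equal(abs(stats::cor(eg$eigengenes[, 1], std)), 1)
  expect_equal(unname(eg$var_explained), 1)

  # two identical genes: same as the single-gene case
  x2 <- rbind(g1 = x[1, ], g2 = x[1, ])
  eg2 <- module_eigengene(x2, c(g1 = 1L, g2 = 1L))
  expect_equal(unname(eg2$var_explained), 1)
  expect_equal(abs(stats::cor(eg2$eigengenes[, 1], eg$eigengenes[, 1])), 1)

  # two orthogonal equal-variance genes: var_explained exactly 1/2
  a <- c(1, -1, 1, -1, 1, -1)
  b <- c(1, 1, -1, -1, 1, -1) # construct orthogonal to a after centering
  b <- b - mean(b)
  a <- a - mean(a)
  b <- b - a * sum(a * b) / sum(a * a)
  x3 <- rbind(g1 = a, g2 = b)
  colnames(x3) <- paste0("s", 1:6)
  eg3 <- module_eigengene(x3, c(g1 = 1L, g2 = 1L))
  expect_equal(unname(eg3$var_explained), 0.5, tolerance = 1e-12)

  # eigengene orientation: mean member correlation is non-negative
  sim <- small_sim()
  lab <- sim$truth$module_labels
  cl <- sim$samples$sample[sim$samples$genotype == "CL"]
  lx <- log2(sim$counts[names(lab)[lab > 0], cl] + 1)
  eg4 <- module_eigengene(lx, lab[lab > 0])
  for (m in colnames(eg4$eigengenes)) {
    mm <- as.integer(sub("ME", "", m))
    genes <- names(lab)[lab == mm]
    expect_gte(mean(stats::cor(t(lx[genes, ]), eg4$eigengenes[, m])), 0)
  }
})

test_that("kME equals the brute-force per-pair correlation loop", {
  withr::with_seed(21, {
    x <- matrix(stats::rnorm(20 * 10), 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    x[20, ] <- 0   # zero-variance convention
  })
  labels <- stats::setNames(rep(1:2, each = 10), rownames(x))
  eg <- module_eigengene(x[1:19, ], labels[1:19])
  k <- module_membership(x, eg$eigengenes)
  for (i in 1:19) for (j in seq_len(ncol(k)))
    expect_equal(k[i, j], stats::cor(x[i, ], eg$eigengenes[, j]))
  expect_identical(unname(k[20, ]), c(0, 0))
})

test_that("kME is highest in a gene's own module on planted fixtures", {
  sim <- small_sim()
  lab <- sim$truth$module_labels
  cl <- sim$samples$sample[sim$samples$genotype == "CL"]
  lx <- carballoc:::standardize_rows(
    log2(sim$counts[names(lab)[lab > 0], cl] + 1))
  eg <- module_eigengene(lx, lab[lab > 0])
  k <- module_membership(lx, eg$eigengenes)
  own <- k[cbind(seq_len(nrow(k)), lab[rownames(k)])]
  other <- apply(k, 1, function(z) stats::median(z))
  expect_gt(stats::median(own), stats::median(other))
  expect_gt(stats::median(own), 0.8)
})

test_that("module_preservation separates planted from random structure", {
  x <- block_expr(30, 12, 60, seed = 31)
  labels <- stats::setNames(c(rep(1:2, each = 30), rep(0, 60)), rownames(x))
  pres <- module_preservation(x, x, labels, n_permutations = 100, seed = 4)
  expect_true(all(pres$z_summary > 2))
  expect_identical(unique(pres$n_permutations), 100)

  withr::with_seed(6, rand <- stats::setNames(sample(labels), names(labels)))
  pres0 <- module_preservation(x, x[sample(nrow(x)), ], rand,
                               n_permutations = 100, seed = 4)
  expect_lt(stats::median(abs(pres0$z_summary)), 2)
  expect_error(module_preservation(x, x, labels, n_permutations = 0), ">= 1")
})

test_that("adding a noise gene never increases var_explained", {
  withr::with_seed(17, {
    base <- stats::rnorm(10)
    mod <- t(replicate(8, base + stats::rnorm(10, 0, 0.1)))
    rownames(mod) <- paste0("g", 1:8)
    for (i in 1:5) {
      noise <- matrix(stats::rnorm(10), 1, dimnames = list("noise"))
      ve1 <- module_eigengene(mod, stats::setNames(rep(1L, 8),
                                                   rownames(mod)))$var_explained
      aug <- rbind(mod, noise)
      ve2 <- module_eigengene(aug, stats::setNames(rep(1L, 9),
                                                   rownames(aug)))$var_explained
      expect_lte(unname(ve2), unname(ve1) + 1e-12)
    }
  })
})

test_that("classify_trend maps sign patterns to the trend classes", {
  expect_identical(classify_trend(c(0, 1, 2, 3)), "up")
  expect_identical(classify_trend(c(3, 2, 1, 0)), "down")
  expect_identical(classify_trend(c(0, 2, 1, 0.5)), "up_down")
  expect_identical(classify_trend(c(2, 0, 1, 2)), "down_up")
  expect_identical(classify_trend(c(1, 1.05, 1)), "flat")
  expect_identical(classify_trend(c(0, 1, 0, 1)), "complex")
  # flat band swallows small wiggles
  expect_identical(classify_trend(c(0, 1, 1.05, 2), eps = 0.1), "up")
})
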