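# Genotype summaries, HWE and LD tests, Holm correction, autocorrelograms
# and Mantel tests.

test_that("locus summaries give gene-counting freqs, Ho and unbiased He", {
  gt <- genotype_table(c("a", "b"), "L1",
                       matrix(c(100L, 100L)), matrix(c(102L, 102L)))
  s <- locus_summaries(gt)
  fr <- attr(s, "freqs")$L1
  expect_equal(as.numeric(fr), c(0.5, 0.5))
  expect_equal(s$Ho, 1)
  # monomorphic locus
  gt2 <- genotype_table(c("a", "b"), "L1",
                        matrix(c(100L, 100L)), matrix(c(100L, 100L)))
  expect_warning(s2 <- locus_summaries(gt2), "monomorphic")
  expect_equal(s2$Ho, 0); expect_equal(s2$He, 0); expect_equal(s2$n_alleles, 1)
  # He matches a direct transcription of the formula on simulated data
  set.seed(21)
  pools <- rand_pools(1, 8); frq <- rand_freqs(pools)
  gts <- replicate(50, draw_genotype(pools, frq), simplify = FALSE)
  g <- gt_from_list(gts)
  s3 <- locus_summaries(g)
  al <- c(g$a1[, 1], g$a2[, 1])
  p <- as.numeric(table(al)) / length(al)
  n <- 50
  expect_equal(s3$He, (2 * n / (2 * n - 1)) * (1 - sum(p^2)), tolerance = 1e-12)
})

test_that("HWE Monte-Carlo test behaves at the trivial extremes", {
  set.seed(22)
  # exact HW proportions: 25 AA, 50 AB, 25 BB
  a1 <- c(rep(1L, 25), rep(1L, 50), rep(2L, 25))
  a2 <- c(rep(1L, 25), rep(2L, 50), rep(2L, 25))
  expect_gte(hwe_exact_test(a1, a2, n_mc = 999)$p, 0.99)
  # total heterozygote deficit: 50 AA, 50 BB
  b1 <- c(rep(1L, 50), rep(2L, 50)); b2 <- b1
  expect_lt(hwe_exact_test(b1, b2, n_mc = 1999)$p, 0.001)
  expect_error(hwe_exact_test(rep(NA_integer_, 5), rep(NA_integer_, 5)), "missing")
  expect_error(hwe_exact_test(rep(1L, 5), rep(1L, 5)), "monomorphic")
})

test_that("HWE Monte-Carlo p matches the full-enumeration (Levene) oracle", {
  # 2 alleles, 10 individuals: enumerate all heterozygote counts compatible
  # with the allele counts; exact conditional p by the Levene distribution
  set.seed(23)
  a1 <- c(1L, 1L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L)
  a2 <- c(1L, 2L, 2L, 2L, 1L, 2L, 1L, 2L, 2L, 2L)
  n <- 10
  nA <- sum(c(a1, a2) == 1L)
  h_obs <- sum(a1 != a2)
  # P(h | nA, n) proportional to n! 2^h / (nAA! h! nBB!) with
  # nAA = (nA - h)/2; support: h with matching parity
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- n - naa - h
    lfactorial(n) + h * log(2) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, numeric(1))
  prob <- exp(logp - max(logp)); prob <- prob / sum(prob)
  p_exact <- sum(prob[prob <= prob[hs == h_obs] + 1e-12])
  mc <- hwe_exact_test(a1, a2, n_mc = 10000)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$p - p_exact), 3 * se + 1e-4)
})

test_that("LD permutation test flags perfect association and skips small n", {
  set.seed(24)
  pools <- rand_pools(1, 6); frq <- rand_freqs(pools)
  gts <- replicate(50, draw_genotype(pools, frq), simplify = FALSE)
  a1 <- vapply(gts, function(g) g[1, 1], integer(1))
  a2 <- vapply(gts, function(g) g[2, 1], integer(1))
  gt <- genotype_table(sprintf("i%02d", 1:50), c("A", "B"),
                       cbind(a1, a1), cbind(a2, a2))  # locus B = copy of A
  res <- ld_permutation_test(gt, "A", "B", n_perm = 1999)
  expect_lte(res$p, 0.001)
  small <- genotype_table(sprintf("i%d", 1:5), c("A", "B"),
                          cbind(a1[1:5], a1[1:5]), cbind(a2[1:5], a2[1:5]))
  expect_true(ld_permutation_test(small, "A", "B")$skipped)
})

test_that("LD p-values are uniform under the null", {
  set.seed(25)
  B <- 200
  ps <- vapply(seq_len(B), function(b) {
    n <- 100
    g <- function() {
      a <- sample(1:4, 2 * n, replace = TRUE)
      list(a1 = pmin(a[1:n], a[n + 1:n]), a2 = pmax(a[1:n], a[n + 1:n]))
    }
    l1 <- g(); l2 <- g()
    gt <- genotype_table(sprintf("i%03d", 1:n), c("A", "B"),
                         cbind(l1$a1, l2$a1), cbind(l1$a2, l2$a2))
    ld_permutation_test(gt, "A", "B", n_perm = 199)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Holm-Bonferroni flags match the stepwise rule and p.adjust", {
  expect_true(holm_bonferroni(0.004, initial_alpha = 0.0065))
  expect_false(any(holm_bonferroni(rep(1, 8))))
  # independent stepwise reference on random vectors
  holm_ref <- function(p, alpha) {
    m <- length(p); ord <- order(p); rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
    }
    rej
  }
  set.seed(26)
  for (b in 1:50) {
    p <- stats::runif(sample(3:12, 1))^sample(1:3, 1)
    got <- holm_bonferroni(p, alpha = 0.05)
    expect_identical(got, holm_ref(p, 0.05))
    expect_identical(got, unname(stats::p.adjust(p, "holm") <= 0.05))
  }
})

test_that("Loiselle kinship matches a longhand transcription and its known
           small-sample behaviour", {
  # 10 individuals, one 2-allele locus, worked by direct formula
  set.seed(27)
  a1 <- sample(c(100L, 102L), 10, TRUE, prob = c(0.3, 0.7))
  a2 <- sample(c(100L, 102L), 10, TRUE, prob = c(0.3, 0.7))
  gt <- genotype_table(sprintf("i%02d", 1:10), "L1",
                       matrix(pmin(a1, a2)), matrix(pmax(a1, a2)))
  k <- loiselle_kinship(gt)
  # longhand: dosages, freqs, correction p(1-p)/(n_genes - 1)
  al <- c(a1, a2)
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    i <- pair[1]; j <- pair[2]
    num <- 0; den <- 0
    for (a in c(100L, 102L)) {
      pa <- mean(al == a)
      pia <- (sum(a1[i] == a) + sum(a2[i] == a)) / 2
      pja <- (sum(a1[j] == a) + sum(a2[j] == a)) / 2
      num <- num + (pia - pa) * (pja - pa) + pa * (1 - pa) / (20 - 1)
      den <- den + pa * (1 - pa)
    }
    expect_equal(k[i, j], num / den, tolerance = 1e-12)
  }
  # mean over all reference dyads sits at (or just below) zero
  expect_lt(mean(k, na.rm = TRUE), 0.05)
  # identical genotypes sharing rare alleles -> positive kinship
  gt2 <- genotype_table(sprintf("i%02d", 1:12), "L1",
                        matrix(c(104L, 104L, rep(100L, 10))),
                        matrix(c(106L, 106L, rep(c(100L, 102L), 5))))
  k2 <- loiselle_kinship(gt2)
  expect_gt(k2[1, 2], 0)
})

test_that("kinship matrix is symmetric and invariant to locus order and
           allele relabeling", {
  set.seed(28)
  pools <- rand_pools(4, 10); frq <- rand_freqs(pools)
  gts <- replicate(15, draw_genotype(pools, frq), simplify = FALSE)
  gt <- gt_from_list(gts)
  k <- loiselle_kinship(gt)
  expect_equal(k, t(k))
  # permute loci
  perm <- c(3, 1, 4, 2)
  gtp <- genotype_table(gt$ids, gt$loci[perm], gt$a1[, perm], gt$a2[, perm])
  expect_equal(loiselle_kinship(gtp), k, tolerance = 1e-12)
  # relabel alleles (order-preserving shift at one locus)
  gtr <- gt
  gtr$a1[, 2] <- gtr$a1[, 2] + 500L
  gtr$a2[, 2] <- gtr$a2[, 2] + 500L
  expect_equal(loiselle_kinship(gtr), k, tolerance = 1e-12)
})

test_that("autocorrelogram classes partition dyads and detect forced signal", {
  set.seed(29)
  n <- 30
  ids <- sprintf("i%02d", 1:n)
  pos <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
  dmat <- as.matrix(stats::dist(pos)); dimnames(dmat) <- list(ids, ids)
  k0 <- matrix(0, n, n, dimnames = list(ids, ids)); diag(k0) <- NA
  ac0 <- autocorrelogram(k0, dmat, n_perm = 99)
  expect_equal(sum(ac0$n_pairs), n * (n - 1) / 2)
  expect_true(all(ac0$mean_k == 0))
  expect_false(any(ac0$significant))
  # clones among the closest dyads: class 1 mean above the upper envelope
  kin <- matrix(stats::rnorm(n * n, 0, 0.01), n)
  kin <- (kin + t(kin)) / 2
  thr <- stats::quantile(dmat[upper.tri(dmat)], 0.2)
  kin[dmat <= thr] <- 0.5
  diag(kin) <- NA; dimnames(kin) <- list(ids, ids)
  ac <- autocorrelogram(kin, dmat, n_perm = 199)
  expect_gt(ac$mean_k[1], ac$env_hi[1])
  expect_true(ac$significant[1])
  # class means weighted by pair counts average to the overall mean
  expect_equal(sum(ac$mean_k * ac$n_pairs) / sum(ac$n_pairs),
               mean(kin[upper.tri(kin)], na.rm = TRUE), tolerance = 1e-12)
})

test_that("Mantel r is exact on identical matrices and matches vegan", {
  set.seed(30)
  n <- 15
  m <- matrix(stats::runif(n * n), n); m <- m + t(m); diag(m) <- 0
  res <- mantel_test(m, m, n_perm = 199)
  expect_equal(res$r, 1)
  expect_lte(res$p, 0.05)
  m2 <- matrix(stats::runif(n * n), n); m2 <- m2 + t(m2); diag(m2) <- 0
  r_pkg <- mantel_test(m, m2, n_perm = 99)$r
  skip_if_not_installed("vegan")
  expect_equal(r_pkg, unname(vegan::mantel(m, m2, permutations = 9)$statistic),
               tolerance = 1e-10)
  # constant matrix flagged
  expect_true(!is.null(mantel_test(matrix(1, n, n) - diag(n), m)$flagged))
})

test_that("Mantel permutation p agrees with complete 4! enumeration", {
  set.seed(31)
  n <- 4
  a <- matrix(stats::runif(16), 4); a <- a + t(a); diag(a) <- 0
  b <- matrix(stats::runif(16), 4); b <- b + t(b); diag(b) <- 0
  perms <- list()
  pm <- expand.grid(1:4, 1:4, 1:4, 1:4)
  pm <- pm[apply(pm, 1, function(x) length(unique(x)) == 4), ]
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], b[ut])
  rs <- apply(pm, 1, function(p) {
    bp <- b[unlist(p), unlist(p)]
    stats::cor(a[ut], bp[ut])
  })
  p_exact <- mean(rs >= r_obs - 1e-12)
  res <- mantel_test(a, b, n_perm = 4999)
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(res$p - p_exact), 3 * se + 1e-3)
})

test_that("a heavyweight neighbouring only its son shows elevated kinship", {
  hab <- toy_habitat(list(c(0, 0, 10, 2), c(50, 0, 60, 2), c(90, 0, 100, 2)))
  cap <- validate_captures(rbind(
    cap_row("f", 2010, "spring", "M", 70, 1),
    cap_row("son", 2010, "spring", "M", 50, 1),
    cap_row("far", 2010, "spring", "M", 50, 3)), hab)
  kin <- matrix(0, 3, 3, dimnames = list(c("f", "son", "far"),
                                         c("f", "son", "far")))
  kin["f", "son"] <- kin["son", "f"] <- 0.25
  diag(kin) <- NA
  hrs <- home_ranges(cap, hab)
  rec <- neighbor_relatedness_contrast("f", cap, kin, hrs[["f"]], hab)
  expect_equal(rec$neighbours, "son")
  expect_equal(rec$mean_k_neighbour, 0.25)
  expect_gt(rec$mean_k_neighbour, rec$mean_k_population)
  # all-zero kinship -> zero difference
  rec0 <- neighbor_relatedness_contrast("f", cap, 0 * kin, hrs[["f"]], hab)
  expect_equal(rec0$difference, 0)
})
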