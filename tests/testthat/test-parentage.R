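# The parentage likelihood engine and the sequential consensus procedure.

simple_freqs <- function(alleles, p) {
  stats::setNames(list(structure(stats::setNames(p, alleles),
                                 n_genes = 1000L)), "L01")
}

test_that("transmission likelihood handles exclusion and forced transmission", {
  fr <- simple_freqs(c(100L, 102L), c(0.5, 0.5))
  off <- rbind(100L, 100L); cand <- rbind(102L, 102L)
  expect_equal(transmission_likelihood(off, cand, NULL, fr, 0), -Inf)
  # offspring (A,B), candidate (A,A), other (B,B): per-locus likelihood 1
  off2 <- rbind(100L, 102L)
  sire <- rbind(100L, 100L); dam <- rbind(102L, 102L)
  expect_equal(transmission_likelihood(off2, sire, dam, fr, 0), 0)  # log 1
  # no co-genotyped locus -> NA
  expect_true(is.na(transmission_likelihood(off2, rbind(NA_integer_, NA_integer_),
                                            NULL, fr, 0)))
})

test_that("transmission likelihood equals exhaustive enumeration with error", {
  # one locus, 4 alleles: brute-force sum over transmitted pairs and
  # independent per-allele error events on the observed offspring genotype
  alleles <- c(100L, 102L, 104L, 106L)
  p <- c(0.4, 0.3, 0.2, 0.1)
  fr <- simple_freqs(alleles, p)
  eps <- 0.05
  e <- function(obs, true) if (obs == true) 1 - eps else eps / 3
  brute <- function(off, sire, dam = NULL) {
    tot <- 0
    dam_draws <- if (is.null(dam)) alleles else dam
    dam_probs <- if (is.null(dam)) p else rep(0.5, 2)
    for (si in 1:2) for (dj in seq_along(dam_draws)) {
      true <- c(sire[si], dam_draws[dj])
      w <- 0.5 * dam_probs[dj]
      # unordered observed pair (u, v) against ordered true genotype
      u <- off[1]; v <- off[2]
      pr <- if (u == v) e(u, true[1]) * e(v, true[2])
            else e(u, true[1]) * e(v, true[2]) + e(v, true[1]) * e(u, true[2])
      tot <- tot + w * pr
    }
    tot
  }
  set.seed(41)
  for (rep in 1:20) {
    off <- rbind(sample(alleles, 1), sample(alleles, 1))
    sire <- rbind(sample(alleles, 1), sample(alleles, 1))
    dam <- rbind(sample(alleles, 1), sample(alleles, 1))
    expect_equal(exp(transmission_likelihood(off, sire, NULL, fr, eps)),
                 brute(off, sire), tolerance = 1e-12)
    expect_equal(exp(transmission_likelihood(off, sire, dam, fr, eps)),
                 brute(off, sire, dam), tolerance = 1e-12)
  }
})

test_that("a lone true sire is assigned with high support", {
  set.seed(42)
  pools <- rand_pools(8, 20); frq <- rand_freqs(pools)
  sire <- draw_genotype(pools, frq); dam <- draw_genotype(pools, frq)
  off <- mendelian_offspring(sire, dam)
  gt <- gt_from_list(list(sire, dam, off), ids = c("S", "D", "O"))
  fr <- freqs_from_known(frq)
  links <- assign_parents(gt, "O", "S", "D", fr)
  sl <- links[links$parent_role == "sire", ]
  expect_equal(sl$parent_id, "S")
  expect_gt(sl$support, 0.95)
  # no candidates -> no links
  none <- assign_parents(gt, "O", character(0), character(0), fr)
  expect_equal(nrow(none), 0)
})

test_that("equal-likelihood candidate ties refuse assignment", {
  set.seed(43)
  pools <- rand_pools(8, 20); frq <- rand_freqs(pools)
  sire <- draw_genotype(pools, frq); dam <- draw_genotype(pools, frq)
  off <- mendelian_offspring(sire, dam)
  # identical twin candidates
  gt <- gt_from_list(list(sire, sire, dam, off),
                     ids = c("S1", "S2", "D", "O"))
  links <- assign_parents(gt, "O", c("S1", "S2"), "D", freqs_from_known(frq))
  expect_false(any(links$parent_role == "sire"))
  expect_true(any(links$parent_role == "dam"))
})

test_that("offspring with excessive missing data are skipped with a reason", {
  set.seed(44)
  pools <- rand_pools(8, 20); frq <- rand_freqs(pools)
  sire <- draw_genotype(pools, frq); dam <- draw_genotype(pools, frq)
  off <- mendelian_offspring(sire, dam)
  off[, 1:5] <- NA_integer_
  gt <- gt_from_list(list(sire, dam, off), ids = c("S", "D", "O"))
  links <- assign_parents(gt, "O", "S", "D", freqs_from_known(frq))
  expect_equal(nrow(links), 0)
  expect_equal(attr(links, "skipped")$id, "O")
})

test_that("founders-only input yields an empty pedigree", {
  sim <- simulate_population(sim_config(founder_n = 30, n_cohorts = 2,
                                        capture_prob = 1, seed = 45))
  cap1 <- sim$captures[sim$captures$cohort == "S2010", ]
  gt <- sim$genotypes
  keep <- match(unique(cap1$id), gt$ids)
  gt1 <- genotype_table(gt$ids[keep], gt$loci,
                        gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE])
  ped <- sequential_pedigree(cap1, gt1,
                             parentage_config(n_replicates = 1), seeds = 1)
  expect_equal(nrow(ped), 0)
})

test_that("a deterministic engine makes replicates and consensus identical", {
  sim <- simulate_population(sim_config(founder_n = 50, n_cohorts = 4, seed = 46))
  cfg <- parentage_config(replicate_perturb = 0)
  ped <- sequential_pedigree(sim$captures, sim$genotypes, cfg, seeds = 1:3)
  reps <- attr(ped, "replicates")
  key <- function(d) sort(paste(d$offspring_id, d$parent_id, d$parent_role))
  expect_identical(key(reps[[1]]), key(reps[[2]]))
  expect_identical(key(reps[[1]]), key(reps[[3]]))
  expect_identical(key(ped), key(reps[[1]]))
})

test_that("consensus links are a subset of every replicate's links", {
  sim <- simulate_population(sim_config(founder_n = 50, n_cohorts = 4, seed = 47))
  ped <- sequential_pedigree(sim$captures, sim$genotypes,
                             parentage_config(), seeds = 1:3)
  key <- function(d) paste(d$offspring_id, d$parent_id, d$parent_role)
  for (r in attr(ped, "replicates"))
    expect_true(all(key(ped) %in% key(r)))
  expect_equal(unique(ped$replicates_supporting), 3L)
})

test_that("with no genotyping error accepted links are Mendel-compatible", {
  sim <- simulate_population(sim_config(founder_n = 50, n_cohorts = 4,
                                        genotyping_error = 0, missing_rate = 0,
                                        seed = 48))
  cfg <- parentage_config(error_rate = 1e-9, replicate_perturb = 0,
                          n_replicates = 1)
  ped <- sequential_pedigree(sim$captures, sim$genotypes, cfg, seeds = 1)
  gt <- sim$genotypes
  compatible <- function(off, par) {
    for (l in seq_along(gt$loci)) {
      o <- c(gt$a1[off, l], gt$a2[off, l]); p <- c(gt$a1[par, l], gt$a2[par, l])
      if (any(is.na(o)) || any(is.na(p))) next
      if (!any(o %in% p)) return(FALSE)
    }
    TRUE
  }
  for (r in seq_len(nrow(ped)))
    expect_true(compatible(ped$offspring_id[r], ped$parent_id[r]))
})

test_that("adding loci widens the true-vs-false parent likelihood gap", {
  set.seed(49)
  pools <- rand_pools(8, 15); frq <- rand_freqs(pools)
  gaps <- sapply(c(3, 8), function(nl) {
    mean(replicate(40, {
      sire <- draw_genotype(pools, frq); dam <- draw_genotype(pools, frq)
      fake <- draw_genotype(pools, frq)
      off <- mendelian_offspring(sire, dam)
      fr <- stats::setNames(frq[seq_len(nl)], sprintf("L%02d", seq_len(nl)))
      fr <- lapply(fr, function(x) structure(x, n_genes = 1000L))
      sub <- function(g) g[, seq_len(nl), drop = FALSE]
      transmission_likelihood(sub(off), sub(sire), NULL, fr, 0.01) -
        transmission_likelihood(sub(off), sub(fake), NULL, fr, 0.01)
    }))
  })
  expect_gt(gaps[2], gaps[1])
})
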