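# The individual-based park simulator: habitat generation, Mendelian
# inheritance, genotyping error, and the population-level contracts.

test_that("generated habitat has disjoint perimeter bushes and is seeded", {
  cfg <- sim_config()
  hab <- generate_habitat(cfg, seed = 3)
  expect_equal(length(hab$bushes), 38)
  # all bushes hug the fence
  cents <- bush_centroids(hab)
  d2fence <- apply(cents, 1, function(p) {
    pr <- anolespat:::project_on_polyline(p, hab$fence)
    sqrt(sum((p - pr$point)^2))
  })
  expect_true(all(d2fence <= cfg$bush_depth))
  # pairwise disjoint
  for (i in 1:37) for (j in (i + 1):38)
    expect_false(polygons_intersect(hab$bushes[[i]], hab$bushes[[j]]))
  # determinism
  hab2 <- generate_habitat(cfg, seed = 3)
  expect_identical(hab, hab2)
  # two bushes
  expect_equal(length(generate_habitat(sim_config(n_bushes = 2), seed = 1)$bushes), 2)
  # impossible packing
  expect_error(generate_habitat(sim_config(n_bushes = 60,
                                           bush_length_range = c(9, 10)),
                                seed = 1), "exceeds")
})

test_that("mendelian transmission follows expected segregation ratios", {
  A <- 100L; B <- 102L
  sire <- rbind(A, A); dam <- rbind(B, B)
  off <- mendelian_offspring(sire, dam)
  expect_setequal(as.integer(off), c(A, B))
  # het x het: 1/4, 1/2, 1/4 tested against the exact multinomial
  set.seed(2)
  sire <- rbind(A, B); dam <- rbind(A, B)
  n <- 10000
  draws <- replicate(n, sort(as.integer(mendelian_offspring(sire, dam))))
  lab <- paste(draws[1, ], draws[2, ])
  counts <- table(factor(lab, levels = c("100 100", "100 102", "102 102")))
  gof <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
  # missing parental locus propagates
  sire_na <- rbind(NA_integer_, NA_integer_)
  expect_true(all(is.na(mendelian_offspring(sire_na, dam))))
})

test_that("genotyping error hits each allele at the configured rate", {
  pools <- list(c(100L, 102L))
  g <- rbind(100L, 100L)
  expect_identical(apply_genotyping_error(g, 0, pools), g)
  set.seed(3)
  flipped <- apply_genotyping_error(g, 1, pools)
  expect_true(all(flipped == 102L))  # pool of 2: every allele flips
  # empirical rate within 3 binomial SE of 1%
  pools2 <- rand_pools(1, 20)
  set.seed(4)
  n <- 50000  # 1e5 allele calls
  gmat <- rbind(rep(110L, 1), rep(130L, 1))
  nerr <- 0
  for (i in seq_len(n)) {
    out <- apply_genotyping_error(gmat, 0.01, pools2)
    nerr <- nerr + sum(out != gmat)
  }
  rate <- nerr / (2 * n)
  se <- sqrt(0.01 * 0.99 / (2 * n))
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("simulation outputs are deterministic byte for byte", {
  cfg <- sim_config(founder_n = 50, n_cohorts = 4, seed = 11)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_population(cfg, d1)
  simulate_population(cfg, d2)
  for (f in c("capture.csv", "genotypes.gen", "habitat.geojson",
              "truth_pedigree.csv", "truth_ranges.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("truth pedigree is acyclic with parents alive the season before", {
  sim <- simulate_population(sim_config(founder_n = 60, n_cohorts = 6, seed = 12))
  tp <- sim$truth$pedigree_all
  expect_silent(anolespat:::check_pedigree_acyclic(
    data.frame(offspring_id = rep(tp$id, 2),
               parent_id = c(tp$sire, tp$dam),
               parent_role = rep(c("sire", "dam"), each = nrow(tp)),
               stringsAsFactors = FALSE)[!is.na(c(tp$sire, tp$dam)), ]))
  # both parents present in the truth occupancy of the offspring's birth season
  tr <- sim$truth$ranges
  first_occ <- tapply(cohort_index(tr$cohort), tr$id, min)
  kids <- tp[!is.na(tp$sire), ]
  for (r in sample(nrow(kids), min(50, nrow(kids)))) {
    expect_true(first_occ[kids$sire[r]] < first_occ[kids$id[r]])
    expect_true(first_occ[kids$dam[r]] < first_occ[kids$id[r]])
  }
})

test_that("capture_prob = 1 captures every living recruited individual", {
  sim <- simulate_population(sim_config(founder_n = 40, n_cohorts = 4,
                                        capture_prob = 1, seed = 13))
  tr <- sim$truth$ranges
  cap <- sim$captures
  for (lab in unique(tr$cohort))
    expect_setequal(cap$id[cap$cohort == lab], tr$id[tr$cohort == lab])
})

test_that("complete male natal dispersal keeps sons out of the sire territory", {
  sim <- simulate_population(sim_config(founder_n = 60, n_cohorts = 6,
                                        capture_prob = 1, seed = 14))
  tp <- sim$truth$pedigree_all
  tr <- sim$truth$ranges
  mo <- sim$truth$morph
  sex_of <- tapply(mo$sex, mo$id, function(s) s[1])
  # no son is ever recorded in a bush its sire ever held as territory
  terr <- mo[!is.na(mo$territory), c("id", "territory")]
  terr_of <- split(terr$territory, terr$id)
  sons <- tp[!is.na(tp$sire) & sex_of[tp$id] == "M" & !is.na(sex_of[tp$id]), ]
  viol <- 0
  for (r in seq_len(nrow(sons))) {
    sb <- unique(tr$bush_id[tr$id == sons$id[r]])
    tb <- terr_of[[sons$sire[r]]]
    if (length(tb) && any(sb %in% tb)) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("with p_resident_sire = 1 offspring born under a resident share him", {
  sim <- simulate_population(sim_config(founder_n = 60, n_cohorts = 5,
                                        p_resident_sire = 1, seed = 15))
  mo <- sim$truth$morph
  tp <- sim$truth$pedigree_all
  tr <- sim$truth$ranges
  natal <- stats::setNames(sim$truth$natal$natal_bush, sim$truth$natal$id)
  labs <- unique(tr$cohort)[order(cohort_index(unique(tr$cohort)))]
  first_occ <- tapply(cohort_index(tr$cohort), tr$id, min)
  kids <- tp[!is.na(tp$sire) & tp$id %in% names(first_occ), ]
  checked <- 0
  for (r in seq_len(nrow(kids))) {
    # birth season = the season before first occupancy (recruitment lag 1)
    birth_lab <- labs[match(first_occ[kids$id[r]], cohort_index(labs)) - 1]
    bush <- natal[[kids$id[r]]]
    resident <- mo$id[mo$cohort == birth_lab & !is.na(mo$territory) &
                        mo$territory == bush]
    if (length(resident)) {
      checked <- checked + 1
      expect_equal(kids$sire[r], resident)
    }
  }
  expect_gt(checked, 0)
})

test_that("founder allele frequencies track the configured pools", {
  sim <- simulate_population(sim_config(founder_n = 120, n_cohorts = 2,
                                        capture_prob = 1, missing_rate = 0,
                                        genotyping_error = 0, seed = 16))
  truth_gt <- sim$truth$genotypes
  founders <- sim$truth$pedigree_all$id[is.na(sim$truth$pedigree_all$sire)]
  founders <- intersect(founders, truth_gt$ids)
  fr <- allele_freqs(truth_gt, founders)
  pools <- sim$truth$founder_pools
  for (l in seq_along(fr)) {
    p_cfg <- pools[[l]]
    p_obs <- fr[[l]]
    # multinomial sampling tolerance with 2 * n_founders gene draws
    ng <- attr(p_obs, "n_genes")
    for (a in names(p_obs)) {
      p0 <- p_cfg[[a]]
      se <- sqrt(p0 * (1 - p0) / ng)
      expect_lt(abs(p_obs[[a]] - p0), 4 * se + 1e-9)
    }
  }
})
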