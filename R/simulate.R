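# Individual-based simulator of a fenced one-hectare park population of green
# anoles: perimeter bush habitat, territorial heavyweight males, polygynous
# mating with sneaker lightweights, Mendelian microsatellite inheritance,
# male-biased natal dispersal, seasonal growth/survival, and mark-recapture
# sampling. Emits the three pipeline input files plus a ground-truth set.

#' Simulation configuration
#'
#' Defaults emulate the study system: a 100 x 100 m fenced park with 38
#' perimeter bushes two metres deep, 8 microsatellite loci with 13-33 alleles,
#' ten seasonal cohorts (spring/fall) and on the order of 850 unique
#' individuals. Demographic rates (survival, fecundity, growth) are documented
#' modelling assumptions, not estimates of the real population.
#'
#' @param park_width,park_height park dimensions in m
#' @param n_bushes number of perimeter bushes
#' @param bush_depth bush depth into the park, m
#' @param bush_length_range along-fence bush length range, m
#' @param n_loci number of microsatellite loci
#' @param alleles_per_locus integer range of founder allele counts per locus
#' @param founder_n number of founders
#' @param n_cohorts number of seasonal cohorts simulated
#' @param start_year first (spring) cohort year
#' @param capture_prob per-individual per-cohort capture probability
#' @param p_female_philopatry probability a daughter settles in her natal bush
#' @param p_male_natal_stay probability a son settles in his natal bush
#' @param p_resident_sire probability a female's offspring is sired by her
#'   bush's resident heavyweight rather than a random lightweight
#' @param survival_prob per-season survival probability
#' @param fecundity mean recruits per adult female per season (Poisson)
#' @param maturity_svl SVL (mm) at sexual maturity
#' @param growth list of per-sex growth increments: mean, sd and asymptote
#'   (mm); SVL grows by a truncated-normal increment each season until the
#'   asymptote, so the lightweight-to-heavyweight transition emerges from
#'   growth
#' @param recruit_svl mean and sd of SVL at recruitment
#' @param genotyping_error per-allele mistyping probability in the emitted
#'   genotype file
#' @param missing_rate per-call missing-data probability in the emitted file
#' @param p_female_move per-season probability a settled female shifts to a
#'   random bush (females range more widely than site-faithful males)
#' @param sire_range_avoidance when TRUE, dispersing sons never settle in a
#'   bush within their father's home range, and territorial males never claim
#'   a bush that would bring a dispersed son's bush inside their range —
#'   the structural form of the "male offspring forced out of the father's
#'   territory" dispersal mechanism
#' @param seed RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(park_width = 100, park_height = 100,
                       n_bushes = 38, bush_depth = 2,
                       bush_length_range = c(5, 9),
                       n_loci = 8, alleles_per_locus = c(13, 33),
                       founder_n = 150, n_cohorts = 10, start_year = 2010,
                       capture_prob = 0.85,
                       p_female_philopatry = 0.8,
                       p_male_natal_stay = 0,
                       p_resident_sire = 0.8,
                       survival_prob = 0.6,
                       fecundity = 2.3,
                       maturity_svl = 45,
                       growth = list(male = c(mean = 8, sd = 2, asym = 72),
                                     female = c(mean = 6, sd = 2, asym = 60)),
                       recruit_svl = c(mean = 35, sd = 3),
                       genotyping_error = 0.01,
                       missing_rate = 0.02,
                       p_female_move = 0.3,
                       sire_range_avoidance = TRUE,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(capture_prob, p_female_philopatry, p_male_natal_stay,
             p_resident_sire, survival_prob, genotyping_error, missing_rate,
             p_female_move)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_bushes < 2) stop("need at least two bushes")
  structure(cfg, class = "sim_config")
}

#' Generate the perimeter-bush habitat map
#'
#' Rectangular bushes of the configured depth are placed along the inside of
#' the park fence with random lengths and gaps, distributed over the four
#' walls. The fence polyline is the park boundary rectangle.
#'
#' @param config a [sim_config()]
#' @param seed RNG seed (defaults to the config seed)
#' @return a `habitat_map`
#' @export
generate_habitat <- function(config, seed = config$seed) {
  set.seed(seed)
  W <- config$park_width; H <- config$park_height
  n <- config$n_bushes
  lr <- config$bush_length_range
  # walls: 1 south, 2 east, 3 north, 4 west; corner margin keeps bushes off
  # the corners
  wall_len <- c(W, H, W, H)
  margin <- 1
  per_wall <- tabulate(rep_len(1:4, n), 4)
  lens <- stats::runif(n, lr[1], lr[2])
  wall_of <- rep_len(1:4, n)
  for (w in 1:4) {
    need <- sum(lens[wall_of == w]) + (per_wall[w] + 1) * 0.5 + 2 * margin
    if (need > wall_len[w])
      stop(sprintf("requested total bush length exceeds wall %d capacity", w))
  }
  bushes <- list()
  k <- 0
  for (w in 1:4) {
    idx <- which(wall_of == w)
    if (!length(idx)) next
    L <- wall_len[w] - 2 * margin
    used <- sum(lens[idx])
    min_gap <- 0.5
    gaps <- stats::rexp(length(idx) + 1)
    gaps <- min_gap + gaps / sum(gaps) * (L - used - min_gap * (length(idx) + 1))
    pos <- margin
    for (j in seq_along(idx)) {
      pos <- pos + gaps[j]
      s <- pos; e <- pos + lens[idx[j]]
      pos <- e
      d <- config$bush_depth
      ring <- switch(w,
        rbind(c(s, 0), c(e, 0), c(e, d), c(s, d)),              # south
        rbind(c(W, s), c(W, e), c(W - d, e), c(W - d, s)),      # east
        rbind(c(W - s, H), c(W - e, H), c(W - e, H - d), c(W - s, H - d)), # north
        rbind(c(0, H - s), c(0, H - e), c(d, H - e), c(d, H - s)))         # west
      k <- k + 1
      bushes[[as.character(k)]] <- ring
    }
  }
  fence <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H), c(0, 0))
  habitat_map(bushes, fence,
              crs_note = "synthetic local park metres, origin SW fence corner",
              fence_buffer = config$bush_depth + 2)
}

#' Mendelian offspring genotype
#'
#' At each locus the offspring receives one uniformly chosen allele from each
#' parent, independently across loci. A locus missing in a parent yields a
#' missing offspring locus.
#'
#' @param sire_gt,dam_gt 2 x L integer matrices of allele sizes (rows = the
#'   two allele copies, columns = loci); NA = missing
#' @return 2 x L integer matrix (row 1 paternal, row 2 maternal allele)
#' @export
mendelian_offspring <- function(sire_gt, dam_gt) {
  L <- ncol(sire_gt)
  stopifnot(ncol(dam_gt) == L)
  pick <- function(gt) gt[cbind(sample(1:2, L, replace = TRUE), seq_len(L))]
  off <- rbind(pick(sire_gt), pick(dam_gt))
  off[, is.na(sire_gt[1, ]) | is.na(dam_gt[1, ])] <- NA_integer_
  off
}

#' Apply per-allele genotyping error
#'
#' Each non-missing allele call is independently replaced with probability
#' `eps` by a uniformly drawn *different* allele from the locus's allele pool.
#'
#' @param gt 2 x L integer matrix of allele sizes
#' @param eps per-allele error probability
#' @param pools list of length L: allele-size pool per locus
#' @return 2 x L integer matrix
#' @export
apply_genotyping_error <- function(gt, eps, pools) {
  if (eps == 0) return(gt)
  for (l in seq_len(ncol(gt))) {
    pool <- pools[[l]]
    for (r in 1:2) {
      a <- gt[r, l]
      if (!is.na(a) && stats::runif(1) < eps) {
        alt <- pool[pool != a]
        if (length(alt)) gt[r, l] <- if (length(alt) == 1) alt else sample(alt, 1)
      }
    }
  }
  gt
}

# bushes whose polygon intersects the convex hull of the polygons of `bids`
# (touching counts: a single-bush range still covers abutting neighbours)
hull_cover <- function(habitat, bids) {
  if (length(bids) == 0) return(integer(0))
  hull <- if (length(bids) == 1) habitat$bushes[[as.character(bids)]]
          else convex_hull(do.call(rbind, habitat$bushes[as.character(bids)]))
  habitat$bush_ids[vapply(habitat$bushes, function(p)
    polygons_intersect(hull, p), logical(1))]
}

#' Simulate the park population and emit pipeline inputs plus ground truth
#'
#' Runs the seasonal individual-based model: growth, survival, recruitment
#' with sex-specific natal dispersal, heavyweight territory claims (largest
#' SVL wins simultaneous claims, ties broken by earlier id; incumbents keep
#' their bush for life), polygynous mating (resident heavyweight vs sneaker
#' lightweight sires) and capture sampling. All outputs are reproducible from
#' the seed.
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory; when given, writes `capture.csv`,
#'   `genotypes.gen`, `habitat.geojson`, `truth_pedigree.csv`,
#'   `truth_ranges.csv`
#' @return list: `captures` (validated data.frame), `genotypes`
#'   (`genotype_table`, with genotyping error applied), `habitat`, `truth`
#'   (list: `pedigree`, `natal`, `ranges`, `morph`, `genotypes` error-free),
#'   `config`
#' @export
simulate_population <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  habitat <- generate_habitat(config, seed = config$seed + 1)
  nb <- length(habitat$bush_ids)
  cents <- habitat$centroids

  # founder allele pools: symmetric Dirichlet(1) frequencies per locus
  L <- config$n_loci
  pools <- vector("list", L); pool_freqs <- vector("list", L)
  for (l in seq_len(L)) {
    K <- sample(seq(config$alleles_per_locus[1], config$alleles_per_locus[2]), 1)
    pools[[l]] <- as.integer(100 + 2 * (0:(K - 1)))
    g <- stats::rgamma(K, 1)
    pool_freqs[[l]] <- g / sum(g)
  }
  locus_names <- sprintf("LOC%02d", seq_len(L))

  # individual state, grown by append
  id <- character(0); sex <- character(0); svl <- numeric(0)
  alive <- logical(0); recruited <- logical(0); bush <- integer(0)
  natal <- integer(0); sire <- character(0); dam <- character(0)
  born <- integer(0); territory <- integer(0); avoids_sire <- logical(0)
  occ <- list()            # occupied bush set per individual
  G <- list()              # truth genotype, 2 x L matrix
  n_ind <- 0
  new_id <- function() sprintf("I%04d", n_ind)

  add_ind <- function(sx, sv, bu, na, si, da, bo, gt, av) {
    n_ind <<- n_ind + 1
    i <- n_ind
    id[i] <<- new_id(); sex[i] <<- sx; svl[i] <<- sv
    alive[i] <<- TRUE; recruited[i] <<- FALSE
    bush[i] <<- bu; natal[i] <<- na
    sire[i] <<- si; dam[i] <<- da; born[i] <<- bo
    territory[i] <<- NA_integer_; avoids_sire[i] <<- av
    occ[[i]] <<- integer(0); G[[i]] <<- gt
    i
  }

  # founders
  for (f in seq_len(config$founder_n)) {
    sx <- if (stats::runif(1) < 0.5) "M" else "F"
    sv <- stats::runif(1, config$recruit_svl["mean"],
                       if (sx == "M") config$growth$male["asym"] - 2
                       else config$growth$female["asym"] - 2)
    gt <- rbind(vapply(seq_len(L), function(l)
                  sample(pools[[l]], 1, prob = pool_freqs[[l]]), integer(1)),
                vapply(seq_len(L), function(l)
                  sample(pools[[l]], 1, prob = pool_freqs[[l]]), integer(1)))
    add_ind(sx, sv, NA_integer_, NA_integer_, NA_character_, NA_character_,
            0L, gt, FALSE)
  }
  alive <- alive[seq_len(n_ind)]; recruited[seq_len(n_ind)] <- TRUE
  # founder placement: random bushes
  bush[seq_len(n_ind)] <- sample(habitat$bush_ids, n_ind, replace = TRUE)

  seasons <- rep(c("spring", "fall"), length.out = config$n_cohorts)
  years <- config$start_year + (seq_len(config$n_cohorts) - 1) %/% 2

  cap_rows <- list()
  range_rows <- list()
  morph_rows <- list()
  pending <- integer(0)   # newborn indices awaiting recruitment

  grow <- function(i) {
    g <- if (sex[i] == "M") config$growth$male else config$growth$female
    inc <- max(0, stats::rnorm(1, g["mean"], g["sd"]))
    min(svl[i] + inc, g["asym"])
  }

  sons_bushes <- function(i) {
    ks <- which(sire == id[i] & sex == "M" & avoids_sire)
    # include the current bush of living recruited sons: within a season,
    # recruitment precedes territory claims but occupancy is recorded after
    cur <- ks[alive[ks] & recruited[ks]]
    unique(c(unlist(occ[ks]), bush[cur]))
  }

  claim_territory <- function(i) {
    holders <- which(alive & !is.na(territory))
    held <- territory[holders]
    free <- setdiff(habitat$bush_ids, held)
    if (!length(free)) return(invisible(NULL))   # floater
    # lifelong avoidance of the sire's range for dispersed sons
    if (avoids_sire[i] && !is.na(sire[i])) {
      si <- match(sire[i], id)
      free <- setdiff(free, hull_cover(habitat, occ[[si]]))
    }
    # a territorial male does not claim a bush that would pull a dispersed
    # son's bush inside his own range
    if (config$sire_range_avoidance) {
      sb <- sons_bushes(i)
      if (length(sb)) {
        ok <- vapply(free, function(b) {
          cov <- hull_cover(habitat, unique(c(occ[[i]], b)))
          !any(sb %in% cov)
        }, logical(1))
        free <- free[ok]
      }
    }
    if (!length(free)) return(invisible(NULL))
    if (length(held)) {
      # spacing: claim the free bush farthest from existing territories
      dmin <- vapply(free, function(b)
        min(sqrt(rowSums((cents[as.character(held), , drop = FALSE] -
                            matrix(cents[as.character(b), ],
                                   length(held), 2, byrow = TRUE))^2))),
        numeric(1))
      territory[i] <<- free[which.max(dmin)]
    } else {
      territory[i] <<- if (bush[i] %in% free) bush[i]
                       else free[sample.int(length(free), 1)]
    }
    bush[i] <<- territory[i]
    invisible(NULL)
  }

  for (t in seq_len(config$n_cohorts)) {
    if (t > 1) {
      # survival then growth of established individuals
      est <- which(alive & recruited)
      dead <- est[stats::runif(length(est)) > config$survival_prob]
      alive[dead] <- FALSE
      territory[dead] <- NA_integer_
      for (i in which(alive & recruited)) svl[i] <- grow(i)
      # recruitment of last season's newborns
      for (i in pending) {
        recruited[i] <- TRUE
        svl[i] <- max(25, stats::rnorm(1, config$recruit_svl["mean"],
                                       config$recruit_svl["sd"]))
        stay_p <- if (sex[i] == "F") config$p_female_philopatry
                  else config$p_male_natal_stay
        if (stats::runif(1) < stay_p) {
          bush[i] <- natal[i]
          avoids_sire[i] <- FALSE
        } else {
          choices <- setdiff(habitat$bush_ids, natal[i])
          if (sex[i] == "M" && config$sire_range_avoidance && !is.na(sire[i])) {
            si <- match(sire[i], id)
            choices <- setdiff(choices, hull_cover(habitat, occ[[si]]))
            avoids_sire[i] <- TRUE
          } else avoids_sire[i] <- FALSE
          if (!length(choices)) choices <- setdiff(habitat$bush_ids, natal[i])
          bush[i] <- choices[sample.int(length(choices), 1)]
        }
      }
      pending <- integer(0)
      # settled females range: occasional shift to a random bush
      fem <- which(alive & recruited & sex == "F")
      mv <- fem[stats::runif(length(fem)) < config$p_female_move]
      if (length(mv)) bush[mv] <- sample(habitat$bush_ids, length(mv), replace = TRUE)
    }
    cur <- which(alive & recruited)
    if (!length(cur)) stop(sprintf("population extinct before cohort %d", t))

    # heavyweight territory claims, largest SVL first, ties by earlier id
    claimants <- cur[sex[cur] == "M" & svl[cur] >= 64 & is.na(territory[cur])]
    claimants <- claimants[order(-svl[claimants], id[claimants])]
    for (i in claimants) claim_territory(i)

    # record occupancy (truth ranges, morphs)
    cur <- which(alive & recruited)
    for (i in cur) occ[[i]] <- unique(c(occ[[i]], bush[i]))
    lab <- cohort_label(years[t], seasons[t])
    range_rows[[t]] <- data.frame(id = id[cur], cohort = lab, bush_id = bush[cur],
                                  stringsAsFactors = FALSE)
    morph_rows[[t]] <- data.frame(
      id = id[cur], cohort = lab, svl = svl[cur], sex = sex[cur],
      morph = ifelse(sex[cur] == "M", classify_morph(pmax(svl[cur], 1)), NA),
      territory = territory[cur], stringsAsFactors = FALSE)

    # capture sampling
    capt <- cur[stats::runif(length(cur)) < config$capture_prob]
    if (length(capt)) {
      mass <- round(2.2e-5 * svl[capt]^2.95 *
                      exp(stats::rnorm(length(capt), 0, 0.08)), 2)
      cap_rows[[t]] <- data.frame(
        id = id[capt], year = years[t], season = seasons[t], sex = sex[capt],
        svl_mm = round(pmin(svl[capt], 80), 2), mass_g = mass,
        bush_id = bush[capt], stringsAsFactors = FALSE)
    }

    # mating (not in the final season: those young would never recruit)
    if (t < config$n_cohorts) {
      males <- cur[sex[cur] == "M" & svl[cur] >= config$maturity_svl]
      lw_males <- males[svl[males] < 64]
      res_of_bush <- rep(NA_integer_, nb)
      hw <- cur[!is.na(territory[cur])]
      res_of_bush[territory[hw]] <- hw
      females <- cur[sex[cur] == "F" & svl[cur] >= config$maturity_svl]
      for (f in females) {
        noff <- stats::rpois(1, config$fecundity)
        if (noff == 0 || !length(males)) next
        for (o in seq_len(noff)) {
          res <- res_of_bush[bush[f]]
          s <- if (!is.na(res) && stats::runif(1) < config$p_resident_sire) res
               else if (length(lw_males)) lw_males[sample.int(length(lw_males), 1)]
               else males[sample.int(length(males), 1)]
          gt <- mendelian_offspring(G[[s]], G[[f]])
          j <- add_ind(if (stats::runif(1) < 0.5) "M" else "F",
                       config$recruit_svl["mean"], bush[f], bush[f],
                       id[s], id[f], t, gt, FALSE)
          alive[j] <- TRUE
          pending <- c(pending, j)
        }
      }
    }
  }

  captures <- validate_captures(do.call(rbind, cap_rows), habitat)
  cap_ids <- unique(captures$id)

  # observed genotypes for captured individuals: genotyping error + missing
  ord <- order(cap_ids)
  cap_ids <- cap_ids[ord]
  idx <- match(cap_ids, id)
  a1 <- matrix(NA_integer_, length(cap_ids), L)
  a2 <- matrix(NA_integer_, length(cap_ids), L)
  t1 <- a1; t2 <- a2
  for (r in seq_along(idx)) {
    gt <- G[[idx[r]]]
    t1[r, ] <- gt[1, ]; t2[r, ] <- gt[2, ]
    gt <- apply_genotyping_error(gt, config$genotyping_error, pools)
    drop <- stats::runif(L) < config$missing_rate
    gt[, drop] <- NA_integer_
    a1[r, ] <- gt[1, ]; a2[r, ] <- gt[2, ]
  }
  genotypes <- genotype_table(cap_ids, locus_names, a1, a2)
  truth_genotypes <- genotype_table(cap_ids, locus_names, t1, t2)

  first_seen <- tapply(cohort_index(captures$cohort), captures$id, min)
  truth_ped <- data.frame(id = id[seq_len(n_ind)], sire = sire[seq_len(n_ind)],
                          dam = dam[seq_len(n_ind)], stringsAsFactors = FALSE)
  truth <- list(
    pedigree = truth_ped[truth_ped$id %in% cap_ids, ],
    pedigree_all = truth_ped,
    natal = data.frame(id = id[seq_len(n_ind)], natal_bush = natal[seq_len(n_ind)],
                       stringsAsFactors = FALSE),
    ranges = do.call(rbind, range_rows),
    morph = do.call(rbind, morph_rows),
    genotypes = truth_genotypes,
    founder_pools = lapply(seq_len(L), function(l)
      stats::setNames(pool_freqs[[l]], pools[[l]])))

  out <- list(captures = captures, genotypes = genotypes, habitat = habitat,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_capture_table(captures, file.path(out_dir, "capture.csv"))
    write_genotypes(genotypes, file.path(out_dir, "genotypes.gen"))
    write_habitat_geojson(habitat, file.path(out_dir, "habitat.geojson"))
    utils::write.csv(truth$pedigree, file.path(out_dir, "truth_pedigree.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(truth$ranges, file.path(out_dir, "truth_ranges.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}
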