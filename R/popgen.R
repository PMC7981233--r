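# Population-genetic statistics: locus summaries, Monte-Carlo exact HWE
# tests, genotypic linkage-disequilibrium permutation tests, Holm-Bonferroni
# correction, Loiselle pairwise kinship, distance-class spatial
# autocorrelograms and Mantel isolation-by-distance tests.

#' Per-locus genotype summaries
#'
#' Allele frequencies by gene counting over non-missing calls, observed
#' heterozygosity Ho (fraction of heterozygous individuals) and Nei's
#' unbiased expected heterozygosity He = (2n/(2n-1)) (1 - sum p^2) with n the
#' number of genotyped individuals.
#'
#' @param gt a `genotype_table`
#' @return data.frame with columns locus, n, n_alleles, Ho, He; per-locus
#'   allele frequencies in attribute `"freqs"`
#' @export
locus_summaries <- function(gt) {
  fr <- allele_freqs(gt)
  out <- data.frame(locus = gt$loci, n = NA_integer_, n_alleles = NA_integer_,
                    Ho = NA_real_, He = NA_real_, stringsAsFactors = FALSE)
  for (l in seq_along(gt$loci)) {
    ok <- !is.na(gt$a1[, l])
    n <- sum(ok)
    if (n < 2) stop("fewer than 2 genotyped individuals at locus ", gt$loci[l])
    p <- fr[[l]]
    out$n[l] <- n
    out$n_alleles[l] <- length(p)
    out$Ho[l] <- mean(gt$a1[ok, l] != gt$a2[ok, l])
    out$He[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    if (length(p) == 1)
      warning("monomorphic locus ", gt$loci[l])
  }
  attr(out, "freqs") <- fr
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Permutation-null exact test: alleles are pooled and randomly re-paired
#' into genotypes; the p-value is the proportion of pairings whose
#' conditional probability (given the allele counts) is as small as or
#' smaller than the observed configuration's, with a +1 correction.
#'
#' @param a1,a2 integer allele vectors for one locus (one entry per
#'   individual); NA pairs dropped
#' @param n_mc number of Monte-Carlo pairings (default 999)
#' @return list: `p`, `n`, `n_mc`
#' @export
hwe_exact_test <- function(a1, a2, n_mc = 999) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0) stop("all calls missing at locus")
  if (length(unique(c(a1, a2))) < 2) stop("monomorphic locus")
  # log conditional probability of a genotype configuration, up to terms
  # fixed by the allele counts: h log 2 - sum log n_g!
  logstat <- function(x, y) {
    g <- paste(pmin(x, y), pmax(x, y))
    tab <- table(g)
    h <- sum(x != y)
    h * log(2) - sum(lgamma(as.numeric(tab) + 1))
  }
  obs <- logstat(a1, a2)
  pool <- c(a1, a2)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(pool)
    s <- logstat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (s <= obs + 1e-9) hits <- hits + 1L
  }
  list(p = (hits + 1) / (n_mc + 1), n = n, n_mc = n_mc)
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests association between the genotypes at two loci with the G statistic
#' of the two-locus genotype contingency table; the null distribution is
#' built by permuting one locus's genotypes across individuals.
#'
#' @param gt a `genotype_table`
#' @param locus_i,locus_j locus names or indices
#' @param n_perm number of permutations (default 999)
#' @param min_shared minimum individuals genotyped at both loci
#' @return list: `p`, `G`, `n`, or a flagged skip when too few shared
#'   individuals
#' @export
ld_permutation_test <- function(gt, locus_i, locus_j, n_perm = 999,
                                min_shared = 10) {
  li <- if (is.character(locus_i)) match(locus_i, gt$loci) else locus_i
  lj <- if (is.character(locus_j)) match(locus_j, gt$loci) else locus_j
  ok <- !is.na(gt$a1[, li]) & !is.na(gt$a1[, lj])
  if (sum(ok) < min_shared)
    return(list(p = NA_real_, G = NA_real_, n = sum(ok), skipped = TRUE))
  g1 <- paste(gt$a1[ok, li], gt$a2[ok, li])
  g2 <- paste(gt$a1[ok, lj], gt$a2[ok, lj])
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.numeric(tab); e <- as.numeric(e)
    2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
  }
  obs <- gstat(g1, g2)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (gstat(g1, sample(g2)) >= obs - 1e-9) hits <- hits + 1L
  list(p = (hits + 1) / (n_perm + 1), G = obs, n = sum(ok), skipped = FALSE)
}

#' Holm-Bonferroni sequential correction
#'
#' Sorts p-values ascending and rejects p_(i) while p_(i) <= alpha/(m-i+1).
#' For the eight-locus HWE battery the conventional starting threshold
#' alpha/m of 0.0065 corresponds to `initial_alpha = 0.0065`.
#'
#' @param p_values numeric vector in `[0, 1]`
#' @param alpha family-wise alpha (default 0.05)
#' @param initial_alpha optional starting threshold alpha/m; when given it
#'   overrides `alpha` via alpha = initial_alpha * m
#' @return logical rejection flags in the input order
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05, initial_alpha = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0) return(logical(0))
  if (!is.null(initial_alpha)) alpha <- initial_alpha * m
  ord <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

#' Loiselle pairwise kinship matrix
#'
#' Multilocus kinship estimator of Loiselle et al. (1995): for a dyad (i, j),
#' k = sum over loci and alleles of
#' (p_ia - p_a)(p_ja - p_a) + p_a(1 - p_a)/(n_l - 1), divided by the summed
#' p_a(1 - p_a), where p_ia is individual i's allele-a dosage/2, p_a the
#' reference allele frequency and n_l the number of gene copies sampled at
#' locus l in the reference. Loci missing in either member of a dyad are
#' excluded from both numerator and denominator for that dyad.
#'
#' @param gt a `genotype_table`
#' @param reference_ids individuals defining the allele-frequency baseline
#'   (default: all); at least 10
#' @param ids individuals to include in the matrix (default: all)
#' @return symmetric kinship matrix with NA diagonal and attribute
#'   `"reference"`
#' @export
loiselle_kinship <- function(gt, reference_ids = NULL, ids = NULL) {
  if (is.null(reference_ids)) reference_ids <- gt$ids
  if (is.null(ids)) ids <- gt$ids
  if (length(reference_ids) < 10) stop("reference set must have >= 10 individuals")
  fr <- allele_freqs(gt, reference_ids)
  rows <- match(ids, gt$ids)
  if (anyNA(rows)) stop("unknown individual id(s)")
  n <- length(ids)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (l in seq_along(gt$loci)) {
    p <- fr[[l]]
    alleles <- as.integer(names(p))
    ng <- attr(p, "n_genes")
    if (ng < 2 || length(p) < 2) next
    a1 <- gt$a1[rows, l]; a2 <- gt$a2[rows, l]
    obs <- as.numeric(!is.na(a1))
    # dosage matrix (n x K), zero rows for missing
    D <- (outer(a1, alleles, "==") + outer(a2, alleles, "==")) / 2
    D[is.na(D)] <- 0
    Dc <- sweep(D, 2, p)
    Dc[obs == 0, ] <- 0
    w <- sum(p * (1 - p))
    corr <- w / (ng - 1)
    oo <- outer(obs, obs)
    num <- num + Dc %*% t(Dc) + corr * oo
    den <- den + w * oo
  }
  k <- num / den
  k[den == 0] <- NA
  diag(k) <- NA
  dimnames(k) <- list(ids, ids)
  attr(k, "reference") <- reference_ids
  k
}

#' Distance-class spatial autocorrelogram of kinship
#'
#' Partitions the pairwise distances into equal-frequency (quantile) classes,
#' computes the mean kinship per class, and builds a permutation envelope by
#' shuffling individuals among the occupied spatial positions.
#'
#' @param kinship symmetric kinship matrix (NA diagonal)
#' @param dmat symmetric distance matrix over the same ids
#' @param n_classes number of distance classes (default 5, reduced with a
#'   warning when there are fewer dyads than classes)
#' @param n_perm number of permutations for the envelope (default 999)
#' @param envelope two-sided envelope quantiles
#' @return data.frame of class `autocorrelogram`: class, lower, upper,
#'   mean_k, env_lo, env_hi, n_pairs, significant
#' @export
autocorrelogram <- function(kinship, dmat, n_classes = 5, n_perm = 999,
                            envelope = c(0.025, 0.975)) {
  ids <- rownames(kinship)
  stopifnot(identical(dim(kinship), dim(dmat)))
  dmat <- dmat[ids, ids]
  n <- nrow(kinship)
  ut <- upper.tri(kinship)
  ok <- ut & !is.na(kinship)
  dv <- dmat[ok]; kv <- kinship[ok]
  n_dyads <- length(dv)
  if (n_dyads < n_classes) {
    warning("fewer dyads than classes; reducing class count")
    n_classes <- max(1, n_dyads)
  }
  qs <- stats::quantile(dv, probs = seq(0, 1, length.out = n_classes + 1))
  qs[1] <- qs[1] - 1e-9
  cls <- cut(dv, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  n_classes <- max(cls)
  mean_k <- tapply(kv, cls, mean)
  n_pairs <- tabulate(cls, n_classes)
  perm_means <- matrix(NA_real_, n_perm, n_classes)
  for (b in seq_len(n_perm)) {
    pm <- sample(n)
    kp <- kinship[pm, pm][ok]
    perm_means[b, ] <- tapply(kp, cls, mean)
  }
  env_lo <- apply(perm_means, 2, stats::quantile, probs = envelope[1], na.rm = TRUE)
  env_hi <- apply(perm_means, 2, stats::quantile, probs = envelope[2], na.rm = TRUE)
  out <- data.frame(
    class = seq_len(n_classes),
    lower = utils::head(unique(qs), n_classes),
    upper = utils::tail(unique(qs), n_classes),
    mean_k = as.numeric(mean_k),
    env_lo = env_lo, env_hi = env_hi,
    n_pairs = n_pairs)
  out$significant <- out$mean_k < out$env_lo | out$mean_k > out$env_hi
  class(out) <- c("autocorrelogram", "data.frame")
  out
}

#' Mantel test of association between two distance/similarity matrices
#'
#' r is the Pearson correlation of the off-diagonal elements; the p-value is
#' the one-tailed proportion of joint row/column permutations with r at least
#' as large as observed, with a +1 correction in numerator and denominator.
#'
#' @param matrix_a,matrix_b symmetric matrices over the same ids with zero
#'   (or NA) diagonal
#' @param n_perm number of permutations (default 999)
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `n`
#' @export
mantel_test <- function(matrix_a, matrix_b, n_perm = 999) {
  stopifnot(identical(dim(matrix_a), dim(matrix_b)))
  n <- nrow(matrix_a)
  ok <- upper.tri(matrix_a) & !is.na(matrix_a) & !is.na(matrix_b)
  # symmetrise the mask so permuted extractions stay aligned
  av <- matrix_a[ok]; bv <- matrix_b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm, n = n,
                          flagged = "constant matrix"), class = "mantel_result"))
  r_obs <- stats::cor(av, bv)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    pm <- sample(n)
    bp <- matrix_b[pm, pm][ok]
    if (stats::cor(av, bp, use = "complete.obs") >= r_obs - 1e-12)
      hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, n = n, flagged = NULL),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4f (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Relatedness of a heavyweight male to its neighbours vs the population
#'
#' Neighbours are the other males of the cohort captured in any bush whose
#' polygon intersects the focal male's home-range polygon. Returns the mean
#' kinship to neighbours, to all non-neighbour cohort males, and their
#' difference.
#'
#' @param focal_id focal heavyweight male id
#' @param cohort_captures capture records of the cohort's males
#' @param kinship kinship matrix covering the males
#' @param hr_focal the focal male's `home_range`
#' @param habitat a `habitat_map`
#' @return list: `id`, `neighbours`, `mean_k_neighbour`, `mean_k_population`,
#'   `difference`, `flagged` (TRUE when no neighbour)
#' @export
neighbor_relatedness_contrast <- function(focal_id, cohort_captures, kinship,
                                          hr_focal, habitat) {
  males <- setdiff(unique(cohort_captures$id), focal_id)
  males <- intersect(males, rownames(kinship))
  inter <- habitat$bush_ids[vapply(habitat$bushes, function(p)
    polygons_intersect(hr_focal$polygon, p), logical(1))]
  nb <- unique(cohort_captures$id[cohort_captures$bush_id %in% inter])
  nb <- intersect(setdiff(nb, focal_id), males)
  rest <- setdiff(males, nb)
  mk <- function(set) if (length(set)) mean(kinship[focal_id, set], na.rm = TRUE)
                      else NA_real_
  list(id = focal_id, neighbours = nb,
       mean_k_neighbour = mk(nb), mean_k_population = mk(rest),
       difference = if (length(nb)) mk(nb) - mk(rest) else NA_real_,
       flagged = length(nb) == 0)
}

#' Cohort-level neighbour-relatedness test for heavyweight males
#'
#' Computes per-focal neighbour-vs-population kinship differences across
#' heavyweight males and tests whether the mean difference departs from zero,
#' with both a Welch/one-sample t-test (reported for comparability) and a
#' label-permutation test (recommended: dyadic kinship values are not
#' independent).
#'
#' @param captures cohort male capture records
#' @param kinship kinship matrix
#' @param ranges list of `home_range` objects named by id
#' @param habitat a `habitat_map`
#' @param n_perm permutations for the permutation test
#' @return list: per-focal `records`, `t_test`, `perm_p`, `mean_difference`
#' @export
heavyweight_neighbor_test <- function(captures, kinship, ranges, habitat,
                                      n_perm = 999) {
  hw <- unique(captures$id[classify_morph(captures$svl_mm) == "heavyweight" &
                             captures$sex == "M"])
  hw <- intersect(hw, rownames(kinship))
  recs <- lapply(hw, function(f)
    neighbor_relatedness_contrast(f, captures[captures$sex == "M", ], kinship,
                                  ranges[[f]], habitat))
  diffs <- vapply(recs, function(r) r$difference %||% NA_real_, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2)
    return(list(records = recs, t_test = NULL, perm_p = NA_real_,
                mean_difference = mean(diffs)))
  tt <- stats::t.test(diffs)
  # permutation: shuffle neighbour labels within each focal's male set
  obs <- mean(diffs)
  males_all <- rownames(kinship)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pd <- vapply(recs, function(r) {
      if (r$flagged) return(NA_real_)
      others <- setdiff(males_all, r$id)
      nb <- sample(others, length(r$neighbours))
      mean(kinship[r$id, nb], na.rm = TRUE) -
        mean(kinship[r$id, setdiff(others, nb)], na.rm = TRUE)
    }, numeric(1))
    if (mean(abs(mean(pd, na.rm = TRUE))) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(records = recs, t_test = tt, perm_p = (hits + 1) / (n_perm + 1),
       mean_difference = obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
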