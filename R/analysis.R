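# Hypothesis-level analyses: H1 home range ~ sex, H2 size-range correlation,
# H3 size-morph spatial distancing, H4 parent-offspring home-range
# inheritance, and the end-to-end driver.

#' H1: linear model of log home-range area on sex
#'
#' @param range_summary the `"summary"` data.frame from [home_ranges()]
#' @return list: `model`, `F`, `df`, `p`, `means` (per-sex raw-scale mean
#'   area), `n`
#' @export
h1_home_range_by_sex <- function(range_summary) {
  if (length(unique(range_summary$sex)) < 2)
    stop("need home ranges for both sexes")
  if (stats::sd(range_summary$log_area) == 0)
    return(list(model = NULL, F = 0, df = c(1, nrow(range_summary) - 2), p = 1,
                means = tapply(range_summary$area, range_summary$sex, mean),
                n = table(range_summary$sex), flagged = "constant areas"))
  m <- stats::lm(log_area ~ sex, data = range_summary)
  a <- stats::anova(m)
  list(model = m, F = a$`F value`[1], df = a$Df, p = a$`Pr(>F)`[1],
       means = tapply(range_summary$area, range_summary$sex, mean),
       n = table(range_summary$sex))
}

#' H2: Pearson correlation of log home-range area with body size
#'
#' SVL is the individual's maximum recorded snout-vent length.
#'
#' @param range_summary the `"summary"` from [home_ranges()]
#' @param captures validated capture table
#' @param subset "all", "male" or "female"
#' @return list: `r`, `p`, `n`, `subset`, `flagged`
#' @export
h2_size_range_correlation <- function(range_summary, captures,
                                      subset = c("all", "male", "female")) {
  subset <- match.arg(subset)
  df <- range_summary
  if (subset != "all")
    df <- df[df$sex == if (subset == "male") "M" else "F", ]
  svl <- vapply(df$id, function(i) max(captures$svl_mm[captures$id == i]),
                numeric(1))
  if (nrow(df) < 3 || stats::sd(svl) == 0 || stats::sd(df$log_area) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(df), subset = subset,
                flagged = TRUE))
  ct <- stats::cor.test(df$log_area, svl)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df), subset = subset,
       flagged = FALSE)
}

#' Per-male average-distance table by size-class pair
#'
#' For every cohort male, d' to the other males of its own morph (LW-LW or
#' HW-HW) and, for lightweights, d' to the cohort's heavyweights (LW-HW).
#'
#' @param captures validated capture table
#' @param dmat bush distance matrix
#' @return data.frame: cohort, id, pair_class, d_prime, n_males (cohort male
#'   count), density
#' @export
distancing_table <- function(captures, dmat) {
  males <- captures[captures$sex == "M", ]
  rows <- list()
  for (lab in unique(males$cohort)) {
    cm <- males[males$cohort == lab, ]
    if (nrow(cm) < 2) next
    bush <- stats::setNames(cm$bush_id, cm$id)
    morph <- stats::setNames(classify_morph(cm$svl_mm), cm$id)
    for (cls in c("LW-LW", "HW-HW", "LW-HW")) {
      foc_m <- if (cls == "HW-HW") "heavyweight" else "lightweight"
      oth_m <- if (cls == "LW-LW") "lightweight" else "heavyweight"
      focals <- names(morph)[morph == foc_m]
      others_all <- names(morph)[morph == oth_m]
      for (f in focals) {
        others <- setdiff(others_all, f)
        if (!length(others)) next
        dv <- vapply(others, function(o)
          dmat[as.character(bush[[f]]), as.character(bush[[o]])], numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          cohort = lab, id = f, pair_class = cls,
          d_prime = mean(dv), n_males = nrow(cm),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$density <- out$n_males
  out
}

#' H3: size-morph spatial distancing analyses
#'
#' Whole-dataset linear model of d' on size-class pair and cohort (a male
#' density covariate is retained only when a partial-F test improves the
#' model), per-cohort pairwise Wilcoxon tests with Holm correction, and
#' Mantel tests of pairwise SVL difference against geographic distance
#' (overall and within morphs).
#'
#' @param captures validated capture table
#' @param dmat bush distance matrix
#' @param n_perm Mantel permutations
#' @param alpha level for the density partial-F decision
#' @return list: `table`, `model`, `density_partial_F`, `per_cohort_wilcox`,
#'   `mantel` (list all/heavyweight/lightweight), `flagged`
#' @export
h3_distancing <- function(captures, dmat, n_perm = 999, alpha = 0.05) {
  tab <- distancing_table(captures, dmat)
  if (is.null(tab) || stats::sd(tab$d_prime) == 0)
    return(list(table = tab, model = NULL, flagged = "degenerate distances"))
  tab$pair_class <- factor(tab$pair_class, levels = c("LW-LW", "HW-HW", "LW-HW"))
  m0 <- stats::lm(d_prime ~ pair_class + cohort, data = tab)
  m1 <- stats::lm(d_prime ~ pair_class + cohort + density, data = tab)
  pf <- stats::anova(m0, m1)
  use_density <- !is.na(pf$`Pr(>F)`[2]) && pf$`Pr(>F)`[2] < alpha
  model <- if (use_density) m1 else m0
  wil <- lapply(split(tab, tab$cohort), function(ct) {
    if (length(unique(ct$pair_class)) < 2) return(NULL)
    stats::pairwise.wilcox.test(ct$d_prime, droplevels(ct$pair_class),
                                p.adjust.method = "holm", exact = FALSE)
  })
  mantel <- list()
  for (sub in c("all", "heavyweight", "lightweight")) {
    ms <- mantel_svl_distance(captures, dmat, sub, n_perm = n_perm)
    mantel[[sub]] <- ms
  }
  list(table = tab, model = model, density_partial_F = pf,
       density_used = use_density, per_cohort_wilcox = wil, mantel = mantel,
       flagged = NULL)
}

# Mantel test of |delta SVL| vs distance over males pooled across cohorts
# (per-individual maximum SVL and modal capture bush)
mantel_svl_distance <- function(captures, dmat, subset = "all", n_perm = 999) {
  males <- captures[captures$sex == "M", ]
  if (subset != "all") {
    keep_morph <- if (subset == "heavyweight") "heavyweight" else "lightweight"
    # classify by the individual's maximum SVL
    msvl <- tapply(males$svl_mm, males$id, max)
    ids <- names(msvl)[classify_morph(as.numeric(msvl)) == keep_morph]
    males <- males[males$id %in% ids, ]
  }
  if (length(unique(males$id)) < 4) return(NULL)
  ids <- unique(males$id)
  svl <- vapply(ids, function(i) max(males$svl_mm[males$id == i]), numeric(1))
  modal_bush <- vapply(ids, function(i) {
    b <- males$bush_id[males$id == i]
    as.integer(names(sort(table(b), decreasing = TRUE))[1])
  }, integer(1))
  dd <- dmat[as.character(modal_bush), as.character(modal_bush)]
  dimnames(dd) <- list(ids, ids)
  sv <- abs(outer(svl, svl, "-"))
  dimnames(sv) <- list(ids, ids)
  diag(dd) <- 0; diag(sv) <- 0
  mantel_test(sv, dd, n_perm = n_perm)
}

#' Yates continuity-corrected chi-square statistic for a 2x2 table
#'
#' The classical correction: sum over cells of (|O - E| - 0.5)^2 / E.
#'
#' @param tab 2x2 matrix of counts
#' @return list: `statistic`, `df`, `p`
#' @export
yates_chisq <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - e) - 0.5)^2 / e)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' H4: parent-offspring home-range inheritance
#'
#' For every assigned parent with a defined home range, classifies each of
#' its captured offspring as inside or outside the parent's range (inside
#' iff any offspring capture bush polygon intersects the parent's home-range
#' polygon). Reports per parent-role x offspring-sex percentages (counted
#' per offspring, and also averaged per parent), and for each role the
#' inside/outside x offspring-sex 2x2 Yates-corrected chi-square; Fisher's
#' exact test is added as a robustness check when any expected cell is
#' below 5.
#'
#' @param pedigree pedigree links (long form)
#' @param ranges list of `home_range` objects named by id
#' @param captures validated capture table
#' @param habitat a `habitat_map`
#' @return list with `records`, per-role `tables`, `percent`,
#'   `percent_per_parent`, `chisq`, `fisher`
#' @export
h4_inheritance <- function(pedigree, ranges, captures, habitat) {
  sex_of <- stats::setNames(captures$sex, captures$id)
  recs <- list()
  for (r in seq_len(nrow(pedigree))) {
    par <- pedigree$parent_id[r]; off <- pedigree$offspring_id[r]
    hr <- ranges[[par]]
    if (is.null(hr)) next
    ob <- unique(captures$bush_id[captures$id == off])
    if (!length(ob)) next
    inside <- any(vapply(as.character(ob), function(b)
      polygons_intersect(habitat$bushes[[b]], hr$polygon), logical(1)))
    recs[[length(recs) + 1]] <- data.frame(
      offspring_id = off, parent_id = par,
      parent_role = pedigree$parent_role[r],
      offspring_sex = unname(sex_of[off]),
      inside_parent_range = inside, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(list(records = NULL, evaluable = FALSE))
  records <- do.call(rbind, recs)
  out <- list(records = records, evaluable = TRUE, tables = list(),
              percent = list(), percent_per_parent = list(), chisq = list(),
              fisher = list())
  for (role in c("sire", "dam")) {
    rr <- records[records$parent_role == role, ]
    if (!nrow(rr)) next
    tab <- table(factor(rr$inside_parent_range, levels = c(TRUE, FALSE)),
                 factor(rr$offspring_sex, levels = c("F", "M")))
    out$tables[[role]] <- tab
    out$percent[[role]] <- 100 * prop.table(tab, margin = 2)[1, ]
    ppp <- tapply(rr$inside_parent_range,
                  list(rr$parent_id, rr$offspring_sex), mean)
    out$percent_per_parent[[role]] <- 100 * colMeans(ppp, na.rm = TRUE)
    if (all(dim(tab) == c(2, 2)) && all(colSums(tab) > 0) && sum(tab) > 0 &&
        all(rowSums(tab) >= 0) && any(tab > 0)) {
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (all(is.finite(e)) && all(e > 0)) {
        out$chisq[[role]] <- yates_chisq(unclass(tab))
        if (any(e < 5))
          out$fisher[[role]] <- stats::fisher.test(tab)
      } else out$chisq[[role]] <- list(statistic = NA, df = 1L, p = NA,
                                       note = "not evaluable")
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' QC -> spatial -> population genetics -> parentage -> the four hypothesis
#' tests, with logged seeds. Stages whose inputs are unavailable are marked
#' skipped; spatial hypotheses (H1, H2) only need captures and habitat.
#'
#' @param captures validated capture table
#' @param habitat a `habitat_map`
#' @param genotypes optional `genotype_table` (NULL skips popgen, parentage
#'   and H4 unless `pedigree` is supplied)
#' @param pedigree optional known pedigree links (e.g. a truth pedigree);
#'   when NULL and genotypes are present, the sequential consensus pedigree
#'   is inferred
#' @param metric bush distance metric
#' @param parentage a [parentage_config()]
#' @param seeds replicate seeds for parentage
#' @param n_perm permutation count for Mantel/envelope tests
#' @param hwe_mc Monte-Carlo draws for HWE tests
#' @return list of class `analysis_report`
#' @export
run_all <- function(captures, habitat, genotypes = NULL, pedigree = NULL,
                    metric = "perimeter",
                    parentage = parentage_config(),
                    seeds = seq_len(parentage$n_replicates),
                    n_perm = 199, hwe_mc = 999) {
  report <- list(provenance = list(seeds = seeds, metric = metric,
                                   n_perm = n_perm, timestamp = NA),
                 stages = list())
  set.seed(seeds[1])  # all Monte-Carlo stages draw from one seeded stream
  dmat <- bush_distance_matrix(habitat, metric = metric)
  hrs <- home_ranges(captures, habitat)
  smry <- attr(hrs, "summary")
  report$ranges <- smry
  report$h1 <- tryCatch(h1_home_range_by_sex(smry),
                        error = function(e) list(error = conditionMessage(e)))
  report$h2 <- lapply(c(all = "all", male = "male", female = "female"),
                      function(s) h2_size_range_correlation(smry, captures, s))
  report$h3 <- h3_distancing(captures, dmat, n_perm = n_perm)
  report$stages$spatial <- "ok"

  if (!is.null(genotypes)) {
    gtf <- filter_genotypes(genotypes)
    qc <- locus_summaries(gtf)
    qc$hwe_p <- vapply(seq_along(gtf$loci), function(l)
      hwe_exact_test(gtf$a1[, l], gtf$a2[, l], n_mc = hwe_mc)$p, numeric(1))
    qc$hwe_reject <- holm_bonferroni(qc$hwe_p, initial_alpha = 0.0065)
    report$qc <- qc
    kin <- loiselle_kinship(gtf)
    report$kinship_mean <- mean(kin[upper.tri(kin)], na.rm = TRUE)
    # within-cohort male IBD Mantel tests
    ibd <- list()
    for (lab in names(cohort_members(captures))) {
      cm <- captures[captures$cohort == lab & captures$sex == "M", ]
      ids <- intersect(unique(cm$id), rownames(kin))
      if (length(ids) < 5) next
      bb <- as.character(vapply(ids, function(i) cm$bush_id[cm$id == i][1],
                                numeric(1)))
      dd <- dmat[bb, bb]; dimnames(dd) <- list(ids, ids)
      kk <- kin[ids, ids]
      diag(kk) <- 0
      ibd[[lab]] <- mantel_test(kk, dd, n_perm = n_perm)
    }
    report$ibd_mantel <- ibd
    report$stages$popgen <- "ok"

    if (is.null(pedigree)) {
      pedigree <- sequential_pedigree(captures, gtf, parentage, seeds)
      report$inbreeding <- inbreeding_trajectory(attr(pedigree, "steps"))
    } else {
      report$inbreeding <- NULL
    }
    report$pedigree <- pedigree
    report$stages$pedigree <- "ok"
  } else if (is.null(pedigree)) {
    report$stages$popgen <- "skipped (no genotypes)"
    report$stages$pedigree <- "skipped (no genotypes)"
  }

  if (!is.null(pedigree)) {
    report$h4 <- h4_inheritance(pedigree, hrs, captures, habitat)
    report$stages$h4 <- "ok"
  } else {
    report$stages$h4 <- "skipped (no pedigree)"
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  cat(" stages:", paste(names(x$stages), unlist(x$stages), sep = "=",
                        collapse = ", "), "\n")
  if (!is.null(x$h1$F))
    cat(sprintf(" H1 log(area)~sex: F(%d,%d) = %.3f, p = %.4f\n",
                x$h1$df[1], x$h1$df[2], x$h1$F, x$h1$p))
  if (!is.null(x$h4$percent$sire))
    cat(sprintf(" H4 %% offspring inside sire range: F %.1f%%, M %.1f%%\n",
                x$h4$percent$sire["F"], x$h4$percent$sire["M"]))
  invisible(x)
}
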