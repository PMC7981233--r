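# Likelihood-based parentage assignment with genotyping error, run under the
# sequential cohort-stacking, replicate-consensus procedure. The engine is a
# trio/pairwise categorical-allocation likelihood: Mendelian transmission with
# independent per-allele mistyping of the offspring's observed alleles at rate
# eps; an unsampled parent contributes population allele frequencies.
#
# Per locus the trio likelihood factorises. With observed offspring alleles
# (u, v) and e(a|b) = 1-eps if a == b else eps/(K-1):
#   a_P(u) = mean over parent P's two alleles b of e(u|b)
#   L(obs | S, D) = a_S(u) a_D(v) + a_S(v) a_D(u)   (u != v)
#                 = a_S(u) a_D(u)                   (u == v)
# replacing a_P by a_pop(u) = sum_b p_b e(u|b) when a parent is unsampled.
# This is the exact sum over transmitted alleles and error events.

#' Parentage-engine configuration
#'
#' @param error_rate per-allele genotyping error rate eps (default 0.01)
#' @param p_parent_sampled prior probability that an offspring's true parent
#'   is among the candidate genotypes (default 0.5)
#' @param min_alpha retention threshold: a parent link is kept only when the
#'   posterior probability that no sampled parent of that role exists falls
#'   below this value (default 0.05, the "p-value less than 0.05" retention
#'   rule)
#' @param n_replicates number of replicate runs (default 3)
#' @param replicate_perturb fraction of genotype calls re-masked at random in
#'   each replicate run (default equal to the assumed genotyping-error rate),
#'   so that the consensus keeps only links that do not hinge on a handful of
#'   possibly erroneous calls; 0 makes the engine fully deterministic and the
#'   replicates identical
#' @param max_missing offspring missing more than this fraction of loci are
#'   skipped
#' @param shortlist number of top single-parent candidates per role carried
#'   into the trio evaluation
#' @return list of class `parentage_config`
#' @export
parentage_config <- function(error_rate = 0.01, p_parent_sampled = 0.5,
                             min_alpha = 0.05, n_replicates = 3,
                             replicate_perturb = error_rate, max_missing = 0.5,
                             shortlist = 20) {
  stopifnot(error_rate >= 0, error_rate < 1,
            p_parent_sampled >= 0, p_parent_sampled <= 1,
            n_replicates >= 1)
  structure(as.list(environment()), class = "parentage_config")
}

#' Log-likelihood of an offspring genotype given candidate parent(s)
#'
#' Sums per-locus log-likelihoods of Mendelian transmission from the
#' candidate (and the other parent when known, otherwise population allele
#' frequencies), with each observed offspring allele independently mistyped
#' with probability `eps`. Loci missing in the offspring are skipped; loci
#' missing in a parent fall back to population frequencies for that parent.
#'
#' @param off,cand 2 x L allele matrices (see [mendelian_offspring()])
#' @param other 2 x L matrix for the known other parent, or NULL
#' @param freqs allele-frequency list from [allele_freqs()]
#' @param eps per-allele error rate
#' @return summed log-likelihood (may be -Inf under eps = 0 Mendelian
#'   exclusion); NA when no locus is co-genotyped
#' @export
transmission_likelihood <- function(off, cand, other = NULL, freqs, eps) {
  L <- ncol(off)
  ll <- 0; used <- 0L
  for (l in seq_len(L)) {
    u <- off[1, l]; v <- off[2, l]
    if (is.na(u)) next
    p <- freqs[[l]]
    alleles <- as.integer(names(p))
    K <- length(alleles)
    aval <- function(gtl, x) {
      if (is.null(gtl) || is.na(gtl[1])) {
        base <- eps / max(1, K - 1)
        sum(as.numeric(p) * ifelse(alleles == x, 1 - eps, base))
      } else {
        base <- eps / max(1, K - 1)
        mean(ifelse(gtl == x, 1 - eps, base))
      }
    }
    cl <- cand[, l]
    ol <- if (is.null(other)) NULL else other[, l]
    if (!is.na(cl[1])) used <- used + 1L
    lik <- if (u == v) aval(cl, u) * aval(ol, u)
           else aval(cl, u) * aval(ol, v) + aval(cl, v) * aval(ol, u)
    ll <- ll + log(lik)
  }
  if (used == 0L) return(NA_real_)
  ll
}

# Per-offspring candidate evaluation. Returns the best configuration among
# (sire+dam, sire only, dam only, none) with posterior-style weights under
# the p_parent_sampled prior.
#
# gt matrices: a1/a2 numeric matrices individuals x loci; freqs per locus.
eval_offspring <- function(o_a1, o_a2, cand_s, cand_d, freqs, eps, pi_s,
                           shortlist = 20) {
  L <- length(o_a1)
  # per-locus a-values for every candidate at the offspring's two alleles
  avals <- function(c_a1, c_a2) {
    n <- nrow(c_a1)
    A <- matrix(NA_real_, L, max(1, n)); B <- A
    for (l in seq_len(L)) {
      u <- o_a1[l]; v <- o_a2[l]
      if (is.na(u)) next
      p <- freqs[[l]]
      alleles <- as.integer(names(p))
      base <- eps / max(1, length(alleles) - 1)
      span <- 1 - eps - base
      apop_u <- sum(as.numeric(p) * (base + span * (alleles == u)))
      apop_v <- sum(as.numeric(p) * (base + span * (alleles == v)))
      if (n > 0) {
        m_u <- ((c_a1[, l] == u) + (c_a2[, l] == u)) / 2
        m_v <- ((c_a1[, l] == v) + (c_a2[, l] == v)) / 2
        au <- base + span * m_u
        av <- base + span * m_v
        au[is.na(au)] <- apop_u
        av[is.na(av)] <- apop_v
        A[l, ] <- au; B[l, ] <- av
      }
      attr(A, paste0("pop", l)) <- c(apop_u, apop_v)
    }
    list(A = A, B = B)
  }
  vs <- avals(cand_s$a1, cand_s$a2)
  vd <- avals(cand_d$a1, cand_d$a2)
  loci_ok <- which(!is.na(o_a1))
  popA <- vapply(seq_len(L), function(l) {
    pv <- attr(vs$A, paste0("pop", l))
    if (is.null(pv)) c(NA_real_, NA_real_) else pv
  }, numeric(2))
  # single-parent log-likelihoods (other parent = population)
  single_ll <- function(va, n) {
    if (n == 0) return(numeric(0))
    ll <- rep(0, n)
    for (l in loci_ok) {
      u <- o_a1[l]; v <- o_a2[l]
      pu <- popA[1, l]; pv <- popA[2, l]
      lik <- if (u == v) va$A[l, ] * pu else va$A[l, ] * pv + va$B[l, ] * pu
      ll <- ll + log(lik)
    }
    ll
  }
  ns <- nrow(cand_s$a1); nd <- nrow(cand_d$a1)
  ll_s <- single_ll(vs, ns)
  ll_d <- single_ll(vd, nd)
  ll_0 <- 0
  for (l in loci_ok) {
    u <- o_a1[l]; v <- o_a2[l]
    pu <- popA[1, l]; pv <- popA[2, l]
    ll_0 <- ll_0 + log(if (u == v) pu * pu else 2 * pu * pv)
  }
  # shortlist for the trio stage
  top_s <- if (ns) utils::head(order(ll_s, decreasing = TRUE), shortlist) else integer(0)
  top_d <- if (nd) utils::head(order(ll_d, decreasing = TRUE), shortlist) else integer(0)
  ll_trio <- matrix(-Inf, length(top_s), length(top_d))
  if (length(top_s) && length(top_d)) {
    ll_trio <- matrix(0, length(top_s), length(top_d))
    for (l in loci_ok) {
      u <- o_a1[l]; v <- o_a2[l]
      as_ <- vs$A[l, top_s]; bs_ <- vs$B[l, top_s]
      ad_ <- vd$A[l, top_d]; bd_ <- vd$B[l, top_d]
      lik <- if (u == v) outer(as_, ad_) else outer(as_, bd_) + outer(bs_, ad_)
      ll_trio <- ll_trio + log(lik)
    }
  }
  # posterior weights under the sampled-parent prior
  w <- list()
  lw <- c()
  lab <- c()
  if (length(top_s) && length(top_d)) {
    lp <- log(pi_s^2) - log(ns) - log(nd)
    lw <- c(lw, as.numeric(ll_trio) + lp)
    lab <- c(lab, paste0("T", rep(top_s, times = length(top_d)), "_",
                         rep(top_d, each = length(top_s))))
  }
  if (length(top_s)) {
    lp <- log(pi_s * (1 - pi_s)) - log(ns)
    lw <- c(lw, ll_s[top_s] + lp)
    lab <- c(lab, paste0("S", top_s))
  }
  if (length(top_d)) {
    lp <- log(pi_s * (1 - pi_s)) - log(nd)
    lw <- c(lw, ll_d[top_d] + lp)
    lab <- c(lab, paste0("D", top_d))
  }
  lw <- c(lw, ll_0 + log((1 - pi_s)^2))
  lab <- c(lab, "N")
  mx <- max(lw[is.finite(lw)], -746)
  pw <- exp(lw - mx)
  pw[!is.finite(pw)] <- 0
  tot <- sum(pw)
  if (tot == 0) return(NULL)
  pw <- pw / tot
  # marginal support per candidate sire / dam, and P(no sampled sire/dam)
  sire_of <- rep(NA_integer_, length(lab)); dam_of <- rep(NA_integer_, length(lab))
  isT <- startsWith(lab, "T")
  if (any(isT)) {
    sp <- strsplit(sub("^T", "", lab[isT]), "_")
    sire_of[isT] <- as.integer(vapply(sp, `[`, "", 1))
    dam_of[isT] <- as.integer(vapply(sp, `[`, "", 2))
  }
  isS <- startsWith(lab, "S"); isD <- startsWith(lab, "D")
  sire_of[isS] <- as.integer(sub("^S", "", lab[isS]))
  dam_of[isD] <- as.integer(sub("^D", "", lab[isD]))
  marg <- function(of) {
    m <- tapply(pw[!is.na(of)], of[!is.na(of)], sum)
    if (length(m)) m else numeric(0)
  }
  ms <- marg(sire_of); md <- marg(dam_of)
  p_nosire <- sum(pw[is.na(sire_of)])
  p_nodam <- sum(pw[is.na(dam_of)])
  pick <- function(m) {
    if (!length(m)) return(NULL)
    ord <- order(m, decreasing = TRUE)
    # refuse ties between equally supported candidates
    if (length(m) > 1 && abs(m[ord[1]] - m[ord[2]]) < 1e-12) return(NULL)
    list(idx = as.integer(names(m)[ord[1]]), support = as.numeric(m[ord[1]]))
  }
  list(sire = pick(ms), dam = pick(md),
       p_nosire = p_nosire, p_nodam = p_nodam)
}

#' Assign parents to a set of offspring
#'
#' For each offspring, evaluates candidate sires and dams jointly (trio,
#' single-parent and no-parent configurations, weighted by the
#' `p_parent_sampled` prior), assigns the best-supported parents and retains
#' a link only when the posterior probability that no sampled parent of that
#' role exists is below the retention threshold. Equal-support ties refuse
#' assignment.
#'
#' @param gt a `genotype_table` covering offspring and candidates
#' @param offspring_ids character vector
#' @param candidate_sires,candidate_dams character vectors (may overlap
#'   offspring across cohorts; an offspring is never its own candidate)
#' @param freqs allele-frequency baseline (from [allele_freqs()])
#' @param config a [parentage_config()]
#' @return pedigree-link data.frame (columns of [pedigree_links()] with
#'   `replicates_supporting = 1`); skipped offspring in attribute
#'   `"skipped"`
#' @export
assign_parents <- function(gt, offspring_ids, candidate_sires, candidate_dams,
                           freqs = allele_freqs(gt), config = parentage_config()) {
  rows <- list(); skipped <- list()
  idx <- function(ids) match(ids, gt$ids)
  for (o in offspring_ids) {
    oi <- idx(o)
    o_a1 <- gt$a1[oi, ]; o_a2 <- gt$a2[oi, ]
    if (mean(is.na(o_a1)) > config$max_missing) {
      skipped[[length(skipped) + 1]] <-
        data.frame(id = o, reason = "missing fraction above threshold")
      next
    }
    cs <- setdiff(candidate_sires, o)
    cd <- setdiff(candidate_dams, o)
    si <- idx(cs); di <- idx(cd)
    res <- eval_offspring(
      o_a1, o_a2,
      list(a1 = gt$a1[si, , drop = FALSE], a2 = gt$a2[si, , drop = FALSE]),
      list(a1 = gt$a1[di, , drop = FALSE], a2 = gt$a2[di, , drop = FALSE]),
      freqs, config$error_rate, config$p_parent_sampled, config$shortlist)
    if (is.null(res)) next
    if (!is.null(res$sire) && res$p_nosire < config$min_alpha) {
      rows[[length(rows) + 1]] <- data.frame(
        offspring_id = o, parent_id = cs[res$sire$idx], parent_role = "sire",
        support = res$sire$support, replicates_supporting = 1L,
        stringsAsFactors = FALSE)
    }
    if (!is.null(res$dam) && res$p_nodam < config$min_alpha) {
      rows[[length(rows) + 1]] <- data.frame(
        offspring_id = o, parent_id = cd[res$dam$idx], parent_role = "dam",
        support = res$dam$support, replicates_supporting = 1L,
        stringsAsFactors = FALSE)
    }
  }
  links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offspring_id = character(0), parent_id = character(0),
               parent_role = character(0), support = numeric(0),
               replicates_supporting = integer(0), stringsAsFactors = FALSE)
  attr(links, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  links
}

#' Sequential cohort-stacking parentage with replicate consensus
#'
#' Iterates the cohorts chronologically: at step k the offspring are the
#' individuals first seen in cohort k without assigned parents, and the
#' candidates are all individuals seen in cohorts 1..k (fathers among males,
#' mothers among females). Links accepted at earlier steps are fixed and
#' never revised. The whole procedure is run `n_replicates` times with
#' distinct seeds (each replicate bootstraps the allele-frequency baseline
#' unless `resample_freqs` is FALSE) and only links recovered in every
#' replicate enter the consensus pedigree.
#'
#' @param captures validated capture table (defines cohorts and sexes)
#' @param gt a `genotype_table`
#' @param config a [parentage_config()]
#' @param seeds one RNG seed per replicate
#' @return consensus pedigree-link data.frame; attributes: `"replicates"`
#'   (list of per-replicate pedigrees) and `"steps"` (per-cohort cumulative
#'   consensus pedigrees, for the inbreeding trajectory)
#' @export
sequential_pedigree <- function(captures, gt, config = parentage_config(),
                                seeds = seq_len(config$n_replicates)) {
  if (length(seeds) != config$n_replicates)
    stop("need one seed per replicate")
  gt <- filter_genotypes(gt, max_missing = config$max_missing)
  info <- individuals(captures)
  info <- info[info$id %in% gt$ids, ]
  labs <- unique(captures$cohort)
  labs <- labs[order(cohort_index(labs))]
  if (is.unsorted(cohort_index(labs))) stop("cohorts must be chronological")
  first_of <- stats::setNames(info$first_cohort, info$id)
  sex_of <- stats::setNames(info$sex, info$id)

  run_replicate <- function(seed) {
    set.seed(seed)
    gt_r <- gt
    if (config$replicate_perturb > 0 && config$n_replicates > 1) {
      m <- matrix(stats::runif(length(gt_r$a1)) < config$replicate_perturb,
                  nrow(gt_r$a1))
      gt_r$a1[m] <- NA_integer_; gt_r$a2[m] <- NA_integer_
    }
    fr <- allele_freqs(gt_r)
    accepted <- NULL
    step_links <- vector("list", length(labs))
    for (k in seq_along(labs)) {
      seen <- info$id[cohort_index(first_of[info$id]) <= cohort_index(labs[k])]
      offspring <- info$id[first_of[info$id] == labs[k]]
      if (!is.null(accepted)) {
        has_s <- accepted$offspring_id[accepted$parent_role == "sire"]
        has_d <- accepted$offspring_id[accepted$parent_role == "dam"]
        offspring <- setdiff(offspring, intersect(has_s, has_d))
      }
      sires <- seen[sex_of[seen] == "M"]
      dams <- seen[sex_of[seen] == "F"]
      if (length(offspring) && (length(sires) || length(dams))) {
        links <- assign_parents(gt_r, offspring, sires, dams, fr, config)
        # drop links that would create a cycle with already accepted ones
        if (nrow(links)) {
          cur <- accepted
          keep <- logical(nrow(links))
          for (r in seq_len(nrow(links))) {
            trial <- rbind(cur, links[r, , drop = FALSE])
            ok <- !inherits(try(check_pedigree_acyclic(trial), silent = TRUE),
                            "try-error")
            if (ok) { cur <- trial; keep[r] <- TRUE }
          }
          links <- links[keep, , drop = FALSE]
        }
        accepted <- rbind(accepted, links)
      }
      step_links[[k]] <- accepted
    }
    list(links = accepted, steps = step_links)
  }

  reps <- lapply(seeds, run_replicate)
  key <- function(df) if (is.null(df) || nrow(df) == 0) character(0) else
    paste(df$offspring_id, df$parent_id, df$parent_role)
  consensus_of <- function(dfs) {
    keys <- lapply(dfs, key)
    common <- Reduce(intersect, keys)
    base <- dfs[[1]]
    if (is.null(base) || nrow(base) == 0 || !length(common))
      return(data.frame(offspring_id = character(0), parent_id = character(0),
                        parent_role = character(0), support = numeric(0),
                        replicates_supporting = integer(0),
                        stringsAsFactors = FALSE))
    out <- base[key(base) %in% common, , drop = FALSE]
    supp <- sapply(dfs, function(d) d$support[match(key(out), key(d))])
    out$support <- if (is.matrix(supp)) apply(supp, 1, min) else min(supp)
    out$replicates_supporting <- length(dfs)
    rownames(out) <- NULL
    out
  }
  cons <- consensus_of(lapply(reps, `[[`, "links"))
  steps <- lapply(seq_along(labs), function(k)
    consensus_of(lapply(reps, function(r) r$steps[[k]])))
  names(steps) <- labs
  attr(cons, "replicates") <- lapply(reps, `[[`, "links")
  attr(cons, "steps") <- steps
  cons
}
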