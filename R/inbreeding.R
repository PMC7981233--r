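# Pedigree inbreeding: F of an individual is the kinship (coancestry) of its
# two parents over the known pedigree, computed by the recursive tabular
# method with unknown parents treated as unrelated founders.

# kinship (coancestry) of two individuals over a pedigree given as named
# lists sire_of / dam_of (NA for unknown), with memoisation
pedigree_kinship_fun <- function(sire_of, dam_of) {
  cache <- new.env(parent = emptyenv())
  depth_of <- new.env(parent = emptyenv())
  depth <- function(i) {
    if (is.na(i)) return(0L)
    d <- depth_of[[i]]
    if (!is.null(d)) return(d)
    if (identical(depth_of[[paste0(".", i)]], TRUE))
      stop("cyclic parentage involving ", i)
    depth_of[[paste0(".", i)]] <- TRUE
    d <- 1L + max(depth(sire_of[[i]] %||% NA_character_),
                  depth(dam_of[[i]] %||% NA_character_))
    depth_of[[i]] <- d
    d
  }
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (identical(i, j)) {
      s <- sire_of[[i]] %||% NA_character_
      d <- dam_of[[i]] %||% NA_character_
      return(0.5 * (1 + f(s, d)))
    }
    key <- paste(sort(c(i, j)), collapse = "\r")
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    # recurse through the parents of the later-generation member
    if (depth(i) < depth(j)) { tmp <- i; i <- j; j <- tmp }
    v <- 0.5 * (f(sire_of[[i]] %||% NA_character_, j) +
                  f(dam_of[[i]] %||% NA_character_, j))
    cache[[key]] <- v
    v
  }
  f
}

ped_maps <- function(pedigree) {
  if (is.data.frame(pedigree) && "parent_role" %in% names(pedigree))
    pedigree <- pedigree_wide(pedigree)
  need <- c("offspring_id", "sire_id", "dam_id")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must have offspring_id, sire_id, dam_id columns")
  s <- as.list(stats::setNames(as.character(pedigree$sire_id),
                               pedigree$offspring_id))
  d <- as.list(stats::setNames(as.character(pedigree$dam_id),
                               pedigree$offspring_id))
  clean <- function(m) lapply(m, function(x)
    if (is.null(x) || is.na(x) || !nzchar(x)) NA_character_ else x)
  list(sire = clean(s), dam = clean(d))
}

#' Pedigree inbreeding coefficient of an individual
#'
#' F = kinship of the individual's two parents over the known pedigree
#' (recursive tabular method); unknown parents contribute as unrelated
#' founders, so F = 0 when either parent is unknown.
#'
#' @param pedigree long-form pedigree links (as returned by
#'   [sequential_pedigree()]) or a wide data.frame with `offspring_id`,
#'   `sire_id`, `dam_id`
#' @param individual_id the individual
#' @return F in `[0, 1]`
#' @export
inbreeding_coefficient <- function(pedigree, individual_id) {
  maps <- ped_maps(pedigree)
  f <- pedigree_kinship_fun(maps$sire, maps$dam)
  s <- maps$sire[[individual_id]] %||% NA_character_
  d <- maps$dam[[individual_id]] %||% NA_character_
  f(s, d)
}

#' Inbreeding coefficients for all individuals with two assigned parents
#' @param pedigree see [inbreeding_coefficient()]
#' @return data.frame: id, F
#' @export
inbreeding_all <- function(pedigree) {
  maps <- ped_maps(pedigree)
  ids <- names(maps$sire)
  both <- vapply(ids, function(i)
    !is.na(maps$sire[[i]]) && !is.na(maps$dam[[i]]), logical(1))
  ids <- ids[both]
  f <- pedigree_kinship_fun(maps$sire, maps$dam)
  data.frame(id = ids,
             F = vapply(ids, function(i) f(maps$sire[[i]], maps$dam[[i]]),
                        numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort trajectory of the mean pedigree inbreeding coefficient
#'
#' After each sequential cohort step, the mean (and sd) of F over all
#' individuals with both parents assigned in the pedigree as known at that
#' step. Mirrors the gradual rise of population F with time and sampling.
#'
#' @param step_pedigrees named list of cumulative pedigrees per cohort step
#'   (attribute `"steps"` of [sequential_pedigree()])
#' @return data.frame: cohort, n (individuals with two parents), mean_F, sd_F
#' @export
inbreeding_trajectory <- function(step_pedigrees) {
  out <- lapply(names(step_pedigrees), function(lab) {
    ped <- step_pedigrees[[lab]]
    fs <- if (is.null(ped) || nrow(ped) == 0)
      numeric(0) else inbreeding_all(ped)$F
    data.frame(cohort = lab, n = length(fs),
               mean_F = if (length(fs)) mean(fs) else 0,
               sd_F = if (length(fs) > 1) stats::sd(fs) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
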