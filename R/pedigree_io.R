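# Pedigree links: inferred parent-offspring assignments with support level and
# replicate-consensus count. The on-disk form is a CSV with one row per
# offspring (sire and dam columns, NA when unassigned).

#' Assemble a pedigree-link table
#'
#' @param offspring_id,parent_id character vectors
#' @param parent_role "sire" or "dam"
#' @param support posterior-style support in `[0, 1]`
#' @param replicates_supporting integer count of replicate runs recovering the
#'   link
#' @return data.frame of pedigree links
#' @export
pedigree_links <- function(offspring_id, parent_id, parent_role, support,
                           replicates_supporting) {
  stopifnot(all(parent_role %in% c("sire", "dam")),
            all(support >= 0 & support <= 1))
  df <- data.frame(offspring_id = as.character(offspring_id),
                   parent_id = as.character(parent_id),
                   parent_role = parent_role,
                   support = support,
                   replicates_supporting = as.integer(replicates_supporting),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("offspring_id", "parent_role")])
  if (any(dup)) stop("more than one ", df$parent_role[dup][1], " for offspring ",
                     df$offspring_id[dup][1])
  check_pedigree_acyclic(df)
  df
}

check_pedigree_acyclic <- function(links) {
  if (nrow(links) == 0) return(invisible(TRUE))
  parent_of <- split(links$parent_id, links$offspring_id)
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    s <- state[[id]]
    if (identical(s, "done")) return(invisible(TRUE))
    if (identical(s, "active")) stop("cyclic parentage involving ", id)
    state[[id]] <- "active"
    for (p in parent_of[[id]]) if (!is.na(p)) visit(p)
    state[[id]] <- "done"
    invisible(TRUE)
  }
  for (id in unique(links$offspring_id)) visit(id)
  invisible(TRUE)
}

#' Write a pedigree to CSV
#'
#' One row per offspring: `offspring_id, sire_id, dam_id, support_sire,
#' support_dam, replicates_sire, replicates_dam`.
#' @param links pedigree-link data.frame (long form, one row per link)
#' @param path output file
#' @export
write_pedigree <- function(links, path) {
  wide <- pedigree_wide(links)
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

pedigree_wide <- function(links) {
  offs <- unique(links$offspring_id)
  pick <- function(o, role, col) {
    r <- links[links$offspring_id == o & links$parent_role == role, ]
    if (nrow(r) == 0) NA else r[[col]][1]
  }
  data.frame(
    offspring_id = offs,
    sire_id = vapply(offs, function(o)
      as.character(pick(o, "sire", "parent_id")), character(1)),
    dam_id = vapply(offs, function(o)
      as.character(pick(o, "dam", "parent_id")), character(1)),
    support_sire = vapply(offs, function(o) as.numeric(pick(o, "sire", "support")), 0),
    support_dam = vapply(offs, function(o) as.numeric(pick(o, "dam", "support")), 0),
    replicates_sire = vapply(offs, function(o)
      as.integer(pick(o, "sire", "replicates_supporting")), 0L),
    replicates_dam = vapply(offs, function(o)
      as.integer(pick(o, "dam", "replicates_supporting")), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a pedigree CSV written by [write_pedigree()]
#' @param path CSV file
#' @return long-form pedigree-link data.frame
#' @export
read_pedigree <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(offspring_id = "character"))
  rows <- list()
  for (i in seq_len(nrow(wide))) {
    for (role in c("sire", "dam")) {
      pid <- wide[[paste0(role, "_id")]][i]
      if (!is.na(pid) && nzchar(pid)) {
        rows[[length(rows) + 1]] <- data.frame(
          offspring_id = wide$offspring_id[i],
          parent_id = as.character(pid),
          parent_role = role,
          support = wide[[paste0("support_", role)]][i],
          replicates_supporting = wide[[paste0("replicates_", role)]][i],
          stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offspring_id = character(0), parent_id = character(0),
               parent_role = character(0), support = numeric(0),
               replicates_supporting = integer(0), stringsAsFactors = FALSE)
  check_pedigree_acyclic(links)
  links
}
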