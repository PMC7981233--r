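# Shared fixture builders: tiny hand-made habitats and genotype generators.

# square park with rectangular bushes given as (x0, y0, x1, y1) on the walls
toy_habitat <- function(rects, side = 100) {
  bushes <- lapply(rects, function(r)
    rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4])))
  names(bushes) <- as.character(seq_along(bushes))
  fence <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side), c(0, 0))
  habitat_map(bushes, fence, fence_buffer = side)
}

# two-bush habitat: 9x2 bush at the south wall plus one on the north wall
two_bush_habitat <- function() {
  toy_habitat(list(c(10, 0, 19, 2), c(40, 98, 44, 100)))
}

# random multiallelic genotype generators over integer allele pools
rand_pools <- function(n_loci = 8, k = 20) {
  lapply(seq_len(n_loci), function(l) as.integer(100 + 2 * (0:(k - 1))))
}

rand_freqs <- function(pools) {
  lapply(pools, function(p) {
    g <- stats::rgamma(length(p), 1)
    stats::setNames(g / sum(g), p)
  })
}

draw_genotype <- function(pools, freqs) {
  rbind(
    vapply(seq_along(pools), function(l)
      sample(pools[[l]], 1, prob = freqs[[l]]), integer(1)),
    vapply(seq_along(pools), function(l)
      sample(pools[[l]], 1, prob = freqs[[l]]), integer(1)))
}

gt_from_list <- function(gts, ids = sprintf("i%04d", seq_along(gts)),
                         loci = sprintf("L%02d", seq_len(ncol(gts[[1]])))) {
  a1 <- do.call(rbind, lapply(gts, function(g) g[1, ]))
  a2 <- do.call(rbind, lapply(gts, function(g) g[2, ]))
  genotype_table(ids, loci, a1, a2)
}

# allele-frequency list in the package format built from known frequencies
freqs_from_known <- function(frq, n_genes = 10000L) {
  out <- lapply(frq, function(p) structure(p, n_genes = n_genes))
  stats::setNames(out, sprintf("L%02d", seq_along(frq)))
}

# minimal valid capture data.frame
cap_row <- function(id, year, season, sex, svl, bush, mass = NA_real_) {
  data.frame(id = id, year = year, season = season, sex = sex,
             svl_mm = svl, mass_g = mass, bush_id = bush,
             stringsAsFactors = FALSE)
}

truth_sire_links <- function(sim) {
  tp <- sim$truth$pedigree
  tp <- tp[!is.na(tp$sire) & tp$sire %in% unique(sim$captures$id), ]
  data.frame(offspring_id = tp$id, parent_id = tp$sire, parent_role = "sire",
             support = 1, replicates_supporting = 3L, stringsAsFactors = FALSE)
}
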