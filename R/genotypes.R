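# Multilocus codominant microsatellite genotypes: individual x locus diploid
# calls stored as two integer allele-size matrices with a1 <= a2 (allele pairs
# are unordered). Missing calls are NA in both matrices.

#' Construct a genotype table
#'
#' @param ids character vector of individual ids
#' @param loci character vector of locus names
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes; pairs
#'   are normalised so that a1 <= a2; a missing call has NA in both
#' @return object of class `genotype_table`
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(nrow(a1) == length(ids), ncol(a1) == length(loci),
            all(dim(a1) == dim(a2)))
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  na_mismatch <- xor(is.na(a1), is.na(a2))
  if (any(na_mismatch)) stop("half-missing genotype call(s)")
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$ids), length(x$loci), 100 * miss))
  invisible(x)
}

#' Read microsatellite genotypes from CSV or GenePop
#'
#' The CSV dialect has one `id` column then two columns per locus named
#' `<locus>_1` and `<locus>_2`; empty cells, `NA` or 0 are missing. The
#' GenePop dialect follows GenePop 4.x: title line, locus names (one per line
#' or one comma-separated line), `Pop` separators, then `id , 102104 000000`
#' lines with 2- or 3-digit allele codes (all-zero = missing).
#'
#' @param path input file
#' @param format "csv", "genepop", or "auto" (by file extension)
#' @param captures optional validated capture table; individuals absent from
#'   it are retained with a warning
#' @return a `genotype_table`
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "genepop"),
                           captures = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "genepop"
  gt <- if (format == "csv") read_genotypes_csv(path) else read_genotypes_genepop(path)
  if (!is.null(captures)) {
    unknown <- setdiff(gt$ids, unique(captures$id))
    if (length(unknown))
      warning(sprintf("%d genotyped individual(s) absent from capture table: %s",
                      length(unknown),
                      paste(utils::head(unknown, 5), collapse = ", ")))
  }
  gt
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("genotype CSV must have an 'id' column")
  acols <- setdiff(names(df), "id")
  if (length(acols) %% 2 != 0) stop("odd allele column count at a locus")
  loci <- unique(sub("_[12]$", "", acols))
  if (!all(c(paste0(loci, "_1"), paste0(loci, "_2")) %in% acols))
    stop("each locus needs exactly two columns '<locus>_1' and '<locus>_2'")
  to_int <- function(v) {
    v <- suppressWarnings(as.integer(v))
    v[!is.na(v) & v == 0] <- NA_integer_
    v
  }
  a1 <- sapply(loci, function(l) to_int(df[[paste0(l, "_1")]]))
  a2 <- sapply(loci, function(l) to_int(df[[paste0(l, "_2")]]))
  if (nrow(df) == 1) { a1 <- t(a1); a2 <- t(a2) }
  genotype_table(as.character(df$id), loci, a1, a2)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("truncated GenePop file")
  body <- lines[-1]  # drop title
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_at) == 0) stop("no 'Pop' separator in GenePop file")
  locus_lines <- body[seq_len(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ind_lines <- body[-seq_len(pop_at[1])]
  ind_lines <- ind_lines[!grepl("^\\s*pop\\s*$", ind_lines, ignore.case = TRUE)]
  ids <- character(length(ind_lines))
  a1 <- matrix(NA_integer_, length(ind_lines), length(loci))
  a2 <- matrix(NA_integer_, length(ind_lines), length(loci))
  for (i in seq_along(ind_lines)) {
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2) stop(sprintf("malformed GenePop line %d", i))
    ids[i] <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop(sprintf("individual %s: %d genotype fields for %d loci",
                   ids[i], length(codes), length(loci)))
    for (l in seq_along(codes)) {
      code <- codes[l]
      w <- nchar(code)
      if (w %% 2 != 0) stop(sprintf("odd allele code width at locus %s", loci[l]))
      half <- w / 2
      x <- as.integer(substr(code, 1, half))
      y <- as.integer(substr(code, half + 1, w))
      if (!is.na(x) && x != 0) a1[i, l] <- x
      if (!is.na(y) && y != 0) a2[i, l] <- y
      if (is.na(a1[i, l]) || is.na(a2[i, l])) { a1[i, l] <- NA; a2[i, l] <- NA }
    }
  }
  genotype_table(ids, loci, a1, a2)
}

#' Write genotypes to CSV or GenePop
#' @param gt a `genotype_table`
#' @param path output file
#' @param format "csv" or "genepop"
#' @param digits allele-code width for GenePop (2 or 3)
#' @param title GenePop title line
#' @export
write_genotypes <- function(gt, path, format = c("genepop", "csv"),
                            digits = 3, title = "anolespat genotypes") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(id = gt$ids, stringsAsFactors = FALSE)
    for (l in seq_along(gt$loci)) {
      df[[paste0(gt$loci[l], "_1")]] <- gt$a1[, l]
      df[[paste0(gt$loci[l], "_2")]] <- gt$a2[, l]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (any(!is.na(gt$a1) & (gt$a1 >= 10^digits | gt$a2 >= 10^digits)))
      stop(sprintf("allele sizes exceed %d-digit GenePop coding", digits))
    fmt <- function(m) {
      v <- sprintf(paste0("%0", digits, "d"), ifelse(is.na(m), 0L, m))
      matrix(v, nrow(m), ncol(m))
    }
    c1 <- fmt(gt$a1); c2 <- fmt(gt$a2)
    rows <- vapply(seq_along(gt$ids), function(i)
      paste0(gt$ids[i], " , ", paste0(c1[i, ], c2[i, ], collapse = " ")),
      character(1))
    writeLines(c(title, gt$loci, "Pop", rows), path)
  }
  invisible(path)
}

#' Drop individuals with too many missing loci
#'
#' Individuals missing more than `max_missing` of loci are excluded from
#' genetic analyses, with the reason recorded in the `"excluded"` attribute.
#' @param gt a `genotype_table`
#' @param max_missing maximum tolerated missing fraction (default 0.25)
#' @return filtered `genotype_table`
#' @export
filter_genotypes <- function(gt, max_missing = 0.25) {
  frac <- rowMeans(is.na(gt$a1))
  drop <- frac > max_missing
  if (!any(drop)) return(gt)
  out <- genotype_table(gt$ids[!drop], gt$loci,
                        gt$a1[!drop, , drop = FALSE], gt$a2[!drop, , drop = FALSE])
  attr(out, "excluded") <- data.frame(id = gt$ids[drop],
                                      missing_fraction = frac[drop],
                                      reason = "missing genotype fraction above threshold",
                                      stringsAsFactors = FALSE)
  out
}

#' Allele frequencies by gene counting
#' @param gt a `genotype_table`
#' @param ids optional reference subset of individuals
#' @return named list per locus: named numeric vector of frequencies over
#'   allele sizes, with attribute `n_genes` (number of gene copies counted)
#' @export
allele_freqs <- function(gt, ids = NULL) {
  keep <- if (is.null(ids)) seq_along(gt$ids) else match(ids, gt$ids)
  if (anyNA(keep)) stop("unknown individual id(s) in reference set")
  out <- vector("list", length(gt$loci))
  names(out) <- gt$loci
  for (l in seq_along(gt$loci)) {
    al <- c(gt$a1[keep, l], gt$a2[keep, l])
    al <- al[!is.na(al)]
    tab <- table(al)
    fr <- as.numeric(tab) / sum(tab)
    names(fr) <- names(tab)
    attr(fr, "n_genes") <- length(al)
    out[[l]] <- fr
  }
  out
}
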