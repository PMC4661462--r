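#' Construct a diploid microsatellite genotype table
#'
#' Genotypes are stored long-form internally: one row per individual with a
#' population id and one column per locus holding `"a1/a2"` allele strings
#' (opaque labels) or `NA` for missing. Every individual x locus cell carries
#' exactly two alleles or is missing; an individual belongs to exactly one
#' population.
#'
#' @param populations Population id per individual.
#' @param individuals Unique individual ids.
#' @param loci Data frame / matrix of `"a1/a2"` strings, one column per locus.
#' @return A `data.frame` of class `genotype_table` with attributes
#'   `locus_ids`.
#' @export
genotype_table <- function(populations, individuals, loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (anyDuplicated(individuals))
    stop("individual present in two populations or duplicated", call. = FALSE)
  if (length(populations) != length(individuals) ||
      nrow(loci) != length(individuals))
    stop("genotype table dimensions inconsistent", call. = FALSE)
  for (j in seq_along(loci)) {
    cell <- loci[[j]]
    miss <- is.na(cell) | cell == "./."
    parts <- strsplit(cell[!miss], "/", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("locus ", names(loci)[j],
           ": each cell needs exactly two alleles ('a1/a2') or './.'",
           call. = FALSE)
    cell[miss] <- NA_character_
    loci[[j]] <- cell
  }
  gt <- data.frame(population = as.character(populations),
                   individual = as.character(individuals),
                   loci, stringsAsFactors = FALSE, check.names = FALSE)
  attr(gt, "locus_ids") <- names(loci)
  class(gt) <- c("genotype_table", "data.frame")
  gt
}

#' Read diploid genotypes from TSV
#'
#' Columns: `population`, `individual`, then one column per locus with
#' `"a1/a2"` calls or `"./."` for missing.
#'
#' @param path File path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("population", "individual")
  if (!all(need %in% names(df)))
    stop("genotype file needs 'population' and 'individual' columns",
         call. = FALSE)
  genotype_table(df$population, df$individual,
                 df[setdiff(names(df), need)])
}

#' Write genotypes as TSV
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  df <- as.data.frame(gt)
  for (loc in attr(gt, "locus_ids")) df[[loc]][is.na(df[[loc]])] <- "./."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# allele frequency list: per locus, per population table of frequencies and
# the number of scored individuals (missing genotypes excluded)
allele_frequencies <- function(gt) {
  loci <- attr(gt, "locus_ids")
  pops <- unique(gt$population)
  res <- list()
  for (loc in loci) {
    per_pop <- list()
    for (p in pops) {
      cells <- gt[[loc]][gt$population == p]
      cells <- cells[!is.na(cells)]
      n <- length(cells)
      alleles <- unlist(strsplit(cells, "/", fixed = TRUE))
      per_pop[[p]] <- list(n = n,
                           freq = if (n > 0) table(alleles) / (2 * n)
                                  else table(character(0)))
    }
    res[[loc]] <- per_pop
  }
  res
}
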