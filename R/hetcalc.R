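#' Read a genotype table from CSV
#'
#' Reads a wide genotype CSV (one row per individual; columns
#' `individual_id`, `nest_id`, `patch_id`, `year`, then one `locus_*`
#' column per SNP with alternate-allele counts 0, 1, 2 or empty/NA for a
#' missing call). Locus order is preserved.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` genotype table.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("individual_id", "nest_id", "patch_id", "year")
  missing_meta <- setdiff(meta, names(gt))
  if (length(missing_meta))
    stop("genotype file lacks required columns: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  loci <- locus_columns(gt)
  if (!length(loci))
    stop("genotype file has no locus_* columns", call. = FALSE)
  for (j in loci) {
    v <- gt[[j]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad))
      stop(sprintf("invalid genotype code %s at row %d, column %s (allowed: 0, 1, 2, NA)",
                   format(v[bad[1]]), bad[1], j), call. = FALSE)
    gt[[j]] <- as.integer(v)
  }
  gt
}

#' @keywords internal
locus_columns <- function(gt) grep("^locus_", names(gt), value = TRUE)

# Extract the calls matrix (individuals x loci) from a genotype table.
.calls_matrix <- function(gt) {
  as.matrix(gt[, locus_columns(gt), drop = FALSE])
}

#' Filter individuals by genotype call rate
#'
#' Retains individuals whose fraction of non-missing calls is at least
#' `min_call_rate` (default 0.95, i.e. individuals with call rates below
#' 95% are excluded).
#'
#' @param gt Genotype table (see [read_genotypes()]).
#' @param min_call_rate Minimum fraction of non-missing calls, in `[0, 1]`.
#' @return The filtered genotype table (possibly with zero rows).
#' @export
filter_individuals <- function(gt, min_call_rate = 0.95) {
  calls <- .calls_matrix(gt)
  rate <- rowMeans(!is.na(calls))
  gt[rate >= min_call_rate, , drop = FALSE]
}

#' Filter out units with too few genotyped individuals
#'
#' Drops all individuals belonging to units (nests or patch-year
#' populations) with fewer than `min_individuals` genotyped individuals —
#' two being the minimum sample required to estimate expected
#' heterozygosity.
#'
#' @param gt Genotype table.
#' @param level `"nest"` or `"population"` (a population is all genotyped
#'   individuals of a patch in a given year).
#' @param min_individuals Minimum individuals per unit (default 2).
#' @return The filtered genotype table.
#' @export
filter_units <- function(gt, level = c("nest", "population"),
                         min_individuals = 2) {
  level <- match.arg(level)
  key <- .unit_key(gt, level)
  n <- table(key)
  keep <- key %in% names(n)[n >= min_individuals]
  gt[keep, , drop = FALSE]
}

.unit_key <- function(gt, level) {
  if (level == "nest") paste(gt$nest_id, gt$year, sep = "\r")
  else paste(gt$patch_id, gt$year, sep = "\r")
}

#' Observed and expected heterozygosity per unit
#'
#' Computes observed heterozygosity (Ho, the fraction of heterozygous
#' calls) and expected heterozygosity (He, gene diversity) for each nest
#' or each patch-year population, using Nei & Chesser's small-sample
#' correction applied per locus:
#' \deqn{\hat{H}_{e,l} = \frac{n_l}{n_l - 1}\left(1 - \sum_a p_{a,l}^2 -
#'   \frac{H_{o,l}}{2 n_l}\right),}
#' where \eqn{n_l} is the number of individuals with a non-missing call at
#' locus \eqn{l} (missingness varies by locus, so \eqn{n_l} is per-locus).
#' Unit values are means over loci with \eqn{n_l \ge 2}; loci monomorphic
#' within the unit contribute He = Ho = 0 to the mean unless
#' `polymorphic_only = TRUE`.
#'
#' @param gt Genotype table, already filtered
#'   ([filter_individuals()], [filter_units()]).
#' @param level `"nest"` or `"population"`.
#' @param polymorphic_only If `TRUE`, average only over loci polymorphic
#'   within the unit. Default `FALSE` (all usable loci).
#' @return A `data.frame` with one row per unit: `unit_id`, `level`,
#'   `year`, `he`, `ho`, `n_individuals`, `n_loci_used`.
#' @export
#' @examples
#' gt <- data.frame(individual_id = c("a", "b"), nest_id = "n1",
#'                  patch_id = "p1", year = 1,
#'                  locus_0001 = c(0L, 2L), locus_0002 = c(1L, 1L))
#' heterozygosity(gt, "nest")  # He = (1.0 + 0.5) / 2
heterozygosity <- function(gt, level = c("nest", "population"),
                           polymorphic_only = FALSE) {
  level <- match.arg(level)
  if (!nrow(gt)) stop("empty genotype table", call. = FALSE)
  key <- .unit_key(gt, level)
  fac <- factor(key, levels = unique(key))
  calls <- .calls_matrix(gt)
  present <- !is.na(calls)
  calls0 <- calls
  calls0[!present] <- 0L

  n_l <- rowsum(present + 0L, fac)            # units x loci: calls per locus
  het_l <- rowsum((calls == 1L & present) + 0L, fac)
  alt_l <- rowsum(calls0, fac)

  usable <- n_l >= 2
  if (any(rowSums(usable) == 0)) {
    bad <- rownames(n_l)[rowSums(usable) == 0]
    stop("cannot estimate heterozygosity: no locus with >= 2 calls in unit(s) ",
         paste(gsub("\r", ":", bad), collapse = ", "), call. = FALSE)
  }

  p <- alt_l / (2 * pmax(n_l, 1L))
  ho_l <- het_l / pmax(n_l, 1L)
  he_l <- n_l / pmax(n_l - 1L, 1L) * (1 - p^2 - (1 - p)^2 - ho_l / (2 * pmax(n_l, 1L)))
  he_l[he_l < 0] <- 0   # numeric guard; exact zero for monomorphic loci

  use <- usable
  if (polymorphic_only) use <- use & (p > 0 & p < 1)
  use_n <- rowSums(use)
  use_n[use_n == 0] <- NA_integer_
  he <- rowSums(he_l * use) / use_n
  ho <- rowSums(ho_l * use) / use_n

  first <- !duplicated(fac)
  unit_id <- if (level == "nest") gt$nest_id[first] else gt$patch_id[first]
  out <- data.frame(unit_id = unit_id,
                    level = level,
                    year = gt$year[first],
                    he = as.numeric(he),
                    ho = as.numeric(ho),
                    n_individuals = as.integer(table(fac)[levels(fac)]),
                    n_loci_used = as.integer(rowSums(use)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
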