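#' Founder minor-allele frequencies
#'
#' Per-site frequency of allele 1 among founder haplotypes:
#' `p_l = (# allele-1 among founder haplotypes at site l) / (2 * # founders)`.
#' After [orient_minor_alleles()] (applied by the readers and by the
#' simulator's analysis path) allele 1 is the founder minor allele, so the
#' value is the founder MAF and is at most 0.5.
#'
#' @param hap A [haplotype_set()].
#' @param ped The matching validated pedigree tibble.
#' @return A named numeric vector of length `L`.
#' @export
founder_maf <- function(hap, ped) {
  fdr <- is_founder(ped)
  if (!any(fdr)) abort("pedigree has no founders")
  f <- colMeans(rbind(hap$h1[fdr, , drop = FALSE],
                      hap$h2[fdr, , drop = FALSE]))
  names(f) <- hap$sites$site
  f
}

# r' Phi r, the genotype-independent variance factor; reused across sites
# and permutations.
quad_form <- function(r, km) {
  as.numeric(crossprod(r, km$Phi %*% r))
}

#' Per-site retrospective score statistics
#'
#' For each site l the statistic is
#' `T_l = (r' g_l)^2 / (2 p_l (1 - p_l) * r' Phi r)`,
#' where `r` is the covariate-adjusted residual vector, `g_l` the genotype
#' score vector (minor-allele counts), `p_l` the founder allele-1 frequency
#' and `Phi` the genetic-correlation matrix (twice the kinship matrix).
#' Genotypes are treated as random and the trait as fixed; under the null
#' `T_l` has an approximate chi-squared distribution with 1 degree of
#' freedom, and the P-value is its upper tail. Sites monomorphic in
#' founders are untestable: they are flagged `valid = FALSE` and assigned
#' P-value 1.
#'
#' The denominator factor `r' Phi r` does not depend on genotypes; it is
#' computed once and reused across sites (and, by the permutation engine,
#' across permutations).
#'
#' @param r Residual vector from [covariate_residuals()], aligned to `ped`.
#' @param hap A [haplotype_set()] aligned to `ped`.
#' @param ped A validated pedigree tibble.
#' @param km A [kinship_matrix()] for `ped` (computed if `NULL`).
#' @return A tibble with one row per site: `site`, `founder_maf`,
#'   `statistic`, `pvalue`, `valid`.
#' @examples
#' ped <- three_generation_pedigree(2)
#' set.seed(1)
#' pool <- coalescent_pool(200, 20)
#' sim <- simulate_families(pool, 2)
#' traits <- tibble::tibble(family = ped$family, id = ped$id,
#'                          trait = stats::rnorm(nrow(ped)))
#' r <- covariate_residuals(traits, ped = ped)
#' site_statistics(r, sim$hap, ped, kinship_matrix(ped))
#' @export
site_statistics <- function(r, hap, ped, km = NULL) {
  if (is.null(km)) km <- kinship_matrix(ped)
  n <- nrow(hap$h1)
  if (length(r) != n || nrow(ped) != n) {
    abort("residuals, haplotypes and pedigree must align on the same individuals")
  }
  denom <- quad_form(r, km)
  if (denom <= 0) abort("degenerate trait: r' Phi r is not positive")
  f <- founder_maf(hap, ped)
  valid <- f > 0 & f < 1
  g <- hap$h1 + hap$h2
  s <- as.numeric(crossprod(g, r))
  stat <- rep(NA_real_, length(f))
  stat[valid] <- s[valid]^2 / (2 * f[valid] * (1 - f[valid]) * denom)
  pval <- rep(1, length(f))
  pval[valid] <- stats::pchisq(stat[valid], df = 1, lower.tail = FALSE)
  tibble::tibble(site = hap$sites$site, founder_maf = unname(f),
                 statistic = stat, pvalue = pval, valid = valid)
}

#' Write per-site results as a tab-delimited table
#'
#' @param res A [site_statistics()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_results <- function(res, path) {
  utils::write.table(res, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
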