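#' Three-generation 12-member pedigree template
#'
#' The default simulated family: a founder couple (1, 2) with two children
#' (3, 4); founders 5 and 6 marry into the family (6 with 3, 5 with 4);
#' children 7-9 are born to (3, 6) and children 10-12 to (4, 5). Founders
#' are therefore individuals 1, 2, 5 and 6, and each family contributes
#' eight non-founders.
#'
#' @param n_families Number of copies of the template (default 1).
#' @param family_prefix Family ids are `paste0(family_prefix, 1:n)`.
#' @return A validated pedigree tibble with `12 * n_families` rows.
#' @export
three_generation_pedigree <- function(n_families = 1, family_prefix = "F") {
  tmpl <- tibble::tibble(
    id     = as.character(1:12),
    father = c(NA, NA, "1", "1", NA, NA, "3", "3", "3", "5", "5", "5"),
    mother = c(NA, NA, "2", "2", NA, NA, "6", "6", "6", "4", "4", "4"),
    sex    = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  )
  ped <- purrr::map_dfr(seq_len(n_families), function(f) {
    dplyr::bind_cols(family = paste0(family_prefix, f), tmpl)
  })
  validate_pedigree(ped)
}

#' Coalescent haplotype pool
#'
#' Simulates a pool of `n_haplotypes` haplotypes over exactly `n_sites`
#' segregating biallelic sites under a single-tree neutral coalescent with
#' no recombination: successive pairwise coalescences with exponential
#' waiting times (rate `k (k - 1) / 2` with `k` active lineages), then
#' `n_sites` mutations placed on branches with probability proportional to
#' branch length under the infinite-sites model (one new site per
#' mutation). Allele 1 is the derived allele; every site is segregating by
#' construction (the root branch carries no mutations).
#'
#' @param n_haplotypes Pool size `H` (even, >= 4).
#' @param n_sites Number of segregating sites `L` (>= 1).
#' @return An object of class `haplotype_pool`: list with `pool`
#'   (`H x L` 0/1 integer matrix) and `maf` (per-site allele-1 frequency,
#'   in (0, 1)).
#' @export
coalescent_pool <- function(n_haplotypes, n_sites) {
  H <- as.integer(n_haplotypes); L <- as.integer(n_sites)
  if (H < 4 || H %% 2 != 0) abort("n_haplotypes must be an even integer >= 4")
  if (L < 1) abort("n_sites must be >= 1")
  members <- as.list(seq_len(H))
  blen <- numeric(H)
  store_members <- vector("list", 2 * H - 2)
  store_len <- numeric(2 * H - 2)
  nstored <- 0
  k <- H
  while (k > 1) {
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + dt
    pair <- sample.int(k, 2)
    for (x in pair) {
      nstored <- nstored + 1
      store_members[[nstored]] <- members[[x]]
      store_len[nstored] <- blen[x]
    }
    merged <- c(members[[pair[1]]], members[[pair[2]]])
    keep <- setdiff(seq_len(k), pair)
    members <- c(members[keep], list(merged))
    blen <- c(blen[keep], 0)
    k <- k - 1
  }
  hit <- sample.int(nstored, L, replace = TRUE, prob = store_len[seq_len(nstored)])
  pool <- matrix(0L, H, L)
  for (l in seq_len(L)) pool[store_members[[hit[l]]], l] <- 1L
  structure(list(pool = pool, maf = colMeans(pool)), class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", nrow(x$pool), " haplotypes x ", ncol(x$pool),
      " segregating sites\n", sep = "")
  invisible(x)
}

#' Simulate family sequence data from a haplotype pool
#'
#' Each founder draws two haplotypes from the pool; every non-founder
#' receives one full-length haplotype from each parent (no within-region
#' recombination), generation by generation, via the [gene_drop()]
#' semantics. Allele codes keep the pool's derived-allele coding; the
#' analysis path re-orients to the founder minor allele internally, and
#' the trait models determine the risk/minor allele from the pool
#' frequency.
#'
#' @param pool A [coalescent_pool()] (or compatible list with a `pool`
#'   matrix), e.g. an externally supplied haplotype matrix.
#' @param n_families Number of families to simulate.
#' @param template A one-family pedigree template tibble (default the
#'   12-member [three_generation_pedigree()] structure); a warning is
#'   emitted for non-12-member templates since the standard experiment
#'   designs assume the default.
#' @param replace Draw founder haplotypes with replacement (default FALSE;
#'   requires a pool of at least two haplotypes per founder).
#' @return A list with `ped` (pedigree tibble) and `hap`
#'   ([haplotype_set()], pool-coded).
#' @export
simulate_families <- function(pool, n_families, template = NULL,
                              replace = FALSE) {
  if (is.null(template)) {
    ped <- three_generation_pedigree(n_families)
  } else {
    if (nrow(template) != 12) {
      warn("pedigree template is not the 12-member three-generation default")
    }
    template$family <- NULL
    ped <- purrr::map_dfr(seq_len(n_families), function(f) {
      dplyr::bind_cols(family = paste0("F", f), template)
    })
    ped <- validate_pedigree(ped)
  }
  P <- pool$pool
  fdr <- which(is_founder(ped))
  need <- 2 * length(fdr)
  if (!replace && nrow(P) < need) {
    abort(paste0("pool of ", nrow(P), " haplotypes cannot seed ", need,
                 " founder haplotypes without replacement"))
  }
  draw <- sample.int(nrow(P), need, replace = replace)
  n <- nrow(ped); L <- ncol(P)
  h1 <- matrix(0L, n, L); h2 <- matrix(0L, n, L)
  h1[fdr, ] <- P[draw[seq_along(fdr)], , drop = FALSE]
  h2[fdr, ] <- P[draw[length(fdr) + seq_along(fdr)], , drop = FALSE]
  hap <- haplotype_set(h1, h2, uid = paste(ped$family, ped$id, sep = "_"))
  hap <- gene_drop(ped, hap)
  list(ped = ped, hap = hap)
}

#' Genotype relative risk from population attributable risk
#'
#' The per-allele genotype relative risk implied by a causal site's
#' marginal population attributable risk (PAR) and its population minor
#' allele frequency:
#' `GRR = PAR / (MAF * (1 - PAR)) + 1`.
#' The GRR is strictly decreasing in MAF (rarer causal variants get larger
#' effects) and increasing in PAR; `PAR = 0` gives `GRR = 1` (no effect).
#'
#' @param par Marginal PAR in `[0, 1)` (vectorised).
#' @param maf Population minor allele frequency in (0, 1) (vectorised).
#' @return Numeric vector of GRRs (>= 1).
#' @examples
#' grr_from_par(0.01, 0.01)  # ~2.01
#' @export
grr_from_par <- function(par, maf) {
  if (any(par < 0) || any(par >= 1)) abort("par must lie in [0, 1)")
  if (any(maf <= 0) || any(maf >= 1)) abort("maf must lie in (0, 1)")
  par / (maf * (1 - par)) + 1
}

#' Disease model: multiplicative penetrance from per-site PAR
#'
#' Builds the dichotomous-trait generative model: each causal site gets a
#' genotype relative risk from its marginal PAR and pool minor allele
#' frequency ([grr_from_par()]), and an individual's penetrance is the
#' baseline multiplied by GRR once per causal (minor) allele carried,
#' clamped at 1 (see [dichotomous_trait()]).
#'
#' @param maf Pool allele-1 frequencies (from [coalescent_pool()]).
#' @param causal_sites 1-based site indices of causal sites (default
#'   `c(10, 20, 30, 40, 50)`; use `integer(0)` for a null model).
#' @param total_par Overall PAR split equally across causal sites (the
#'   marginal PAR per site is `total_par / length(causal_sites)`).
#' @param par_per_site Alternative: explicit per-site marginal PARs.
#' @param baseline_penetrance Penetrance of a subject with no causal
#'   minor allele (default 0.05).
#' @return An object of class `disease_model`: tibble of causal sites with
#'   `site`, `maf`, `risk_allele`, `par`, `grr`, plus the baseline in
#'   attribute `f0`.
#' @export
disease_model <- function(maf, causal_sites = c(10L, 20L, 30L, 40L, 50L),
                          total_par = 0.05, par_per_site = NULL,
                          baseline_penetrance = 0.05) {
  causal_sites <- as.integer(causal_sites)
  if (length(causal_sites) > 0 && max(causal_sites) > length(maf)) {
    abort("causal site index exceeds the number of sites")
  }
  if (is.null(par_per_site)) {
    par_per_site <- rep(total_par / max(1, length(causal_sites)),
                        length(causal_sites))
  }
  f <- maf[causal_sites]
  minor <- pmin(f, 1 - f)
  if (length(causal_sites) > 0 && any(minor <= 0)) {
    abort("causal site is monomorphic in the pool")
  }
  grr <- if (length(causal_sites) > 0) grr_from_par(par_per_site, minor) else numeric(0)
  m <- tibble::tibble(site = causal_sites, maf = minor,
                      risk_allele = ifelse(f <= 0.5, 1L, 0L),
                      par = par_per_site, grr = grr)
  attr(m, "f0") <- baseline_penetrance
  class(m) <- c("disease_model", class(m))
  m
}

#' Simulate a dichotomous trait under the multiplicative penetrance model
#'
#' Each individual's penetrance is
#' `min(1, f0 * prod_j GRR_j ^ c_ij)`, where `c_ij` in 0/1/2 counts the
#' causal (minor) alleles carried at causal site j over both haplotypes;
#' disease status is Bernoulli(penetrance). With no causal site everyone
#' has penetrance `f0`.
#'
#' @param hap A [haplotype_set()] (pool-coded, as from
#'   [simulate_families()]).
#' @param model A [disease_model()].
#' @return Integer 0/1 affection vector along the rows of `hap`.
#' @export
dichotomous_trait <- function(hap, model) {
  f0 <- attr(model, "f0")
  n <- nrow(hap$h1)
  if (nrow(model) == 0) {
    pen <- rep(f0, n)
  } else {
    cnt <- (hap$h1[, model$site, drop = FALSE] ==
              rep(model$risk_allele, each = n)) +
           (hap$h2[, model$site, drop = FALSE] ==
              rep(model$risk_allele, each = n))
    pen <- pmin(1, f0 * exp(cnt %*% log(model$grr)))
  }
  as.integer(stats::runif(n) < pen)
}

#' QTL model: additive genotypic values calibrated to variance explained
#'
#' Builds the continuous-trait generative model. At QTL l with minor
#' allele frequency `p_l`, genotype score `x` in 0/1/2 contributes a
#' genotypic value drawn from Normal with mean `a_l (x - 1)` (so +a, 0, -a
#' for 2, 1, 0 minor alleles) and variance `sigma2_g`; the additive effect
#' `a_l` is calibrated under Hardy-Weinberg founder frequencies so that the
#' QTL explains fraction `h2_l` of the total trait variance:
#' `V = sigma2_e / (1 - sum h2)` and `a_l^2 * 2 p_l (1 - p_l) + sigma2_g =
#' h2_l * V`.
#'
#' @inheritParams disease_model
#' @param h2_per_site Per-QTL fraction of trait variance explained
#'   (recycled; default 0.001).
#' @param mean Overall trait mean (default 100).
#' @param sigma2_e Error variance (default 100). Neither the mean nor the
#'   error variance affects the test, which is scale and location
#'   invariant.
#' @param sigma2_g Within-genotype variance of the genotypic value
#'   (default 0).
#' @return An object of class `qtl_model`: tibble with `site`, `maf`,
#'   `minor_allele`, `h2`, `a`, plus attributes `mu`, `sigma2_e`,
#'   `sigma2_g`.
#' @export
qtl_model <- function(maf, causal_sites = c(10L, 20L, 30L, 40L, 50L),
                      h2_per_site = 0.001, mean = 100, sigma2_e = 100,
                      sigma2_g = 0) {
  causal_sites <- as.integer(causal_sites)
  if (length(causal_sites) > 0 && max(causal_sites) > length(maf)) {
    abort("causal site index exceeds the number of sites")
  }
  h2 <- rep_len(h2_per_site, length(causal_sites))
  if (sum(h2) >= 1) abort("total variance explained must be below 1")
  f <- maf[causal_sites]
  minor <- pmin(f, 1 - f)
  if (length(causal_sites) > 0 && any(minor <= 0)) {
    abort("causal QTL is monomorphic in the pool")
  }
  V <- sigma2_e / (1 - sum(h2))
  a2 <- (h2 * V - sigma2_g) / (2 * minor * (1 - minor))
  if (length(a2) > 0 && any(a2 < 0)) {
    abort("sigma2_g exceeds the variance budget of a QTL")
  }
  m <- tibble::tibble(site = causal_sites, maf = minor,
                      minor_allele = ifelse(f <= 0.5, 1L, 0L),
                      h2 = h2, a = sqrt(a2))
  attr(m, "mu") <- mean
  attr(m, "sigma2_e") <- sigma2_e
  attr(m, "sigma2_g") <- sigma2_g
  class(m) <- c("qtl_model", class(m))
  m
}

#' Simulate a continuous trait under the additive QTL model
#'
#' `Y_i = mu + sum_l G_il + e_i`, with `G_il ~ Normal(a_l (x_il - 1),
#' sigma2_g)` for minor-allele count `x_il` and `e_i ~ Normal(0,
#' sigma2_e)`.
#'
#' @param hap A [haplotype_set()] (pool-coded).
#' @param model A [qtl_model()].
#' @return Numeric trait vector along the rows of `hap`.
#' @export
continuous_trait <- function(hap, model) {
  n <- nrow(hap$h1)
  mu <- attr(model, "mu")
  s2e <- attr(model, "sigma2_e")
  s2g <- attr(model, "sigma2_g")
  gsum <- 0
  if (nrow(model) > 0) {
    x <- (hap$h1[, model$site, drop = FALSE] ==
            rep(model$minor_allele, each = n)) +
         (hap$h2[, model$site, drop = FALSE] ==
            rep(model$minor_allele, each = n))
    means <- (x - 1) %*% diag(model$a, nrow = nrow(model))
    G <- means + matrix(stats::rnorm(n * nrow(model), 0, sqrt(s2g)),
                        n, nrow(model))
    gsum <- rowSums(G)
  }
  mu + gsum + stats::rnorm(n, 0, sqrt(s2e))
}
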