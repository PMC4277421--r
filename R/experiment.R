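#' Type-I error / power experiments for the ADA region test
#'
#' Runs replicated simulations of the standard study design: a fresh
#' coalescent haplotype pool per replicate, `n_families` copies of the
#' three-generation 12-member pedigree, `n_sites` segregating sites, a
#' trait simulated under the chosen generative model, and one [ada_test()]
#' per replicate. Returns the rejection proportion of the adjusted P-value
#' at each nominal level, with binomial standard errors.
#'
#' With `causal_sites = integer(0)` (or zero effect) this estimates the
#' type-I error rate; with causal sites and a positive effect it estimates
#' power. For dichotomous traits the effect is the overall PAR split
#' equally over the causal sites; for continuous traits it is the total
#' variance explained, split equally per QTL. In the improbable event that
#' a simulated trait is constant (untestable by construction) the trait is
#' redrawn.
#'
#' @param trait `"dichotomous"` or `"continuous"`.
#' @param effect Vector of overall effect sizes: total PAR (dichotomous)
#'   or total variance explained (continuous); `0` simulates the null with
#'   no causal sites. One scenario is run per element.
#' @param n_families,n_sites Families per replicate and sites per region
#'   (defaults 50 and 100).
#' @param causal_sites Causal site indices (default sites 10, 20, 30, 40,
#'   50; ignored when the effect is 0).
#' @param n_replicates Simulation replicates per scenario.
#' @param B Permutations per replicate (default 1000).
#' @param alpha Nominal significance levels to report (default 0.01-0.05).
#' @param pool_haplotypes Coalescent pool size per replicate (default
#'   1000).
#' @param baseline_penetrance,mu,sigma2_e Trait-model parameters (defaults
#'   0.05, 100, 100).
#' @param thresholds,transform Passed to [ada_test()].
#' @return A tibble with one row per scenario x nominal level: `trait`,
#'   `effect`, `n_families`, `n_sites`, `n_causal`, `B`, `n_replicates`,
#'   `alpha`, `rejections`, `rate`, `se`. Attribute `"pvalues"` holds the
#'   per-scenario adjusted P-values (named list by effect).
#' @examples
#' set.seed(42)
#' run_experiment("dichotomous", effect = 0, n_families = 2, n_sites = 10,
#'                n_replicates = 2, B = 100, pool_haplotypes = 100)
#' @export
run_experiment <- function(trait = c("dichotomous", "continuous"),
                           effect = 0, n_families = 50, n_sites = 100,
                           causal_sites = c(10L, 20L, 30L, 40L, 50L),
                           n_replicates = 1000, B = 1000,
                           alpha = c(0.01, 0.02, 0.03, 0.04, 0.05),
                           pool_haplotypes = 1000,
                           baseline_penetrance = 0.05, mu = 100,
                           sigma2_e = 100, thresholds = ada_thresholds(),
                           transform = "ln") {
  trait <- match.arg(trait)
  if (length(causal_sites) > 0 && any(effect > 0) &&
      max(causal_sites) > n_sites) {
    abort("causal site index exceeds n_sites")
  }
  ped <- three_generation_pedigree(n_families)
  km <- kinship_matrix(ped)
  base_trait <- tibble::tibble(family = ped$family, id = ped$id)
  pv_by_effect <- list()
  out <- purrr::map_dfr(effect, function(eff) {
    cs <- if (eff > 0) as.integer(causal_sites) else integer(0)
    pv <- vapply(seq_len(n_replicates), function(rep_i) {
      pool <- coalescent_pool(pool_haplotypes, n_sites)
      sim <- simulate_families(pool, n_families)
      for (try in 1:100) {
        y <- if (trait == "dichotomous") {
          dichotomous_trait(sim$hap,
            disease_model(pool$maf, causal_sites = cs, total_par = eff,
                          baseline_penetrance = baseline_penetrance))
        } else {
          continuous_trait(sim$hap,
            qtl_model(pool$maf, causal_sites = cs,
                      h2_per_site = if (length(cs)) eff / length(cs) else 0,
                      mean = mu, sigma2_e = sigma2_e))
        }
        if (stats::var(y) > 0) break
      }
      tt <- dplyr::mutate(base_trait, trait = y)
      fit <- ada_test(ped, sim$hap, tt, km = km, thresholds = thresholds,
                      B = B, transform = transform)
      fit$adjusted_pvalue
    }, numeric(1))
    pv_by_effect[[as.character(eff)]] <<- pv
    purrr::map_dfr(alpha, function(a) {
      rej <- sum(pv <= a)
      tibble::tibble(trait = trait, effect = eff,
                     n_families = n_families, n_sites = n_sites,
                     n_causal = length(cs), B = B,
                     n_replicates = n_replicates, alpha = a,
                     rejections = rej, rate = rej / max(1, n_replicates),
                     se = sqrt(a * (1 - a) / max(1, n_replicates)))
    })
  })
  if (n_replicates == 0) out <- out[0, ]
  attr(out, "pvalues") <- pv_by_effect
  out
}

#' Plot rejection rates from an experiment table
#'
#' Power (or type-I error) as a function of the overall effect size, one
#' line per nominal level.
#'
#' @param data A [run_experiment()] result tibble (rows from several
#'   effects may be bound together).
#' @return A ggplot object.
#' @export
plot_power <- function(data) {
  ggplot(data, aes(x = .data$effect, y = .data$rate,
                   colour = factor(.data$alpha))) +
    geom_line() + geom_point() +
    labs(x = "overall effect (total PAR or variance explained)",
         y = "rejection rate", colour = "nominal level")
}
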