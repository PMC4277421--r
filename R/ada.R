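#' Default truncation-threshold grid
#'
#' Candidate P-value truncation thresholds for the adaptive combination
#' score: 0.05 to 0.50 in steps of 0.05. Wider grids add little power;
#' the grid is user-configurable throughout.
#'
#' @return A numeric vector of strictly increasing thresholds in (0, 1).
#' @export
ada_thresholds <- function() seq(0.05, 0.50, by = 0.05)

# fast numeric core: S_j = sum_l w_l * 1[P_l < theta_j] over valid sites
sig_scores_num <- function(pvalues, thresholds, valid = NULL,
                           transform = "ln") {
  if (!is.null(valid)) pvalues <- pvalues[valid]
  w <- if (transform == "log10") -log10(pvalues) else -log(pvalues)
  vapply(thresholds, function(th) sum(w[pvalues < th]), numeric(1))
}

#' Truncated significance scores over the threshold grid
#'
#' For each truncation threshold `theta_j`, the significance score is
#' `S_j = sum_l (-ln P_l) * 1[P_l < theta_j]`, summed over valid sites
#' only; sites whose P-value is at or above the threshold are discarded
#' from the score (strict inequality). Scores are nondecreasing in the
#' threshold.
#'
#' @param pvalues A [site_statistics()] tibble (columns `pvalue`, `valid`),
#'   or a bare numeric vector of per-site P-values.
#' @param thresholds Strictly increasing thresholds in (0, 1).
#' @param transform Per-site transform: `"ln"` (default) or `"log10"`.
#' @return A tibble with columns `threshold` and `score`.
#' @examples
#' significance_scores(c(0.04, 0.06, 0.5), thresholds = c(0.05, 0.10))
#' @export
significance_scores <- function(pvalues, thresholds = ada_thresholds(),
                                transform = c("ln", "log10")) {
  transform <- match.arg(transform)
  check_thresholds(thresholds)
  if (is.data.frame(pvalues)) {
    p <- pvalues$pvalue
    valid <- pvalues$valid %||% rep(TRUE, length(p))
  } else {
    p <- as.numeric(pvalues)
    valid <- rep(TRUE, length(p))
  }
  tibble::tibble(threshold = thresholds,
                 score = sig_scores_num(p, thresholds, valid, transform))
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) == 0) abort("threshold grid must not be empty")
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    abort("thresholds must be strictly increasing and inside (0, 1)")
  }
  invisible(thresholds)
}

# #{x' in xs : x' >= x} for each x in xs (self included)
count_ge_self <- function(xs) length(xs) - rank(xs, ties.method = "min") + 1

#' Adaptive combination of P-values (ADA) test for a region
#'
#' Runs the full family-based adaptive combination test on one region:
#' per-site kinship-adjusted score statistics and P-values
#' ([site_statistics()]), truncated significance scores over a threshold
#' grid ([significance_scores()]), and a permutation null obtained by
#' gene dropping conditional on founder genotypes ([gene_drop()]), with
#' traits held fixed. The residuals, the genetic-correlation quadratic form
#' `r'Phi r`, the founder allele frequencies and the site validity flags
#' are genotype-invariant under this null and are computed once.
#'
#' For each permutation b, scores `S_j^(b)` are computed from the permuted
#' genotypes. The observed score's P-value at threshold j is
#' `p(S_j) = #\{b : S_j^(b) >= S_j\} / B`; each permuted score's P-value is
#' ranked against all B replicates (self included). `MinP` is the minimum
#' over thresholds, for the observed data and every permutation, and the
#' adjusted region P-value is
#' `(1 + #\{b : MinP^(b) <= MinP\}) / (B + 1)`,
#' which corrects for the adaptive choice of threshold.
#'
#' @param ped A validated pedigree tibble.
#' @param hap A [haplotype_set()] aligned to `ped` (phased founders
#'   required).
#' @param traits A trait table (columns `family`, `id`, `trait`, optional
#'   covariates); aligned to `ped` internally.
#' @param km Optional precomputed [kinship_matrix()].
#' @param thresholds Truncation threshold grid (default [ada_thresholds()]).
#' @param B Number of permutations (>= 100; default 1000).
#' @param transform Per-site transform, `"ln"` (default) or `"log10"`.
#' @param covariates Covariate column names (default: all numeric non-id
#'   columns of `traits`).
#' @param sequential_cap Optional sequential Monte-Carlo cap: permutations
#'   are generated in blocks and stopped early once the exceedance count
#'   `#\{b : MinP^(b) <= MinP\}` reaches the cap (the reported `B` is the
#'   number actually used). `NULL` (default) disables early stopping.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference
#'   implementation via [gene_drop()]; identical results on the same seed).
#' @return An object of class `ada_fit`; see [tidy.ada_fit()],
#'   [glance.ada_fit()], [autoplot.ada_fit()].
#' @examples
#' set.seed(7)
#' ped <- three_generation_pedigree(5)
#' pool <- coalescent_pool(200, 30)
#' sim <- simulate_families(pool, 5)
#' traits <- tibble::tibble(family = ped$family, id = ped$id,
#'                          trait = stats::rbinom(nrow(ped), 1, 0.2))
#' fit <- ada_test(ped, sim$hap, traits, B = 100)
#' glance(fit)
#' @export
ada_test <- function(ped, hap, traits, km = NULL,
                     thresholds = ada_thresholds(), B = 1000,
                     transform = c("ln", "log10"), covariates = NULL,
                     sequential_cap = NULL, engine = c("cpp", "r")) {
  transform <- match.arg(transform)
  engine <- match.arg(engine)
  check_thresholds(thresholds)
  if (B < 100) abort("B must be at least 100")
  ped <- validate_pedigree(ped)
  if (is.null(km)) km <- kinship_matrix(ped)
  traits <- align_traits(traits, ped)
  r <- covariate_residuals(traits, covariates = covariates)
  denom <- quad_form(r, km)
  if (denom <= 0) abort("degenerate trait: r' Phi r is not positive")
  obs <- site_statistics(r, hap, ped, km)
  if (!any(obs$valid)) abort("no testable site: all sites are monomorphic in founders")
  S_obs <- sig_scores_num(obs$pvalue, thresholds, obs$valid, transform)

  fdr <- is_founder(ped)
  ord <- ped_topo_order(ped)
  nonf <- ord[!fdr[ord]]
  K <- length(nonf)
  f <- founder_maf(hap, ped)
  idx <- parent_indices(ped)
  fa0 <- ifelse(is.na(idx$father), -1L, idx$father - 1L)
  mo0 <- ifelse(is.na(idx$mother), -1L, idx$mother - 1L)

  block <- if (is.null(sequential_cap)) B else min(B, 100L)
  S_perm <- matrix(0, 0, length(thresholds))
  repeat {
    b_new <- min(block, B - nrow(S_perm))
    if (b_new <= 0) break
    U <- matrix(stats::runif(2 * K * b_new), nrow = 2 * K)
    S_new <- if (engine == "cpp") {
      perm_scores_cpp(hap$h1, hap$h2, fa0, mo0,
                      nonf - 1L, r, denom, unname(f), obs$valid,
                      thresholds, U, as.integer(transform == "log10"))
    } else {
      r_perm_scores(ped, hap, r, denom, f, obs$valid, thresholds, U,
                    transform)
    }
    S_perm <- rbind(S_perm, S_new)
    if (is.null(sequential_cap)) next
    st <- minp_summary(S_obs, S_perm)
    if (st$exceed >= sequential_cap || nrow(S_perm) >= B) break
  }
  st <- minp_summary(S_obs, S_perm)
  B_used <- nrow(S_perm)

  structure(list(
    sites = obs, thresholds = thresholds, scores = S_obs,
    per_threshold_pvalues = st$p_obs, minp = st$minp_obs,
    adjusted_pvalue = (1 + st$exceed) / (B_used + 1),
    B = B_used, perm_scores = S_perm, perm_minp = st$minp_perm,
    transform = transform, n_sites = nrow(obs), n_valid = sum(obs$valid),
    exact = FALSE
  ), class = "ada_fit")
}

# observed/permutation P-values, row minima and exceedance count
minp_summary <- function(S_obs, S_perm) {
  B <- nrow(S_perm)
  J <- length(S_obs)
  p_obs <- vapply(seq_len(J), function(j) sum(S_perm[, j] >= S_obs[j]) / B,
                  numeric(1))
  p_perm <- vapply(seq_len(J), function(j) count_ge_self(S_perm[, j]) / B,
                   numeric(B))
  if (B == 1) p_perm <- matrix(p_perm, nrow = 1)
  minp_perm <- apply(p_perm, 1, min)
  minp_obs <- min(p_obs)
  list(p_obs = p_obs, minp_obs = minp_obs, minp_perm = minp_perm,
       exceed = sum(minp_perm <= minp_obs))
}

# reference permutation path: gene_drop + per-site statistics, consuming
# the same deviate layout as the compiled core
r_perm_scores <- function(ped, hap, r, denom, f, valid, thresholds, U,
                          transform) {
  B <- ncol(U)
  S <- matrix(0, B, length(thresholds))
  dfac <- 2 * f * (1 - f) * denom
  for (b in seq_len(B)) {
    hb <- gene_drop(ped, hap, u = U[, b])
    s <- as.numeric(crossprod(hb$h1 + hb$h2, r))
    pv <- rep(1, length(f))
    pv[valid] <- stats::pchisq(s[valid]^2 / dfac[valid], df = 1,
                               lower.tail = FALSE)
    S[b, ] <- sig_scores_num(pv, thresholds, valid, transform)
  }
  S
}

#' Exact (enumeration) version of the ADA test for small pedigrees
#'
#' Replaces the Monte-Carlo permutation null of [ada_test()] with the exact
#' distribution over all equally likely transmission patterns from
#' [enumerate_transmissions()]. P-values are exact expectations over that
#' distribution (no smoothing): the observed score's P-value at threshold j
#' is `P(S_j^(c) >= S_j)`, the adjusted P-value is
#' `P(MinP^(c) <= MinP)`. Feasible only for pedigrees within the
#' enumeration guard (single small family, e.g. a trio).
#'
#' @inheritParams ada_test
#' @param max_meioses Passed to [enumerate_transmissions()].
#' @return An `ada_fit` object with `exact = TRUE` and `B = NA`.
#' @export
ada_test_exact <- function(ped, hap, traits, km = NULL,
                           thresholds = ada_thresholds(),
                           transform = c("ln", "log10"), covariates = NULL,
                           max_meioses = 24) {
  transform <- match.arg(transform)
  check_thresholds(thresholds)
  ped <- validate_pedigree(ped)
  if (is.null(km)) km <- kinship_matrix(ped)
  traits <- align_traits(traits, ped)
  r <- covariate_residuals(traits, covariates = covariates)
  denom <- quad_form(r, km)
  if (denom <= 0) abort("degenerate trait: r' Phi r is not positive")
  obs <- site_statistics(r, hap, ped, km)
  if (!any(obs$valid)) abort("no testable site: all sites are monomorphic in founders")
  S_obs <- sig_scores_num(obs$pvalue, thresholds, obs$valid, transform)

  en <- enumerate_transmissions(ped, hap, max_meioses = max_meioses)
  nonf <- attr(en, "nonfounder_rows")
  f <- founder_maf(hap, ped)
  valid <- obs$valid
  dfac <- 2 * f * (1 - f) * denom
  g_obs <- hap$h1 + hap$h2
  base <- as.numeric(crossprod(g_obs, r)) -
    as.numeric(crossprod(g_obs[nonf, , drop = FALSE], r[nonf]))
  Sc <- matrix(0, nrow(en), length(thresholds))
  for (ci in seq_len(nrow(en))) {
    G <- en$genotypes[[ci]]
    s <- base + as.numeric(crossprod(G, r[nonf]))
    pv <- rep(1, length(f))
    pv[valid] <- stats::pchisq(s[valid]^2 / dfac[valid], df = 1,
                               lower.tail = FALSE)
    Sc[ci, ] <- sig_scores_num(pv, thresholds, valid, transform)
  }
  w <- en$prob
  J <- length(thresholds)
  p_obs <- vapply(seq_len(J), function(j) sum(w[Sc[, j] >= S_obs[j]]),
                  numeric(1))
  p_conf <- vapply(seq_len(J), function(j) {
    vapply(Sc[, j], function(x) sum(w[Sc[, j] >= x]), numeric(1))
  }, numeric(nrow(en)))
  if (nrow(en) == 1) p_conf <- matrix(p_conf, nrow = 1)
  minp_conf <- apply(p_conf, 1, min)
  minp_obs <- min(p_obs)
  structure(list(
    sites = obs, thresholds = thresholds, scores = S_obs,
    per_threshold_pvalues = p_obs, minp = minp_obs,
    adjusted_pvalue = sum(w[minp_conf <= minp_obs]),
    B = NA_integer_, perm_scores = Sc, perm_minp = minp_conf,
    config_prob = w, transform = transform, n_sites = nrow(obs),
    n_valid = sum(obs$valid), exact = TRUE
  ), class = "ada_fit")
}

#' @export
print.ada_fit <- function(x, ...) {
  cat("Adaptive combination of P-values (ADA) region test\n")
  cat("  sites: ", x$n_sites, " (", x$n_valid, " testable)\n", sep = "")
  if (x$exact) {
    cat("  null: exact enumeration over transmission patterns\n")
  } else {
    cat("  null: ", x$B, " gene-dropping permutations\n", sep = "")
  }
  cat("  MinP: ", format(x$minp, digits = 4),
      "   adjusted P-value: ", format(x$adjusted_pvalue, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Tidy and one-row summaries of an ADA fit
#'
#' `tidy()` returns the per-threshold table (threshold, observed score,
#' permutation P-value); `glance()` returns a one-row summary.
#'
#' @param x An `ada_fit` from [ada_test()] or [ada_test_exact()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ada_fit <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, score = x$scores,
                 pvalue = x$per_threshold_pvalues)
}

#' @rdname tidy.ada_fit
#' @export
glance.ada_fit <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, n_valid = x$n_valid, B = x$B,
                 min_p = x$minp, p_value = x$adjusted_pvalue)
}

#' Plot the permutation null of an ADA fit
#'
#' Histogram of the permuted `MinP` values with the observed `MinP` marked;
#' the adjusted P-value is the (smoothed) fraction of the null at or below
#' the line.
#'
#' @param object An `ada_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ada_fit <- function(object, ...) {
  df <- tibble::tibble(minp = object$perm_minp)
  ggplot(df, aes(x = .data$minp)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$minp, colour = "firebrick",
               linetype = "dashed") +
    labs(x = "permutation MinP", y = "count",
         title = sprintf("ADA permutation null (adjusted P = %.4g)",
                         object$adjusted_pvalue))
}

#' Serialize an ADA fit
#'
#' `ada_to_json()` writes the full result (thresholds, scores, P-values,
#' MinP, adjusted P-value, B) as JSON; `write_ada_summary()` writes a
#' one-row tab-delimited summary.
#'
#' @param x An `ada_fit`.
#' @param path Output path.
#' @param region Region/gene label for the summary row.
#' @return `path`, invisibly.
#' @export
ada_to_json <- function(x, path, region = "region") {
  out <- list(region = region, thresholds = x$thresholds,
              scores = x$scores, per_threshold_pvalues = x$per_threshold_pvalues,
              min_p = x$minp, adjusted_pvalue = x$adjusted_pvalue,
              B = x$B, n_sites = x$n_sites, n_valid = x$n_valid,
              transform = x$transform, exact = x$exact)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ada_to_json
#' @export
write_ada_summary <- function(x, path, region = "region") {
  row <- cbind(region = region, glance(x))
  utils::write.table(row, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
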