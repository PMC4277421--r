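#' Gene-dropping permutation of haplotype transmission
#'
#' Generates one permutation replicate of the genotype data under the null
#' hypothesis that the transmission of haplotypes from parents to offspring
#' is completely random, conditional on parental genotypes. Founders'
#' haplotypes are returned unchanged; every non-founder's pair is
#' regenerated, generation by generation, by drawing one full-length
#' haplotype from the father's current pair and one from the mother's
#' (independently and uniformly; no within-region recombination). Trait
#' data are untouched by construction — only genotypes are resampled.
#'
#' @param ped A validated pedigree tibble.
#' @param hap A [haplotype_set()] with phased founder haplotypes (only
#'   founder haplotypes are consumed; non-founder rows are overwritten).
#' @param u Optional numeric vector of `2 * K` uniform(0,1) deviates, where
#'   `K` is the number of non-founders: for the k-th non-founder in
#'   founders-first order, `u[2k-1]` picks the paternal haplotype (< 0.5 =
#'   the father's first) and `u[2k]` the maternal. Drawn from the R random
#'   number stream when `NULL`. Supplying `u` makes the draw reproducible
#'   independent of RNG state (used to cross-check the compiled
#'   permutation core).
#' @return A new [haplotype_set()] with identical founder rows.
#' @export
gene_drop <- function(ped, hap, u = NULL) {
  fdr <- is_founder(ped)
  ord <- ped_topo_order(ped)
  nonf <- ord[!fdr[ord]]
  K <- length(nonf)
  if (is.null(u)) u <- stats::runif(2 * K)
  if (length(u) != 2 * K) abort("u must have one pair of deviates per non-founder")
  idx <- parent_indices(ped)
  h1 <- hap$h1; h2 <- hap$h2
  depth <- ped_depth(ped)
  pos <- match(seq_len(nrow(ped)), nonf)   # u-index of each individual
  for (d in sort(unique(depth[nonf]))) {
    lev <- nonf[depth[nonf] == d]
    fa <- idx$father[lev]; mo <- idx$mother[lev]
    uf <- u[2 * pos[lev] - 1]; um <- u[2 * pos[lev]]
    new1 <- h1[fa, , drop = FALSE]
    take2 <- uf >= 0.5
    new1[take2, ] <- h2[fa[take2], , drop = FALSE]
    new2 <- h1[mo, , drop = FALSE]
    take2 <- um >= 0.5
    new2[take2, ] <- h2[mo[take2], , drop = FALSE]
    h1[lev, ] <- new1
    h2[lev, ] <- new2
  }
  haplotype_set(h1, h2, sites = hap$sites, uid = hap$uid)
}

#' Exact enumeration of transmission patterns
#'
#' Enumerates all `4^K` equally likely joint meiosis choices for the `K`
#' non-founders of a (small) pedigree and tabulates the distinct
#' non-founder genotype configurations with their exact probabilities. This
#' is the exact counterpart of [gene_drop()] and the oracle behind
#' enumeration-based ADA P-values ([ada_test_exact()]).
#'
#' @param ped A validated pedigree tibble (one family).
#' @param hap A [haplotype_set()]; required unless
#'   `distinct_founder_alleles = TRUE`.
#' @param distinct_founder_alleles If TRUE, ignore allele codes and treat
#'   each of the `2 F` founder haplotypes as a distinct labelled allele at a
#'   single marker; a configuration is then the joint unordered pair of
#'   founder-haplotype labels across non-founders. Used to count the
#'   transmission patterns distinguishable from fully heterozygous
#'   founders.
#' @param max_meioses Enumeration guard: `2 K` must not exceed this
#'   (default 24; counts above ~20 are slow).
#' @return A tibble with one row per distinct configuration: `config` (key
#'   string), `prob` (exact probability; sums to 1), `n_patterns` (number
#'   of meiosis patterns mapping to it), and a list-column `genotypes`
#'   holding the non-founder genotype-score matrix (`K x L`), or the
#'   `K x 2` labelled-pair matrix when `distinct_founder_alleles = TRUE`.
#'   Non-founder order (rows) is founders-first order; attribute
#'   `"nonfounders"` gives their `family:id` labels.
#' @examples
#' ped <- three_generation_pedigree(1)
#' nrow(enumerate_transmissions(ped, distinct_founder_alleles = TRUE))
#' @export
enumerate_transmissions <- function(ped, hap = NULL,
                                    distinct_founder_alleles = FALSE,
                                    max_meioses = 24) {
  ped <- validate_pedigree(ped)
  fdr <- is_founder(ped)
  ord <- ped_topo_order(ped)
  nonf <- ord[!fdr[ord]]
  K <- length(nonf)
  if (2 * K > max_meioses) {
    abort(paste0("pedigree too large for enumeration: ", 2 * K,
                 " meioses exceed the guard of ", max_meioses))
  }
  idx <- parent_indices(ped)
  n <- nrow(ped)
  if (!distinct_founder_alleles) {
    if (is.null(hap)) abort("hap is required unless distinct_founder_alleles = TRUE")
    L <- ncol(hap$h1)
    # global haplotype allele lookup: rows 2i-1 / 2i are individual i's pair
    M <- matrix(0L, 2 * n, L)
    M[2 * seq_len(n) - 1, ] <- hap$h1
    M[2 * seq_len(n), ] <- hap$h2
  }
  if (K == 0) {
    return(tibble::tibble(config = "", prob = 1, n_patterns = 1,
                          genotypes = list(matrix(integer(0), 0, 0))))
  }
  total <- 4^K
  chunk <- min(total, 32768)
  counts <- numeric(0)
  reps <- list()
  start <- 0
  while (start < total) {
    m <- min(chunk, total - start)
    pat <- start + seq_len(m) - 1
    ids1 <- matrix(0, m, n); ids2 <- matrix(0, m, n)
    fi <- which(fdr)
    ids1[, fi] <- rep(2 * fi - 1, each = m)
    ids2[, fi] <- rep(2 * fi, each = m)
    for (k in seq_len(K)) {
      i <- nonf[k]; fa <- idx$father[i]; mo <- idx$mother[i]
      d <- (pat %/% 4^(k - 1)) %% 4
      cf <- d %% 2; cm <- d %/% 2
      ids1[, i] <- ifelse(cf == 0, ids1[, fa], ids2[, fa])
      ids2[, i] <- ifelse(cm == 0, ids1[, mo], ids2[, mo])
    }
    if (distinct_founder_alleles) {
      lo <- pmin(ids1[, nonf, drop = FALSE], ids2[, nonf, drop = FALSE])
      hi <- pmax(ids1[, nonf, drop = FALSE], ids2[, nonf, drop = FALSE])
      cols <- lapply(seq_len(K), function(k) paste0(lo[, k], "/", hi[, k]))
      confmat <- function(row) cbind(first = lo[row, ], second = hi[row, ])
    } else {
      cols <- list()
      G <- array(0L, c(m, K, L))
      for (k in seq_len(K)) {
        G[, k, ] <- M[ids1[, nonf[k]], , drop = FALSE] +
          M[ids2[, nonf[k]], , drop = FALSE]
      }
      cols <- lapply(seq_len(K), function(k) {
        do.call(paste0, lapply(seq_len(L), function(l) G[, k, l]))
      })
      confmat <- function(row) {
        gm <- matrix(G[row, , ], nrow = K, ncol = L)
        storage.mode(gm) <- "integer"
        gm
      }
    }
    key <- do.call(paste, c(cols, sep = ";"))
    tab <- table(key)
    counts <- c(counts, stats::setNames(as.numeric(tab), names(tab)))
    new <- setdiff(names(tab), names(reps))
    for (k2 in new) reps[[k2]] <- confmat(match(k2, key))
    start <- start + m
  }
  counts <- tapply(counts, names(counts), sum)
  keys <- names(counts)
  out <- tibble::tibble(config = keys,
                        prob = as.numeric(counts) / total,
                        n_patterns = as.numeric(counts),
                        genotypes = unname(reps[keys]))
  attr(out, "nonfounders") <- paste(ped$family[nonf], ped$id[nonf], sep = ":")
  attr(out, "nonfounder_rows") <- nonf
  out
}
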