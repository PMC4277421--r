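# Shared fixture builders and independent oracles (built in code, no files).

trio_pedigree <- function(fam = "T1") {
  validate_pedigree(tibble::tibble(
    family = fam, id = c("1", "2", "3"),
    father = c(NA, NA, "1"), mother = c(NA, NA, "2"), sex = c(1L, 2L, 1L)
  ))
}

# trio haplotypes: father 0|1, mother 0|0, child 0|1 at one site
trio_hap <- function(child = c(0L, 1L)) {
  haplotype_set(h1 = matrix(c(0L, 0L, child[1]), 3, 1),
                h2 = matrix(c(1L, 0L, child[2]), 3, 1))
}

# iid Hardy-Weinberg founder haplotypes dropped through the pedigree
hwe_hap <- function(ped, maf, seeded_drop = TRUE) {
  n <- nrow(ped)
  L <- length(maf)
  fdr <- which(is_founder(ped))
  h1 <- matrix(0L, n, L); h2 <- matrix(0L, n, L)
  h1[fdr, ] <- matrix(rbinom(length(fdr) * L, 1, rep(maf, each = length(fdr))),
                      length(fdr), L)
  h2[fdr, ] <- matrix(rbinom(length(fdr) * L, 1, rep(maf, each = length(fdr))),
                      length(fdr), L)
  gene_drop(ped, haplotype_set(h1, h2))
}

# Monte-Carlo identity-by-descent oracle for kinship: founders carry
# distinct allele labels; phi_ij is estimated as the mean over drops of the
# probability that one allele sampled from each individual is identical.
mc_kinship <- function(ped, pairs, n_drops = 1e6, chunk = 1e5) {
  idx <- parent_indices(ped)
  fdr <- is_founder(ped)
  ord <- ped_topo_order(ped)
  nonf <- ord[!fdr[ord]]
  est <- matrix(0, 0, nrow(pairs))
  done <- 0
  while (done < n_drops) {
    m <- min(chunk, n_drops - done)
    a1 <- matrix(0L, m, nrow(ped)); a2 <- matrix(0L, m, nrow(ped))
    fi <- which(fdr)
    a1[, fi] <- rep(2L * fi - 1L, each = m)
    a2[, fi] <- rep(2L * fi, each = m)
    for (i in nonf) {
      fa <- idx$father[i]; mo <- idx$mother[i]
      uf <- runif(m) < 0.5; um <- runif(m) < 0.5
      a1[, i] <- ifelse(uf, a1[, fa], a2[, fa])
      a2[, i] <- ifelse(um, a1[, mo], a2[, mo])
    }
    kin <- sapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs$i[k]; j <- pairs$j[k]
      ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
         (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    })
    est <- rbind(est, kin)
    done <- done + m
  }
  tibble::tibble(i = pairs$i, j = pairs$j,
                 phi_hat = colMeans(est),
                 se = apply(est, 2, sd) / sqrt(nrow(est)))
}

# binomial trait tibble for a pedigree
null_trait <- function(ped, prob = 0.05) {
  repeat {
    y <- rbinom(nrow(ped), 1, prob)
    if (var(y) > 0) break
  }
  tibble::tibble(family = ped$family, id = ped$id, trait = y)
}

write_trio_vcf <- function(path, gts = c("0|1", "0|0", "0|1"),
                           samples = c("T1_1", "T1_2", "T1_3")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "T", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  )
  writeLines(lines, path)
  path
}
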