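#' Construct a phased haplotype set
#'
#' The in-memory container for phased genotypes: two haplotypes per
#' individual over `L` biallelic sites, coded 0/1. Row order must match the
#' pedigree the set will be analysed with; the genotype score of individual
#' `i` at site `l` is the sum of the two haplotype codes (0, 1, or 2 minor
#' alleles under the additive model).
#'
#' @param h1,h2 Integer matrices (individuals x sites) of 0/1 allele codes;
#'   one row per pedigree member, in pedigree order.
#' @param sites Optional tibble describing sites, with columns `site`
#'   (identifier), `pos`, `ref`, `alt`. Defaults are generated.
#' @param uid Optional character vector of individual labels (for printing
#'   and export); defaults to rownames of `h1` or `1..n`.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(h1, h2, sites = NULL, uid = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (!identical(dim(h1), dim(h2))) abort("h1 and h2 must have identical dimensions")
  if (anyNA(h1) || anyNA(h2)) abort("missing allele codes are not supported")
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L))) {
    abort("allele codes must be 0 or 1")
  }
  L <- ncol(h1)
  if (is.null(sites)) {
    sites <- tibble::tibble(site = paste0("s", seq_len(L)),
                            pos = seq_len(L), ref = "A", alt = "T")
  }
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != L) abort("sites must have one row per column of h1")
  if (is.null(uid)) uid <- rownames(h1) %||% as.character(seq_len(nrow(h1)))
  dimnames(h1) <- dimnames(h2) <- NULL
  structure(list(h1 = h1, h2 = h2, sites = sites, uid = as.character(uid)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$h1), " individuals x ", ncol(x$h1),
      " sites\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_set <- function(x) dim(x$h1)

#' Genotype scores (minor-allele counts)
#'
#' @param hap A [haplotype_set()].
#' @return An integer matrix (individuals x sites) of genotype scores
#'   0/1/2, the per-site sums of the two haplotype codes.
#' @export
genotype_scores <- function(hap) {
  g <- hap$h1 + hap$h2
  rownames(g) <- hap$uid
  colnames(g) <- hap$sites$site
  g
}

#' Read phased genotypes from VCF
#'
#' Reads a phased VCF (GT fields with the `|` separator) and returns a
#' [haplotype_set()] aligned to the pedigree rows. Allele codes are
#' re-oriented so that code 1 is the minor allele among founders (see
#' [orient_minor_alleles()]). Mendelian inconsistencies between parents and
#' children raise warnings, not errors.
#'
#' Sample names are matched against the pedigree's individual ids; if those
#' are not globally unique, names of the form `family_id` are expected.
#'
#' @param path Path to a VCF file.
#' @param ped A validated pedigree tibble.
#' @param orient Re-orient codes so 1 = founder minor allele (default TRUE).
#' @return A [haplotype_set()] with one row per pedigree member, in
#'   pedigree order.
#' @export
read_phased_vcf <- function(path, ped, orient = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # always a character matrix, one row per variant
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    abort(paste0("multi-allelic site not supported: ",
                 fix[grepl(",", fix[, "ALT"]), "ID"][1]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {   # single-variant files drop to a named vector
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  samples <- colnames(gt)
  want <- as.character(ped$id)
  if (anyDuplicated(want) || !all(want %in% samples)) {
    want <- paste(ped$family, ped$id, sep = "_")
  }
  miss <- setdiff(want, samples)
  if (length(miss) > 0) {
    abort(paste0("pedigree member missing from VCF: ", miss[1]))
  }
  gt <- gt[, want, drop = FALSE]
  if (anyNA(gt) || any(gt %in% c(".", ".|.", "./."))) {
    abort("missing genotypes are not supported")
  }
  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("unphased genotypes found (\"/\" separator); phased input is required")
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  if (!all(a1 %in% c("0", "1")) || !all(a2 %in% c("0", "1"))) {
    abort("GT alleles must be 0 or 1 (biallelic sites only)")
  }
  sites <- tibble::tibble(
    site = unname(ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                         paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                         fix[, "ID"])),
    pos = as.integer(unname(fix[, "POS"])),
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"])
  )
  hap <- haplotype_set(t(matrix(as.integer(a1), nrow = nrow(fix))),
                       t(matrix(as.integer(a2), nrow = nrow(fix))),
                       sites = sites, uid = paste(ped$family, ped$id, sep = "_"))
  mendel_warn(hap, ped)
  if (orient) hap <- orient_minor_alleles(hap, ped)
  hap
}

#' Write a haplotype set as phased VCF
#'
#' @param hap A [haplotype_set()].
#' @param ped The matching pedigree tibble (sample names are written as
#'   `family_id`).
#' @param path Output path (plain text, VCF v4.2).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hap, ped, path) {
  n <- nrow(hap$h1)
  if (n != nrow(ped)) abort("haplotype set and pedigree sizes differ")
  gt <- matrix(paste0(t(hap$h1), "|", t(hap$h2)), nrow = ncol(hap$h1))
  samples <- paste(ped$family, ped$id, sep = "_")
  s <- hap$sites
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste("1", s$pos, s$site, s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from a plain-text haplotype table
#'
#' The table format is whitespace-delimited with one row per haplotype:
#' columns `family`, `id`, `hap` (1 or 2), then one 0/1 allele code per
#' site.
#'
#' @inheritParams read_phased_vcf
#' @return A [haplotype_set()] in pedigree order.
#' @export
read_haplotype_table <- function(path, ped, orient = TRUE) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 4) abort("haplotype table needs columns family, id, hap, sites...")
  key <- paste(raw[[1]], raw[[2]], sep = "\r")
  alle <- as.matrix(raw[, -(1:3), drop = FALSE])
  storage.mode(alle) <- "integer"
  want <- ped_uid(ped)
  pick <- function(h) {
    rows <- match(paste0(want, "\rh", h), paste0(key, "\rh", raw[[3]]))
    if (anyNA(rows)) {
      abort(paste0("pedigree member missing from haplotype table: ",
                   sub("\r", ":", want[which(is.na(rows))[1]])))
    }
    alle[rows, , drop = FALSE]
  }
  hap <- haplotype_set(pick(1), pick(2),
                       uid = paste(ped$family, ped$id, sep = "_"))
  mendel_warn(hap, ped)
  if (orient) hap <- orient_minor_alleles(hap, ped)
  hap
}

#' @rdname read_haplotype_table
#' @param hap A [haplotype_set()] to write.
#' @export
write_haplotype_table <- function(hap, ped, path) {
  rows <- rbind(
    cbind(ped$family, ped$id, "1", hap$h1),
    cbind(ped$family, ped$id, "2", hap$h2)
  )
  rows <- rows[order(rep(seq_len(nrow(ped)), 2)), , drop = FALSE]
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Orient allele codes to the founder minor allele
#'
#' Flips the 0/1 coding at every site where the frequency of allele 1 among
#' founder haplotypes exceeds 0.5, so that code 1 is the founder minor
#' allele everywhere (ties at exactly 0.5 keep the original alt allele).
#' Idempotent. `ref`/`alt` labels in `sites` are swapped accordingly and a
#' logical `flipped` column records the flips.
#'
#' @param hap A [haplotype_set()].
#' @param ped The matching validated pedigree tibble.
#' @return The re-oriented [haplotype_set()].
#' @export
orient_minor_alleles <- function(hap, ped) {
  fdr <- is_founder(ped)
  if (!any(fdr)) abort("pedigree has no founders")
  f <- colMeans(rbind(hap$h1[fdr, , drop = FALSE], hap$h2[fdr, , drop = FALSE]))
  flip <- f > 0.5
  if (any(flip)) {
    hap$h1[, flip] <- 1L - hap$h1[, flip]
    hap$h2[, flip] <- 1L - hap$h2[, flip]
    s <- hap$sites
    tmp <- s$ref[flip]; s$ref[flip] <- s$alt[flip]; s$alt[flip] <- tmp
    hap$sites <- s
  }
  prev <- if ("flipped" %in% names(hap$sites)) hap$sites$flipped
          else rep(FALSE, ncol(hap$h1))
  hap$sites$flipped <- xor(prev, flip)
  hap
}

# Mendelian consistency: child score within the range attainable from the
# parents' genotypes. Emits one summary warning; returns violations tibble.
mendel_warn <- function(hap, ped) {
  idx <- parent_indices(ped)
  kids <- which(!is.na(idx$father))
  if (length(kids) == 0) return(invisible(tibble::tibble()))
  g <- hap$h1 + hap$h2
  gf <- g[idx$father[kids], , drop = FALSE]
  gm <- g[idx$mother[kids], , drop = FALSE]
  gc <- g[kids, , drop = FALSE]
  lo <- (gf == 2L) + (gm == 2L)
  hi <- (gf >= 1L) + (gm >= 1L)
  bad <- which(gc < lo | gc > hi, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    viol <- tibble::tibble(
      family = ped$family[kids[bad[, 1]]],
      id     = ped$id[kids[bad[, 1]]],
      site   = hap$sites$site[bad[, 2]]
    )
    warn(paste0(nrow(viol), " Mendelian inconsistency(ies) detected, e.g. ",
                "individual ", viol$family[1], ":", viol$id[1],
                " at site ", viol$site[1]))
    return(invisible(viol))
  }
  invisible(tibble::tibble())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
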