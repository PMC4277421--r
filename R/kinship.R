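#' Pedigree kinship and genetic-correlation matrices
#'
#' Computes the pairwise kinship coefficients `phi_ij` (the probability that
#' one allele sampled from each of i and j is identical by descent) by the
#' standard founders-first recursion, and assembles the genetic-correlation
#' matrix `Phi = 2 phi` used by the per-site score statistic. Founders are
#' taken as non-inbred and mutually unrelated, so members of different
#' families have kinship exactly 0 and `Phi` is block-diagonal with one
#' block per family.
#'
#' Recursion (individuals processed so that parents precede children):
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2`, and for a non-founder i
#' and any previously processed j, `phi(i,j) = (phi(father_i, j) +
#' phi(mother_i, j)) / 2`.
#'
#' @param ped A pedigree tibble (validated; cycles raise an error).
#' @return An object of class `kinship_model`: a list with `phi` and `Phi`
#'   (dense symmetric matrices with `family:id` dimnames, aligned to the
#'   pedigree row order) and `blocks` (the family partition).
#' @examples
#' ped <- three_generation_pedigree(1)
#' km <- kinship_matrix(ped)
#' km$Phi[1:4, 1:4]
#' @export
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- parent_indices(ped)
  phi <- matrix(0, n, n)
  blocks <- family_blocks(ped)
  for (block in blocks) {
    ord <- block[order(ped_depth(ped)[block], block)]
    done <- integer(0)
    for (i in ord) {
      fa <- idx$father[i]; mo <- idx$mother[i]
      if (is.na(fa)) {
        phi[i, i] <- 0.5
      } else {
        phi[i, i] <- 0.5 * (1 + phi[fa, mo])
        if (length(done) > 0) {
          v <- 0.5 * (phi[fa, done] + phi[mo, done])
          phi[i, done] <- v
          phi[done, i] <- v
        }
      }
      done <- c(done, i)
    }
  }
  uid <- paste(ped$family, ped$id, sep = ":")
  dimnames(phi) <- list(uid, uid)
  structure(list(phi = phi, Phi = 2 * phi, blocks = blocks),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("<kinship_model> ", nrow(x$phi), " individuals, ",
      length(x$blocks), " family block(s)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.kinship_model <- function(x, which = c("Phi", "phi"), ...) {
  x[[match.arg(which)]]
}

#' Tidy a kinship model into long format
#'
#' @param x A [kinship_matrix()] result.
#' @param upper Keep only pairs with `id1 <= id2` in row order (default
#'   TRUE); cross-family pairs (kinship 0) are dropped.
#' @param ... Unused.
#' @return A tibble with columns `id1`, `id2`, `kinship`.
#' @export
tidy.kinship_model <- function(x, upper = TRUE, ...) {
  uid <- rownames(x$phi)
  pairs <- purrr::map_dfr(x$blocks, function(b) {
    ij <- which(upper.tri(diag(length(b)), diag = TRUE), arr.ind = TRUE)
    tibble::tibble(id1 = uid[b[ij[, 2]]], id2 = uid[b[ij[, 1]]],
                   kinship = x$phi[cbind(b[ij[, 2]], b[ij[, 1]])])
  })
  pairs
}

#' Positive-semi-definiteness check for the genetic-correlation matrix
#'
#' @param km A [kinship_matrix()] result.
#' @param tol Relative tolerance: smallest eigenvalue must be at least
#'   `-tol * largest`.
#' @return TRUE/FALSE.
#' @export
is_psd <- function(km, tol = 1e-8) {
  ev <- eigen(km$Phi, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev))
}

#' Export kinship as a square matrix file or long table
#'
#' @param km A [kinship_matrix()] result.
#' @param path Output path.
#' @param format `"matrix"` (tab-delimited square matrix with row/col
#'   names) or `"long"` (id1, id2, kinship).
#' @return `path`, invisibly.
#' @export
write_kinship <- function(km, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(km$phi, path, quote = FALSE, sep = "\t",
                       col.names = NA)
  } else {
    utils::write.table(tidy(km), path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(path)
}
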