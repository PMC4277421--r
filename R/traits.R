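#' Validate and align a trait table to a pedigree
#'
#' A trait table has one row per pedigree member with columns `family`,
#' `id`, `trait`, plus any number of numeric covariate columns (e.g. age,
#' smoking status). Missing trait or covariate values are rejected: the
#' permutation engine requires complete data.
#'
#' @param traits A data frame with columns `family`, `id`, `trait` and
#'   optional covariate columns.
#' @param ped A validated pedigree tibble; rows of the result follow `ped`.
#' @return A tibble aligned to the pedigree row order.
#' @export
align_traits <- function(traits, ped) {
  traits <- tibble::as_tibble(traits)
  req <- c("family", "id", "trait")
  if (!all(req %in% names(traits))) {
    abort("trait table must have columns family, id, trait")
  }
  traits$family <- as.character(traits$family)
  traits$id <- as.character(traits$id)
  rows <- match(ped_uid(ped), paste(traits$family, traits$id, sep = "\r"))
  if (anyNA(rows)) {
    miss <- ped_uid(ped)[which(is.na(rows))[1]]
    abort(paste0("trait value missing for pedigree member ",
                 sub("\r", ":", miss)))
  }
  out <- traits[rows, , drop = FALSE]
  num <- out[setdiff(names(out), c("family", "id"))]
  if (anyNA(num)) abort("missing trait/covariate values are not supported")
  out
}

#' Covariate-adjusted trait residuals
#'
#' Ordinary-least-squares residuals of the trait on an intercept plus the
#' covariate columns: \code{r = Y - X (X'X)^-1 X'Y}. With no covariates this is
#' mean-centring. The same linear adjustment is applied to dichotomous
#' (0/1) and continuous traits; the downstream score statistic only
#' requires residuals that sum to zero, which the intercept guarantees.
#'
#' @param traits A trait table (see [align_traits()]); if `ped` is given the
#'   table is aligned to it first.
#' @param covariates Character vector of covariate column names. Default:
#'   every numeric column other than `family`, `id`, `trait`.
#' @param ped Optional pedigree tibble to align against.
#' @return A numeric residual vector, one value per row.
#' @export
covariate_residuals <- function(traits, covariates = NULL, ped = NULL) {
  if (!is.null(ped)) traits <- align_traits(traits, ped)
  y <- as.numeric(traits$trait)
  if (anyNA(y)) abort("missing trait values are not supported")
  if (stats::var(y) == 0) abort("degenerate trait: all values identical")
  if (is.null(covariates)) {
    covariates <- setdiff(names(traits), c("family", "id", "trait"))
    covariates <- covariates[vapply(traits[covariates], is.numeric, logical(1))]
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(traits[covariates]))
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("missing covariate values are not supported")
  if (qr(X)$rank < ncol(X)) {
    abort("covariate matrix (with intercept) is rank deficient")
  }
  fit <- stats::lm.fit(X, y)
  as.numeric(fit$residuals)
}
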