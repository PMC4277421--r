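#' Read a pedigree from a PED/FAM file
#'
#' Reads a whitespace-delimited pedigree file with columns family id,
#' individual id, father id, mother id, sex, and (optionally) phenotype.
#' A parent id of `"0"` denotes an absent parent. The returned tibble is
#' validated: every non-founder must have both parents present in the same
#' family, ids must be unique within a family, and the parentage graph must
#' be acyclic.
#'
#' @param path Path to a PED/FAM file (>= 5 whitespace-separated columns).
#' @return A tibble with columns `family`, `id`, `father`, `mother`
#'   (character, `NA` for absent parents), `sex` (integer) and, when a sixth
#'   column is present, `phenotype`. Row order follows the file.
#' @seealso [validate_pedigree()], [founder_ids()], [family_blocks()]
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 5) {
    abort("PED/FAM file must have at least 5 columns (family, id, father, mother, sex).")
  }
  ped <- tibble::tibble(
    family = raw[[1]],
    id     = raw[[2]],
    father = dplyr::na_if(raw[[3]], "0"),
    mother = dplyr::na_if(raw[[4]], "0"),
    sex    = suppressWarnings(as.integer(raw[[5]]))
  )
  if (ncol(raw) >= 6) {
    ph <- suppressWarnings(as.numeric(raw[[6]]))
    ped$phenotype <- if (all(is.na(ph) == is.na(raw[[6]]))) ph else raw[[6]]
  }
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks the structural invariants of a pedigree: ids unique within family,
#' both parents present or both absent, parents found within the same
#' family, and an acyclic parentage graph (every individual's ancestry
#' terminates in founders).
#'
#' @param ped A tibble with columns `family`, `id`, `father`, `mother`
#'   (character; `NA` marks an absent parent).
#' @return `ped`, invisibly unchanged, with rows in their original order.
#'   Errors describe the offending individual.
#' @export
validate_pedigree <- function(ped) {
  req <- c("family", "id", "father", "mother")
  if (!all(req %in% names(ped))) {
    abort(paste0("pedigree must have columns: ", paste(req, collapse = ", ")))
  }
  ped$family <- as.character(ped$family)
  for (col in c("id", "father", "mother")) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & v == "0"] <- NA_character_
    ped[[col]] <- v
  }
  key <- ped_uid(ped)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0("duplicate individual id within family: ", dup[1]))
  }
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) {
    abort(paste0("individual ", key[which(half)[1]],
                 " has one parent recorded but not the other"))
  }
  # parents must be rows of the same family
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    pk <- ifelse(is.na(p), NA_character_, paste(ped$family, p, sep = "\r"))
    missing <- !is.na(pk) & !(pk %in% key)
    if (any(missing)) {
      abort(paste0(col, " '", p[which(missing)[1]], "' of individual ",
                   key[which(missing)[1]], " not found in the same family"))
    }
  }
  # acyclicity via generation-depth fixed point
  if (any(is.na(ped_depth(ped, error_on_cycle = TRUE)))) {
    abort("cycle detected in parentage graph")  # unreachable; ped_depth aborts
  }
  ped
}

# family-scoped unique key (uses a separator that cannot occur in read ids)
ped_uid <- function(ped) paste(ped$family, ped$id, sep = "\r")

# row indices of each individual's parents (NA for founders)
parent_indices <- function(ped) {
  key <- ped_uid(ped)
  fa <- match(ifelse(is.na(ped$father), NA_character_,
                     paste(ped$family, ped$father, sep = "\r")), key)
  mo <- match(ifelse(is.na(ped$mother), NA_character_,
                     paste(ped$family, ped$mother, sep = "\r")), key)
  list(father = fa, mother = mo)
}

# generation depth: founders 0, child = 1 + max(parent depths).
# NA depths after n sweeps indicate a cycle.
ped_depth <- function(ped, error_on_cycle = FALSE) {
  idx <- parent_indices(ped)
  n <- nrow(ped)
  depth <- ifelse(is.na(idx$father) & is.na(idx$mother), 0, NA_real_)
  for (pass in seq_len(n + 1)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    d <- pmax(depth[idx$father[todo]], depth[idx$mother[todo]]) + 1
    depth[todo] <- d
  }
  if (error_on_cycle && any(is.na(depth))) {
    abort(paste0("cycle in parentage graph involving individual ",
                 ped_uid(ped)[which(is.na(depth))[1]]))
  }
  depth
}

# row indices in topological (founders-first) order
ped_topo_order <- function(ped) order(ped_depth(ped), seq_len(nrow(ped)))

#' Founder indicator and founder ids
#'
#' Founders are pedigree members with neither parent recorded; their
#' genotypes are held fixed by the permutation null and define the minor
#' allele and its frequency.
#'
#' @param ped A validated pedigree tibble.
#' @return `is_founder()`: a logical vector along the rows of `ped`.
#'   `founder_ids()`: a tibble with columns `family` and `id` of founders.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' @rdname is_founder
#' @export
founder_ids <- function(ped) {
  dplyr::select(ped[is_founder(ped), ], "family", "id")
}

#' Partition a pedigree into family blocks
#'
#' @param ped A validated pedigree tibble.
#' @return A named list of integer row-index vectors, one per family id, in
#'   order of first appearance; the genetic-correlation matrix is
#'   block-diagonal over this partition.
#' @export
family_blocks <- function(ped) {
  split(seq_len(nrow(ped)), factor(ped$family, levels = unique(ped$family)))
}

#' Write a pedigree to a PED/FAM file
#'
#' @param ped A validated pedigree tibble.
#' @param path Output path.
#' @param phenotype Optional numeric vector written as column 6 (defaults to
#'   the `phenotype` column when present, else 0).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, phenotype = NULL) {
  if (is.null(phenotype)) {
    phenotype <- if ("phenotype" %in% names(ped)) ped$phenotype else rep(0, nrow(ped))
  }
  out <- data.frame(
    ped$family, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    ifelse(is.na(ped$sex), 0L, ped$sex),
    phenotype
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}
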