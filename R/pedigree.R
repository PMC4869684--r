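#' Read a pedigree from a FAM/PED-style file
#'
#' Reads a whitespace-delimited pedigree file with columns family id,
#' individual id, father id, mother id, sex (1 = male, 2 = female).
#' `"0"` (or `NA`) denotes a missing parent. Extra columns are ignored.
#'
#' @param file Path to the pedigree file.
#' @param header Logical; does the file have a header line? Default `FALSE`
#'   (the conventional FAM layout has none).
#' @return A `data.frame` of class `pedigree_df` with columns `fam`, `id`,
#'   `father`, `mother`, `sex` (all character except `sex`, integer).
#' @seealso [kinship_matrix()], [write_kinship()]
#' @export
read_pedigree <- function(file, header = FALSE) {
  raw <- utils::read.table(file, header = header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 5L)
    stop("pedigree file must have at least 5 columns: fam, id, father, mother, sex")
  ped <- data.frame(fam = raw[[1L]], id = raw[[2L]],
                    father = raw[[3L]], mother = raw[[4L]],
                    sex = as.integer(raw[[5L]]),
                    stringsAsFactors = FALSE)
  as_pedigree(ped)
}

#' Construct and validate a pedigree table
#'
#' Validates the structural invariants a pedigree must satisfy before a
#' kinship matrix can be derived from it: ids unique within family, each
#' non-founder with both parents present in the same family, and no
#' individual its own ancestor.
#'
#' @param ped A data.frame with columns `fam`, `id`, `father`, `mother`,
#'   `sex`. Missing parents are `"0"`, `""` or `NA`.
#' @return The validated data.frame, classed `pedigree_df`.
#' @export
as_pedigree <- function(ped) {
  need <- c("fam", "id", "father", "mother", "sex")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  ped$fam <- as.character(ped$fam)
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  ped$father[is.na(ped$father) | ped$father %in% c("0", "")] <- NA_character_
  ped$mother[is.na(ped$mother) | ped$mother %in% c("0", "")] <- NA_character_
  miss <- is.na(ped$father) != is.na(ped$mother)
  if (any(miss))
    stop("individuals with exactly one known parent: ",
         paste(ped$id[miss], collapse = ", "))
  for (f in unique(ped$fam)) {
    sub <- ped[ped$fam == f, ]
    if (anyDuplicated(sub$id))
      stop("duplicated individual ids in family ", f)
    parents <- stats::na.omit(c(sub$father, sub$mother))
    unknown <- setdiff(parents, sub$id)
    if (length(unknown))
      stop("family ", f, ": parent id(s) not present in family: ",
           paste(unique(unknown), collapse = ", "))
    ped_topo_order(sub)  # errors on cycles
  }
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

# Topological order of one family's members (founders first). Errors if the
# parent-offspring graph contains a cycle (an individual its own ancestor).
ped_topo_order <- function(sub) {
  n <- nrow(sub)
  placed <- logical(n)
  order <- integer(0)
  idx <- stats::setNames(seq_len(n), sub$id)
  repeat {
    ready <- !placed &
      (is.na(sub$father) | placed[idx[sub$father]]) &
      (is.na(sub$mother) | placed[idx[sub$mother]])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order) < n)
    stop("cycle detected in pedigree of family ", sub$fam[1L],
         " (individual is its own ancestor)")
  order
}

# Kinship coefficients for one family via the standard recursion, assuming
# founders are unrelated and non-inbred. Returns the n x n matrix of
# 2 * kinship, ordered as `sub` rows.
family_relationship <- function(sub) {
  n <- nrow(sub)
  ord <- ped_topo_order(sub)
  idx <- stats::setNames(seq_len(n), sub$id)
  K <- matrix(0, n, n)
  for (pos in seq_len(n)) {
    i <- ord[pos]
    fa <- sub$father[i]; mo <- sub$mother[i]
    if (is.na(fa)) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 + 0.5 * K[idx[fa], idx[mo]]
    }
    if (pos > 1L) {
      js <- ord[seq_len(pos - 1L)]
      if (is.na(fa)) {
        kij <- rep(0, length(js))
      } else {
        kij <- 0.5 * (K[idx[fa], js] + K[idx[mo], js])
      }
      K[i, js] <- kij
      K[js, i] <- kij
    }
  }
  Phi <- 2 * K
  dimnames(Phi) <- list(sub$id, sub$id)
  Phi
}

#' Pedigree relationship matrix (twice the kinship coefficients)
#'
#' Computes the relationship matrix Phi whose entries are twice the kinship
#' coefficient for each pair, 1 on the diagonal for non-inbred individuals,
#' and 0 between members of different families. Phi enters the mixed-model
#' covariance as `Omega = sigma_a^2 * Phi + sigma_e^2 * I`; for a cohort of
#' unrelated subjects it is the identity matrix.
#'
#' @param ped A pedigree, see [as_pedigree()].
#' @param ids Optional character vector giving the individual ordering of the
#'   returned matrix. Ids not present in the pedigree are treated as
#'   singleton founders (identity row/column), which supports cohorts mixing
#'   family and unrelated samples.
#' @return A symmetric `length(ids)` square matrix with `ids` dimnames.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   fam = "1", id = c("dad", "mom", "kid1", "kid2"),
#'   father = c(NA, NA, "dad", "dad"), mother = c(NA, NA, "mom", "mom"),
#'   sex = c(1L, 2L, 1L, 2L)))
#' kinship_matrix(ped)["kid1", "kid2"]  # 0.5 for full sibs
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  ped <- if (inherits(ped, "pedigree_df")) ped else as_pedigree(ped)
  if (anyDuplicated(ped$id))
    stop("kinship_matrix requires globally unique individual ids")
  if (is.null(ids)) ids <- ped$id
  n <- length(ids)
  Phi <- diag(n)
  dimnames(Phi) <- list(ids, ids)
  for (f in unique(ped$fam)) {
    sub <- ped[ped$fam == f, , drop = FALSE]
    keep <- sub$id %in% ids
    if (!any(keep)) next
    B <- family_relationship(sub)
    present <- sub$id[keep]
    Phi[present, present] <- B[present, present]
  }
  Phi
}

#' Write a relationship matrix as TSV
#'
#' @param phi Symmetric relationship matrix with id dimnames.
#' @param file Output path.
#' @export
write_kinship <- function(phi, file) {
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
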