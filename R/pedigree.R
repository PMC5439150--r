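#' Construct a pedigree table
#'
#' @param animal Character (or coercible) animal identifiers, unique.
#' @param sire,dam Parent identifiers; `NA` (or the missing token in files)
#'   marks an unknown parent, treated as an unrelated non-inbred founder.
#' @return A tibble of class `sadmix_pedigree` with columns `animal`, `sire`,
#'   `dam`, sorted so parents precede offspring.
#' @export
pedigree <- function(animal, sire, dam) {
  ped <- tibble::tibble(
    animal = as.character(animal),
    sire = as.character(sire),
    dam = as.character(dam)
  )
  if (anyDuplicated(ped$animal)) abort("Animal ids must be unique.")
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    missing_ids <- setdiff(ped[[col]][known], ped$animal)
    if (length(missing_ids)) {
      abort(sprintf("Unknown %s id(s) referenced: %s", col,
                    paste(head(missing_ids, 5), collapse = ", ")))
    }
  }
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  class(ped) <- c("sadmix_pedigree", class(ped))
  ped
}

# Topological order (parents first); errors on a cycle.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$animal)
  parent_idx <- cbind(
    ifelse(is.na(ped$sire), NA_integer_, pos[ped$sire]),
    ifelse(is.na(ped$dam), NA_integer_, pos[ped$dam])
  )
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parent_idx[i, ]) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) abort("Pedigree contains a cycle (an animal is its own ancestor).")
  out
}

#' Read a pedigree from delimited text
#'
#' Expects three columns (animal, sire, dam); extra columns are ignored.
#'
#' @param path File path.
#' @param missing Token for an unknown parent (default `"0"`).
#' @param delim Field delimiter (`NULL` = guess comma/tab).
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, missing = "0", delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 3) abort("Pedigree file needs columns animal, sire, dam.")
  df <- df[, 1:3]
  names(df) <- c("animal", "sire", "dam")
  df$sire[df$sire %in% missing] <- NA_character_
  df$dam[df$dam %in% missing] <- NA_character_
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree to delimited text
#' @param ped A [pedigree()] object.
#' @param path Output file.
#' @param missing Token used for unknown parents.
#' @param delim Field delimiter.
#' @return Invisibly `path`.
#' @export
write_pedigree <- function(ped, path, missing = "0", delim = ",") {
  out <- tibble::tibble(
    animal = ped$animal,
    sire = dplyr::coalesce(ped$sire, missing),
    dam = dplyr::coalesce(ped$dam, missing)
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix by the tabular
#' method with inbreeding: processing animals parents-first,
#' `A[i,i] = 1 + F_i` with `F_i = A[sire,dam]/2`, and
#' `A[i,j] = (A[j,sire] + A[j,dam])/2` for older animals `j`.  Unknown
#' parents contribute 0.  Dense storage; intended for pedigrees up to a few
#' thousand animals.
#'
#' @param ped A [pedigree()] object.
#' @return Symmetric positive-definite matrix with animal ids as labels.
#' @export
relationship_matrix <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0) A[j, s] else 0
      ad_ <- if (d > 0) A[j, d] else 0
      aij <- (as_ + ad_) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
    Fi <- if (s > 0 && d > 0) A[s, d] / 2 else 0
    A[i, i] <- 1 + Fi
  }
  A
}

#' Inbreeding coefficients
#' @param ped A [pedigree()] object.
#' @return Named numeric vector `F` per animal.
#' @export
inbreeding <- function(ped) {
  diag(relationship_matrix(ped)) - 1
}

#' Inverse of the numerator relationship matrix
#'
#' Built directly by Henderson's rules accounting for inbreeding: each
#' animal contributes `1/d_i` to the inverse at its (animal, parent) pattern,
#' where `d_i` is the Mendelian sampling variance
#' `0.5 - 0.25 (F_sire + F_dam)` (with unknown parents treated as non-inbred
#' founders contributing variance instead).
#'
#' @param ped A [pedigree()] object.
#' @return Symmetric positive-definite matrix, the inverse of
#'   [relationship_matrix()].
#' @export
relationship_inverse <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  Fi <- inbreeding(ped)
  Ainv <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dii <- 0.5
    # both parents known: 0.5 - 0.25(F_s + F_d); one known: 0.75 - 0.25 F;
    # none: 1 (unknown parents are unrelated non-inbred founders)
    if (s > 0) dii <- dii - 0.25 * Fi[s] else dii <- dii + 0.25
    if (d > 0) dii <- dii - 0.25 * Fi[d] else dii <- dii + 0.25
    w <- 1 / dii
    Ainv[i, i] <- Ainv[i, i] + w
    for (p in c(s, d)) {
      if (p > 0) {
        Ainv[i, p] <- Ainv[i, p] - w / 2
        Ainv[p, i] <- Ainv[p, i] - w / 2
      }
    }
    if (s > 0 && d > 0) {
      Ainv[s, d] <- Ainv[s, d] + w / 4
      Ainv[d, s] <- Ainv[d, s] + w / 4
    }
    if (s > 0) Ainv[s, s] <- Ainv[s, s] + w / 4
    if (d > 0) Ainv[d, d] <- Ainv[d, d] + w / 4
  }
  Ainv
}
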