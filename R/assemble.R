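#' Assemble a phenotype table and model specification for estimation
#'
#' Validates the long-format phenotype records against the specification,
#' orders them into independent blocks (connected components of the
#' relationship matrix restricted to recorded animals), builds the fixed
#' design matrix trait by trait, and precomputes the index structures used
#' by the REML evaluator.
#'
#' Factor covariates are coded by first appearance within each trait's
#' records, with the first-appearing level as the reference under the
#' default treatment contrasts.  Columns made redundant by rank deficiency
#' are dropped (and recorded in `$dropped_columns`).
#'
#' @param data Long-format phenotype tibble with columns `animal`, `time`,
#'   `trait`, `value`, plus any covariates named in the specification's
#'   fixed-effect formulas and the group column if used.
#' @param spec A [sad_model()] specification (an RR specification reuses the
#'   same grid/trait/fixed metadata).
#' @param ped A [pedigree()] containing every recorded animal.
#' @return An object of class `sad_assembled`.
#' @export
assemble_model <- function(data, spec, ped) {
  data <- tibble::as_tibble(data)
  need <- c("animal", "time", "trait", "value")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must have columns", paste(need, collapse = ", ")))
  }
  data$animal <- as.character(data$animal)
  data$trait <- as.character(data$trait)
  bad_trait <- setdiff(unique(data$trait), spec$traits)
  if (length(bad_trait)) {
    abort(sprintf("Undeclared trait(s) in data: %s", paste(bad_trait, collapse = ", ")))
  }
  bad_time <- setdiff(unique(data$time), spec$times)
  if (length(bad_time)) {
    abort(sprintf("Time(s) outside the model grid: %s", paste(bad_time, collapse = ", ")))
  }
  dup <- duplicated(data[, c("animal", "time", "trait")])
  if (any(dup)) {
    abort(sprintf("Duplicate (animal, time, trait) record(s), e.g. row %d.",
                  which(dup)[1]))
  }
  if (anyNA(data$value)) abort("`value` must not contain NA; drop missing cells first.")
  if (!is.null(spec$group) && !spec$group %in% names(data)) {
    abort(sprintf("Group column '%s' not found in data.", spec$group))
  }
  missing_animals <- setdiff(unique(data$animal), ped$animal)
  if (length(missing_animals)) {
    abort(sprintf("Animal(s) missing from pedigree: %s",
                  paste(head(missing_animals, 5), collapse = ", ")))
  }

  A <- relationship_matrix(ped)
  rec_ids <- sort(unique(data$animal))
  A_rec <- A[rec_ids, rec_ids, drop = FALSE]
  comp <- connected_components(abs(A_rec) > 1e-12)

  cells <- trait_time_cells(spec$times, spec$traits)
  data <- data |>
    dplyr::mutate(
      .an = match(.data$animal, rec_ids),
      .block = comp[.data$.an],
      .cell = cells$cell[match(paste0(.data$trait, "@", .data$time), cells$label)]
    ) |>
    dplyr::arrange(.data$.block, .data$.an, .data$.cell)

  n <- nrow(data)
  block_sizes <- tabulate(data$.block, nbins = max(comp))
  offsets <- as.integer(c(0, cumsum(block_sizes)))
  # per-record within-block animal index (0-based)
  an_local <- integer(n)
  Amats <- vector("list", max(comp))
  for (b in seq_len(max(comp))) {
    rows <- which(data$.block == b)
    ids <- unique(data$.an[rows])
    an_local[rows] <- match(data$.an[rows], ids) - 1L
    Amats[[b]] <- A_rec[ids, ids, drop = FALSE]
  }

  X <- build_fixed_design(data, spec)
  dropped <- attr(X, "dropped")

  Zg <- NULL
  group_cols <- NULL
  if (!is.null(spec$group)) {
    glev <- unique(as.character(data[[spec$group]]))
    group_cols <- tidyr::expand_grid(level = glev, trait = spec$traits)
    Zg <- matrix(0, n, nrow(group_cols))
    jg <- match(
      paste(as.character(data[[spec$group]]), data$trait),
      paste(group_cols$level, group_cols$trait)
    )
    Zg[cbind(seq_len(n), jg)] <- 1
  }

  y <- data$value
  structure(list(
    records = data,
    y = y, X = X, Zg = Zg, group_cols = group_cols,
    Tm = cbind(X, y, Zg),
    offsets = offsets, an = an_local, cell0 = data$.cell - 1L,
    Amats = Amats, cells = cells, rec_ids = rec_ids,
    n = n, p = ncol(X),
    logdetXtX = determinant(crossprod(X), logarithm = TRUE)$modulus[1],
    dropped_columns = dropped,
    traits = spec$traits, times = spec$times, group = spec$group,
    fingerprint = c(n = n, y1 = round(sum(y), 6), y2 = round(sum(y^2), 6))
  ), class = "sad_assembled")
}

# Fixed design: block by trait, factor levels by first appearance.
build_fixed_design <- function(data, spec) {
  n <- nrow(data)
  blocks <- lapply(spec$traits, function(tr) {
    rows <- which(data$trait == tr)
    sub <- data[rows, , drop = FALSE]
    f <- spec$fixed[[tr]]
    vars <- all.vars(f)
    missing_vars <- setdiff(vars, names(sub))
    if (length(missing_vars)) {
      abort(sprintf("Covariate(s) %s for trait %s not in data.",
                    paste(missing_vars, collapse = ", "), tr))
    }
    for (v in vars) {
      if (is.character(sub[[v]]) || is.factor(sub[[v]])) {
        sub[[v]] <- factor(as.character(sub[[v]]), levels = unique(as.character(sub[[v]])))
      }
    }
    mm <- model.matrix(f, data = sub)
    colnames(mm) <- paste0(tr, ":", colnames(mm))
    out <- matrix(0, n, ncol(mm), dimnames = list(NULL, colnames(mm)))
    out[rows, ] <- mm
    out
  })
  X <- do.call(cbind, blocks)
  qr_x <- qr(X)
  dropped <- character(0)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

# Connected components of a logical adjacency matrix (union-find).
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(adj & upper.tri(adj, diag = FALSE), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ri <- find(idx[k, 1]); rj <- find(idx[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.sad_assembled <- function(x, ...) {
  cat("Assembled SAD model: ", x$n, " records, ", length(x$rec_ids),
      " recorded animals, ", length(x$Amats), " independent blocks, ",
      x$p, " fixed-effect columns\n", sep = "")
  invisible(x)
}
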