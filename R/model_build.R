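#' Contemporary groups from farm, birth year and sex
#'
#' Animals born on the same farm, in the same year and of the same sex form
#' one contemporary group. Returns the per-record group index and the level
#' table.
#'
#' @param records A record data.frame with columns `farm`, `birth_year`,
#'   `sex`.
#' @return List with `cg` (integer factor per record) and `levels`
#'   (data.frame of distinct farm/birth_year/sex combinations).
#' @export
make_contemporary_groups <- function(records) {
  need <- c("farm", "birth_year", "sex")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(records$farm) | is.na(records$birth_year) |
                 is.na(records$sex))
  if (length(bad)) {
    stop("missing farm/birth_year/sex in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  key <- paste(records$farm, records$birth_year, records$sex, sep = ":")
  lev <- sort(unique(key))
  cg <- factor(key, levels = lev)
  parts <- do.call(rbind, strsplit(lev, ":", fixed = TRUE))
  list(cg = cg,
       levels = data.frame(cg = seq_along(lev), farm = parts[, 1L],
                           birth_year = parts[, 2L], sex = parts[, 3L]))
}

#' Assemble the design structures of the animal model
#'
#' Builds `y`, `X` and `Z` for `y = X beta + Z alpha + e` from a record
#' table and a pedigree. `X` carries a global intercept plus treatment-coded
#' (first level dropped) indicators for each requested factor — a full-rank
#' coding, required because the fixed effects carry flat priors. `Z` links
#' each record to its pedigree animal; animals without records simply get no
#' `Z` entry and are informed through the relationship matrix.
#'
#' @param records Record data.frame (columns `animal`, `farm`, `birth_year`,
#'   `sex`, `yc`, `ac`, `cat`, plus trait columns; missing trait = `NA`).
#' @param ped A `Pedigree`; every recorded animal must appear in it.
#' @param factors Character vector of fixed effects among
#'   `c("cg", "yc", "ac", "cat")`; `"cg"` is formed with
#'   [make_contemporary_groups()].
#' @param trait Name of the trait column to model.
#' @return A `ModelMatrices` list: `y`, sparse `X` (n x f), `animal`
#'   (1-based pedigree index per record, the one nonzero column of each `Z`
#'   row), `N`, factor level maps, the trait name and the number of rows
#'   dropped for a missing trait value.
#' @export
build_design <- function(records, ped,
                         factors = c("cg", "yc", "ac", "cat"),
                         trait) {
  validate_pedigree(ped)
  stopifnot(trait %in% names(records))
  unknown <- setdiff(factors, c("cg", "yc", "ac", "cat"))
  if (length(unknown)) stop("unknown factors: ", paste(unknown, collapse = ", "))

  keep <- !is.na(records[[trait]])
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records with observed trait ", trait)

  idx <- attr(ped, "index")[as.character(records$animal)]
  if (anyNA(idx)) {
    stop("recorded animals absent from pedigree: ",
         paste(utils::head(records$animal[is.na(idx)], 5L), collapse = ", "))
  }
  dup <- duplicated(records$animal)
  if (any(dup)) {
    stop("more than one record per animal for trait ", trait,
         " (first duplicate: ", records$animal[dup][1L], ")")
  }

  n <- nrow(records)
  fac_list <- list()
  for (f in factors) {
    v <- if (f == "cg") make_contemporary_groups(records)$cg
         else factor(records[[f]])
    if (nlevels(v) < 2L) {
      warning("factor ", f, " has a single level; absorbed into the intercept")
      next
    }
    fac_list[[f]] <- v
  }
  X <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                            dims = c(n, 1L))
  colnames(X) <- "(Intercept)"
  level_map <- list()
  for (f in names(fac_list)) {
    v <- fac_list[[f]]
    level_map[[f]] <- levels(v)
    ii <- which(as.integer(v) > 1L)               # drop first level
    Xf <- Matrix::sparseMatrix(i = ii, j = as.integer(v)[ii] - 1L, x = 1,
                               dims = c(n, nlevels(v) - 1L))
    colnames(Xf) <- paste(f, levels(v)[-1L], sep = "=")
    X <- cbind(X, Xf)
  }
  # drop aliased columns so X is full column rank (flat priors need it)
  qrX <- qr(as.matrix(X))
  if (qrX$rank < ncol(X)) {
    drop_cols <- sort(qrX$pivot[-seq_len(qrX$rank)])
    warning("dropping ", length(drop_cols),
            " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }

  structure(list(y = as.numeric(records[[trait]]),
                 X = methods::as(X, "CsparseMatrix"),
                 animal = unname(idx),
                 animal_label = as.character(records$animal),
                 N = nrow(ped),
                 levels = level_map,
                 trait = trait,
                 n_dropped = n_dropped),
            class = "ModelMatrices")
}

#' @export
print.ModelMatrices <- function(x, ...) {
  cat(sprintf("ModelMatrices for '%s': %d records, %d fixed-effect columns, %d pedigree animals (%d rows dropped)\n",
              x$trait, length(x$y), ncol(x$X), x$N, x$n_dropped))
  invisible(x)
}

#' Read / write record files
#'
#' Record files are CSV with a named header (`animal`, `farm`,
#' `birth_year`, `sex`, `yc`, `ac`, `cat`, then one column per trait);
#' missing values are empty fields or `NA`.
#'
#' @param path File path.
#' @return `read_records()` returns a data.frame.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param records Record data.frame to write.
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
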