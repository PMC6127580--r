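#' Build a validated, renumbered pedigree
#'
#' Takes raw animal/sire/dam triplets (any hashable labels; `0`, `NA` or `""`
#' encode an unknown parent), adds parents that never appear in the animal
#' column as founders, topologically sorts the result so that every parent
#' precedes its offspring, and renumbers animals consecutively `1..N`.
#'
#' @param x A data.frame (or matrix) whose first three columns are animal,
#'   sire and dam, or a vector of animal labels when `sire` and `dam` are
#'   given separately.
#' @param sire,dam Optional vectors of parent labels, used when `x` is a
#'   vector of animal labels.
#'
#' @return An object of class `Pedigree`: a data.frame with integer columns
#'   `id`, `sire`, `dam` (0 = unknown parent) in topological order, and a
#'   `label` column carrying the original animal labels. The label-to-index
#'   map is available via `attr(ped, "index")`.
#'
#' @details Unknown parents are treated as draws from an unrelated,
#'   non-inbred base population. An animal appearing twice with conflicting
#'   parents, or a pedigree loop (an animal among its own ancestors), is an
#'   error.
#'
#' @examples
#' ped <- pedigree(data.frame(animal = "C", sire = "A", dam = "B"))
#' ped$label  # A and B added as founders ahead of C
#' @export
pedigree <- function(x, sire = NULL, dam = NULL) {
  if (is.null(sire) != is.null(dam)) {
    stop("supply both `sire` and `dam`, or neither")
  }
  if (!is.null(sire)) {
    x <- data.frame(animal = x, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  if (nrow(x) == 0L) {
    ped <- data.frame(id = integer(), sire = integer(), dam = integer(),
                      label = character(), stringsAsFactors = FALSE)
    attr(ped, "index") <- integer()
    class(ped) <- c("Pedigree", "data.frame")
    return(ped)
  }
  if (ncol(x) < 3L) stop("pedigree input needs three columns: animal, sire, dam")
  lab <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v == "0" | v == ""] <- NA_character_
    v
  }
  animal <- lab(x[[1L]]); sire <- lab(x[[2L]]); dam <- lab(x[[3L]])
  if (anyNA(animal)) stop("animal labels must not be missing or 0")

  # conflicting duplicate rows
  dup <- duplicated(animal)
  if (any(dup)) {
    key <- paste(animal, sire, dam, sep = "\r")
    for (a in unique(animal[dup])) {
      if (length(unique(key[animal == a])) > 1L) {
        stop("animal ", a, " appears twice with conflicting parents")
      }
    }
    keep <- !dup
    animal <- animal[keep]; sire <- sire[keep]; dam <- dam[keep]
  }

  # parents never listed as animals become founders
  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }

  n <- length(animal)
  pos <- match(animal, animal)            # identity; labels unique now
  si <- match(sire, animal)               # NA = unknown
  di <- match(dam, animal)

  # Kahn topological sort (parents before offspring)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_out) < n) {
    bad <- animal[setdiff(seq_len(n), order_out)][1L]
    stop("pedigree loop detected: animal ", bad, " is among its own ancestors")
  }

  newid <- integer(n); newid[order_out] <- seq_len(n)
  to0 <- function(ix) ifelse(is.na(ix), 0L, newid[ix])
  ped <- data.frame(id = seq_len(n),
                    sire = to0(si)[order_out],
                    dam = to0(di)[order_out],
                    label = animal[order_out],
                    stringsAsFactors = FALSE)
  attr(ped, "index") <- stats::setNames(seq_len(n), ped$label)
  class(ped) <- c("Pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate the structural invariants of a Pedigree
#'
#' Checks consecutive ids `1..N`, parents preceding offspring, and no
#' self-parenting. Called by [pedigree()]; exported for use on pedigrees
#' read from files.
#'
#' @param ped A `Pedigree`.
#' @return `ped`, invisibly; errors describe the first violation found.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  n <- nrow(ped)
  if (n == 0L) return(invisible(ped))
  if (!identical(ped$id, seq_len(n))) stop("ids must be consecutive 1..N")
  bad <- which(ped$sire >= ped$id | ped$dam >= ped$id)
  if (length(bad)) {
    stop("parent does not precede offspring at id ", ped$id[bad[1L]])
  }
  invisible(ped)
}

#' @export
print.Pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(x$sire == 0L & x$dam == 0L), "founders )\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the inbreeding coefficient F of every animal without forming the
#' dense relationship matrix, so pedigrees of tens of thousands of animals
#' are cheap. F equals half the relationship between the parents.
#'
#' @param ped A `Pedigree`.
#' @return Numeric vector of length N with `F[i]` in `[0, 1)`.
#' @references Meuwissen & Luo (1992) Genet Sel Evol 24:305.
#' @export
inbreeding <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  if (n == 0L) return(numeric())
  inbreeding_cpp(ped$sire, ped$dam)
}

#' Wright's numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A, with
#' `a_ii = 1 + 0.5 * a_sd` (s, d the parents of i) and
#' `a_ij = 0.5 * (a_js + a_jd)` for animals j preceding i; unknown parents
#' contribute 0. The diagonal equals `1 + F` with F the inbreeding
#' coefficient.
#'
#' @param ped A `Pedigree`.
#' @return A dense symmetric N x N matrix with the pedigree labels as
#'   dimnames.
#' @export
makeA <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$label, ped$label))
  if (n == 0L) return(A)
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s[i] > 0L) v <- v + A[j, s[i]]
      if (d[i] > 0L) v <- v + A[j, d[i]]
      A[j, i] <- A[i, j] <- 0.5 * v
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by the Henderson rules
#' with Quaas' inbreeding correction: each animal contributes
#' `b = 1/d` at its (animal, sire, dam) positions, where the
#' Mendelian-sampling variance is `d = 0.5 - 0.25 (F_s + F_d)` when both
#' parents are known, `0.75 - 0.25 F_p` with one known parent p, and 1 for
#' founders. Inbreeding coefficients come from [inbreeding()], so the dense
#' A is never formed.
#'
#' @param ped A `Pedigree`.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) equal to the
#'   inverse of [makeA()] up to numerical round-off.
#' @export
makeAinv <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  if (n == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, 0L), symmetric = TRUE))
  }
  f <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  # triplets: diagonal 1/d_i at i, cross terms at parents
  ii <- jj <- integer(0); xx <- numeric(0)
  Fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  nk <- (s > 0L) + (d > 0L)
  dvec <- ifelse(nk == 2L, 0.5 - 0.25 * (Fs + Fd),
                 ifelse(nk == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  b <- 1 / dvec
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  add(seq_len(n), seq_len(n), b)
  for (p in list(s, d)) {
    k <- which(p > 0L)
    if (length(k)) {
      add(k, p[k], -0.5 * b[k])
      add(p[k], k, -0.5 * b[k])
      add(p[k], p[k], 0.25 * b[k])
    }
  }
  k <- which(s > 0L & d > 0L)
  if (length(k)) {
    add(s[k], d[k], 0.25 * b[k])
    add(d[k], s[k], 0.25 * b[k])
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$label, ped$label))
  Matrix::forceSymmetric(Ainv)
}

#' Read / write pedigree files
#'
#' Plain-text pedigree files have three columns (animal, sire, dam),
#' whitespace- or comma-delimited, with `0` for an unknown parent.
#'
#' @param path File path.
#' @param header Does the file carry a header line?
#' @return `read_pedigree()` returns a `Pedigree`; `write_pedigree()`
#'   returns `path` invisibly.
#' @export
read_pedigree <- function(path, header = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character",
                          strip.white = TRUE)
  pedigree(df[, 1:3])
}

#' @param ped A `Pedigree` to write (original labels are written out).
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  lab0 <- function(ix) ifelse(ix == 0L, "0", ped$label[pmax(ix, 1L)])
  df <- data.frame(animal = ped$label, sire = lab0(ped$sire),
                   dam = lab0(ped$dam))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
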