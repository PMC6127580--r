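test_that("raw triplets are renumbered, sorted and completed with founders", {
  ped <- pedigree(data.frame(animal = "C", sire = "A", dam = "B"))
  expect_s3_class(ped, "Pedigree")
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$label[3], "C")
  expect_true(all(ped$sire < ped$id & ped$dam < ped$id))
  idx <- attr(ped, "index")
  expect_equal(unname(idx[c("A", "B")]), c(1L, 2L))

  empty <- pedigree(data.frame(a = character(), s = character(),
                               d = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("pedigree loops and conflicting duplicates are rejected", {
  expect_error(pedigree(data.frame(a = c("A", "B"), s = c("B", "A"),
                                   d = c(0, 0))),
               "loop")
  expect_error(pedigree(data.frame(a = c("A", "A"), s = c("B", "C"),
                                   d = c(0, 0))),
               "conflicting")
  # exact duplicate rows are tolerated
  expect_equal(nrow(pedigree(data.frame(a = c("A", "A"), s = c(0, 0),
                                        d = c(0, 0)))), 1L)
})

test_that("tabular A reproduces the classical kinship identities", {
  two <- pedigree(c("a", "b"), c(0, 0), c(0, 0))
  expect_equal(makeA(two), diag(2), ignore_attr = TRUE)

  trio <- pedigree(c("s", "d", "o"), c(0, 0, "s"), c(0, 0, "d"))
  A <- makeA(trio)
  expect_equal(A["o", "s"], 0.5)
  expect_equal(A["o", "d"], 0.5)
  expect_equal(A["o", "o"], 1)

  # full sibs x,y mated: offspring inbred F = 0.25
  fs <- pedigree(c("s", "d", "x", "y", "o"),
                 c(0, 0, "s", "s", "x"), c(0, 0, "d", "d", "y"))
  A <- makeA(fs)
  expect_equal(A["x", "y"], 0.5)
  expect_equal(A["o", "o"], 1.25)
  expect_equal(inbreeding(fs), c(0, 0, 0, 0, 0.25))
})

test_that("A satisfies its structural invariants on random pedigrees", {
  for (seed in 1:5) {
    ped <- random_pedigree(40, seed)
    A <- makeA(ped)
    expect_equal(A, t(A))
    expect_true(all(diag(A) >= 1 & diag(A) < 2))
    expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
                >= -1e-10)
    founders <- which(ped$sire == 0L & ped$dam == 0L)
    # founders are mutually unrelated and non-inbred
    expect_equal(A[founders, founders], diag(length(founders)),
                 ignore_attr = TRUE)
    expect_equal(inbreeding(ped), unname(diag(A)) - 1, tolerance = 1e-12)
  }
})

test_that("Henderson/Quaas A-inverse equals the dense inverse of A", {
  trio <- pedigree(c("s", "d", "o"), c(0, 0, "s"), c(0, 0, "d"))
  Ainv <- as.matrix(makeAinv(trio))
  expect_equal(Ainv, solve(makeA(trio)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(Ainv["o", "o"], 2)

  for (seed in 1:5) {
    ped <- random_pedigree(20, seed + 100)
    err <- max(abs(as.matrix(makeAinv(ped)) - solve(makeA(ped))))
    expect_lt(err, 1e-8)
    prod_err <- max(abs(as.matrix(makeAinv(ped)) %*% makeA(ped) -
                          diag(nrow(ped))))
    expect_lt(prod_err, 1e-8)
  }
})

test_that("pedigree files round-trip through read/write", {
  ped <- random_pedigree(30, 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path, header = TRUE)
  expect_equal(ped2$label, ped$label)
  expect_equal(makeA(ped2), makeA(ped))
})
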