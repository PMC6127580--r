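base_records <- function(n, ...) {
  df <- data.frame(animal = as.character(seq_len(n)),
                   farm = "f1", birth_year = 2013L, sex = "F",
                   yc = 1L, ac = 1L, cat = "dry",
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

test_that("contemporary groups are farm x birth-year x sex classes", {
  r <- base_records(2, y = c(1, 2))
  expect_equal(nlevels(make_contemporary_groups(r)$cg), 1L)

  r$sex <- c("F", "M")
  cg <- make_contemporary_groups(r)
  expect_equal(nlevels(cg$cg), 2L)
  expect_equal(nrow(cg$levels), 2L)

  r$farm[1] <- NA
  expect_error(make_contemporary_groups(r), "missing")
})

test_that("CG count on the synthetic study is bounded by the cell count", {
  st <- small_study()
  cg <- make_contemporary_groups(st$records)
  expect_lte(nlevels(cg$cg), 4 * 3 * 2)
  expect_gt(nlevels(cg$cg), 1)
})

test_that("design matrices use full-rank coding and index every record", {
  ped <- pedigree(as.character(1:3), c(0, 0, 0), c(0, 0, 0))
  r <- base_records(3, yc = c("a", "a", "b"), y = c(1.5, 2, 3))
  mm <- build_design(r, ped, factors = "yc", trait = "y")
  X <- as.matrix(mm$X)
  # intercept + one treatment column for the second level
  expect_equal(unname(X), cbind(c(1, 1, 1), c(0, 0, 1)))
  expect_equal(mm$animal, 1:3)
  expect_equal(mm$y, c(1.5, 2, 3))

  # row sums: intercept plus one indicator per non-reference level hit
  st <- small_study()
  mm <- build_design(st$records, st$pedigree, trait = "weight")
  rs <- Matrix::rowSums(mm$X)
  expect_true(all(rs >= 1 & rs <= 1 + length(mm$levels)))
  expect_equal(length(mm$animal), nrow(st$records))
  expect_equal(ncol(mm$X),
               1 + sum(vapply(mm$levels, length, 1L) - 1L))
  # every record maps to its pedigree position
  expect_equal(st$pedigree$label[mm$animal], as.character(st$records$animal))
})

test_that("missing traits are dropped and duplicates rejected", {
  ped <- pedigree(as.character(1:4), rep(0, 4), rep(0, 4))
  r <- base_records(4, sex = c("F", "M", "F", "M"), y = c(1, NA, 3, 4))
  mm <- build_design(r, ped, factors = "cg", trait = "y")
  expect_equal(mm$n_dropped, 1L)
  expect_equal(length(mm$y), 3L)
  # dropping a record does not change the others' animal coding
  expect_equal(st <- mm$animal, c(1L, 3L, 4L))

  r2 <- base_records(2, y = c(1, 2))
  r2$animal <- c("1", "1")
  expect_error(build_design(r2, ped, factors = "cg", trait = "y"),
               "one record per animal")

  r3 <- base_records(2, y = c(NA_real_, NA_real_))
  expect_error(build_design(r3, ped, factors = "cg", trait = "y"),
               "no records")
})

test_that("degenerate factors warn and unknown animals error", {
  ped <- pedigree(as.character(1:2), c(0, 0), c(0, 0))
  r <- base_records(2, y = c(1, 2))
  expect_warning(build_design(r, ped, factors = "cg", trait = "y"),
                 "single level")
  r$animal <- c("1", "99")
  expect_error(suppressWarnings(build_design(r, ped, factors = "cg",
                                             trait = "y")),
               "absent from pedigree")
})

test_that("record files round-trip with missing values preserved", {
  st <- small_study()
  r <- st$records
  r$weight[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(r, path)
  r2 <- read_records(path)
  expect_equal(r2$weight, r$weight)
  expect_equal(as.character(r2$animal), as.character(r$animal))
  expect_equal(r2$score, r$score)
})
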