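# Numerator relationship matrix, inbreeding and the sparse inverse.

test_that("sorting preserves valid orders, repairs invalid ones, detects cycles", {
  ped <- pedigree_table(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
  expect_identical(sort_pedigree(ped)$animal, c("s", "d", "x"))

  shuffled <- pedigree_table(c("x", "s", "d"), c("s", NA, NA), c("d", NA, NA))
  sorted <- sort_pedigree(shuffled)
  expect_lt(which(sorted$animal == "s"), which(sorted$animal == "x"))
  expect_lt(which(sorted$animal == "d"), which(sorted$animal == "x"))

  cyc <- pedigree_table(c("A", "B"), c("B", "A"), c(NA, NA))
  expect_error(sort_pedigree(cyc), "cycle")
})

test_that("tabular A reproduces textbook closed forms", {
  founders <- pedigree_table(c("a", "b", "c"), rep(NA, 3), rep(NA, 3))
  expect_equal(unname(build_A(founders)$A), diag(3))

  # sire + dam unrelated, offspring, two full sibs, paternal half sib
  ped <- pedigree_table(c("s", "d", "d2", "o1", "o2", "o3"),
                        c(NA, NA, NA, "s", "s", "s"),
                        c(NA, NA, NA, "d", "d", "d2"))
  A <- build_A(ped)$A
  expect_equal(A["s", "o1"], 0.5)       # parent-offspring
  expect_equal(A["o1", "o1"], 1.0)      # non-inbred diagonal
  expect_equal(A["o1", "o2"], 0.5)      # full sibs
  expect_equal(A["o1", "o3"], 0.25)     # paternal half sibs

  # offspring of two full sibs: F = 0.25
  fs <- pedigree_table(c("f1", "f2", "s1", "s2", "x"),
                       c(NA, NA, "f1", "f1", "s1"),
                       c(NA, NA, "f2", "f2", "s2"))
  Afs <- build_A(fs)
  expect_equal(Afs$A["x", "x"], 1.25)
  expect_equal(unname(Afs$F["x"]), 0.25)
})

test_that("A matches the gene-dropping oracle on a random pedigree", {
  ped <- random_pedigree(40, n_founders = 8, seed = 4)
  A <- build_A(ped)$A
  gd <- genedrop_relationship(ped, nrep = 30000L, seed = 7)
  tol <- 3 * gd$se[gd$ids, gd$ids] + 1e-12
  expect_true(all(abs(A[gd$ids, gd$ids] - gd$A[gd$ids, gd$ids]) <= tol))
})

test_that("Henderson's inverse matches A and the Meuwissen-Luo F matches the diagonal", {
  ped <- random_pedigree(150, n_founders = 20, seed = 11)
  A <- build_A(ped)
  ai <- build_A_inverse(ped)
  prod <- as.matrix(ai$Ainv %*% A$A[ai$ids, ai$ids])
  expect_lt(max(abs(prod - diag(nrow(prod)))), 1e-8)
  expect_equal(ai$F[ai$ids], A$F[ai$ids], tolerance = 1e-12)
  expect_equal(unname(ai$log_det_A),
               unname(determinant(A$A)$modulus[1]), tolerance = 1e-8)
})

test_that("A is positive semi-definite and unaffected by adding an unrelated founder", {
  ped <- random_pedigree(80, n_founders = 12, seed = 3)
  A1 <- build_A(ped)
  expect_gt(min(eigen(A1$A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  plus <- pedigree_table(c(ped$animal, "new_founder"),
                         c(ped$sire, NA), c(ped$dam, NA))
  A2 <- build_A(plus)
  ids <- A1$ids
  expect_equal(A2$A[ids, ids], A1$A[ids, ids])
  expect_equal(unname(A2$A["new_founder", "new_founder"]), 1)
  expect_true(all(A2$A["new_founder", ids] == 0))
})

test_that("A-inverse nonzeros connect only animals, their parents and mates", {
  # two unrelated families -> no cross-family fill-in
  ped <- pedigree_table(c("s1", "d1", "o1", "s2", "d2", "o2"),
                        c(NA, NA, "s1", NA, NA, "s2"),
                        c(NA, NA, "d1", NA, NA, "d2"))
  ai <- build_A_inverse(ped)
  M <- as.matrix(ai$Ainv)
  expect_equal(M["s1", "s2"], 0)
  expect_equal(M["s1", "o2"], 0)
  expect_equal(M["o1", "o2"], 0)
  # mates are connected, parent-offspring are connected
  expect_true(M["s1", "d1"] != 0)
  expect_true(M["s1", "o1"] != 0)
})

test_that("pedigree TSV and coordinate writers round-trip", {
  ped <- random_pedigree(25, n_founders = 6, seed = 2)
  tf <- tempfile(fileext = ".tsv")
  write_pedigree(ped, tf)
  expect_identical(read_pedigree(tf), ped)

  A <- build_A(ped)
  cf <- tempfile(fileext = ".coo")
  write_relationship_coo(A, cf)
  coo <- utils::read.table(cf, header = TRUE)
  idmap <- utils::read.table(paste0(cf, ".ids"), header = TRUE,
                             colClasses = c("integer", "character"))
  rebuilt <- matrix(0, 25, 25, dimnames = list(idmap$id, idmap$id))
  rebuilt[cbind(coo$i, coo$j)] <- coo$value
  rebuilt[cbind(coo$j, coo$i)] <- coo$value
  expect_equal(rebuilt, A$A, tolerance = 1e-12)
})
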