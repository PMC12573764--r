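# Excitation-space enumeration and spin-flip task expansion.

test_that("window below the gap yields the ground pattern only and growth is monotone", {
  eps <- c(-1.0, -0.5, 0.3, 0.8)
  s0 <- enumerate_space(eps, 2, hartree_to_ev(0.5))
  expect_equal(nrow(s0), 1)
  expect_identical(s0$type, "ground")
  sizes <- vapply(c(5, 15, 25, 40, 80), function(d)
    nrow(enumerate_space(eps, 2, d)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(enumerate_space(eps, 2, 10, window = list(occ = integer(0))),
               "empty occupied")
})

test_that("enumeration matches a brute-force oracle on a six-orbital spectrum", {
  eps <- c(-1.2, -0.9, -0.4, 0.2, 0.5, 1.1)
  no <- 3
  de_ev <- 40
  de <- ev_to_hartree(de_ev)
  sp <- enumerate_space(eps, no, de_ev)
  # exhaustive oracle over all index tuples
  pats <- character(0)
  for (i in 1:no) for (a in (no + 1):6) {
    if (eps[a] - eps[i] <= de) pats <- c(pats, paste("single", i, a))
  }
  for (i in 1:no) for (a in (no + 1):6) for (j in i:no) for (b in a:6) {
    sen <- if (i == j && a == b) 0 else if (xor(i == j, a == b)) 2 else NA
    if (is.na(sen)) next
    gap <- eps[a] + eps[b] - eps[i] - eps[j]
    if (gap <= de) pats <- c(pats, paste("double", i, j, a, b))
  }
  sing <- sp[sp$type == "single", , drop = FALSE]
  dbl <- sp[sp$type == "double", , drop = FALSE]
  got <- c(paste("single", sing$i, sing$a),
           if (nrow(dbl)) paste("double", dbl$i, dbl$j, dbl$a, dbl$b))
  expect_setequal(got, pats)
  # gaps nondecreasing after the ground pattern; no duplicates
  gaps <- sp$gap_ev[sp$type != "ground"]
  expect_true(all(diff(gaps) >= -1e-12))
  expect_false(any(duplicated(sp[c("type", "i", "j", "a", "b")])))
})

test_that("four-orbital reference space expands to 14 or 16 tasks", {
  sp <- polyene_space(10)
  expect_equal(nrow(sp), 10)  # ground + 4 singles + 3 sen-0 + 2 sen-2
  coox <- expand_with_spin_flips(sp, "coox")
  imom <- expand_with_spin_flips(sp, "imom")
  expect_equal(nrow(coox), 14)
  expect_equal(nrow(imom), 16)
  # composition: ground 1, singles 4x2, seniority-0 3x1, seniority-2 2x{1,2}
  expect_equal(sum(coox$type == "ground"), 1)
  expect_equal(sum(coox$type == "single"), 8)
  expect_equal(sum(coox$type == "double" & coox$seniority == 0), 3)
  expect_equal(sum(coox$type == "double" & coox$seniority == 2), 2)
  expect_equal(sum(imom$type == "double" & imom$seniority == 2), 4)
})

test_that("an empty excitation space expands to the single ground task", {
  eps <- c(-1, 1)
  sp <- enumerate_space(eps, 1, 1)  # gap far above 1 eV
  tasks <- expand_with_spin_flips(sp, "coox")
  expect_equal(nrow(tasks), 1)
  expect_identical(tasks$type, "ground")
})

test_that("cumulative space growth with the window is superlinear on a dense spectrum", {
  set.seed(4)
  eps <- sort(c(-runif(8, 0.2, 1.2), runif(8, 0.2, 1.2)))
  thresholds <- c(20, 30, 40, 55)
  counts <- vapply(thresholds, function(d)
    nrow(enumerate_space(eps, 8, d)), numeric(1))
  # superlinear: growth ratio increases faster than the threshold ratio
  expect_gt((counts[4] - counts[3]) / (thresholds[4] - thresholds[3]),
            (counts[2] - counts[1]) / (thresholds[2] - thresholds[1]))
})
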