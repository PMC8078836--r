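# Frozen hand-oracle values for the tiny fixture (4 diseases x 6
# metabolites), computed by element-wise evaluation of the similarity
# definitions with pencil-and-paper-checkable inputs.
fixtureMHS <- matrix(c(
  1.00, 0.50, 0.25, 0.25, 0.50, 0.50,
  0.50, 1.00, 0.75, 0.25, 0.00, 0.50,
  0.25, 0.75, 1.00, 0.50, 0.25, 0.75,
  0.25, 0.25, 0.50, 1.00, 0.75, 0.25,
  0.50, 0.00, 0.25, 0.75, 1.00, 0.50,
  0.50, 0.50, 0.75, 0.25, 0.50, 1.00), 6, 6, byrow = TRUE)

fixtureDNF <- matrix(c(
  1.0000000, 0.4170246, 0.0000000, 0,
  0.4170246, 1.0000000, 0.4170246, 0,
  0.0000000, 0.4170246, 1.0000000, 0,
  0.0000000, 0.0000000, 0.0000000, 1), 4, 4, byrow = TRUE)

fixtureDGS <- matrix(c(
  1.0000000, 0.2635971, 0.1083680, 0.1083680,
  0.2635971, 1.0000000, 0.1690133, 0.4111123,
  0.1083680, 0.1690133, 1.0000000, 0.4111123,
  0.1083680, 0.4111123, 0.4111123, 1.0000000), 4, 4, byrow = TRUE)

test_that("tiny-fixture similarity matrices match the frozen hand oracle", {
  ds <- tinyFixture()
  expect_equal(unname(simValues(metaboliteHammingSimilarity(ds$pathways))),
               fixtureMHS, tolerance = 1e-9)
  expect_equal(unname(simValues(diseaseNmiSimilarity(ds$symptoms,
                                                     diseaseIds(ds$assoc)))),
               fixtureDNF, tolerance = 1e-7)
  expect_equal(unname(simValues(gipSimilarity(ds$assoc, "disease"))),
               fixtureDGS, tolerance = 1e-7)
})

test_that("Hamming similarity follows the mismatch-fraction definition", {
  ids <- list(paste0("p", 1:4), c("a", "b"))
  mp <- PathwayMembership(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2,
                                 dimnames = ids))
  expect_equal(simValues(metaboliteHammingSimilarity(mp))["a", "b"], 0.5)

  same <- PathwayMembership(matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 4, 2,
                                   dimnames = ids))
  expect_equal(simValues(metaboliteHammingSimilarity(same))["a", "b"], 1)
  alldiff <- PathwayMembership(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2,
                                      dimnames = ids))
  expect_equal(simValues(metaboliteHammingSimilarity(alldiff))["a", "b"], 0)
  nopw <- PathwayMembership(matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  expect_error(metaboliteHammingSimilarity(nopw), "zero pathways")
})

test_that("Hamming similarity matches a bit-wise oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    np <- sample(1:20, 1); nm <- sample(2:20, 1)
    MP <- matrix(rbinom(np * nm, 1, 0.4), np, nm,
                 dimnames = list(paste0("p", 1:np), paste0("m", 1:nm)))
    got <- simValues(metaboliteHammingSimilarity(PathwayMembership(MP)))
    expect_equal(unname(got), oracleHamming(MP), tolerance = 1e-12)
  }
})

test_that("symptom entropy uses global-frequency masses", {
  one <- SymptomCatalog(list(d1 = c(s1 = 4)))
  expect_equal(symptomEntropy("d1", one), -1 * log2(1) * 1)  # p = 1 -> 0
  expect_equal(symptomEntropy("d1", one), 0)

  sc <- SymptomCatalog(list(d1 = c(s1 = 1), d2 = c(s2 = 3)))
  expect_equal(symptomEntropy("d1", sc), -(1 / 4) * log2(1 / 4))  # 0.5
  expect_equal(symptomEntropy("d1", sc), 0.5)

  set.seed(7)
  cat <- list(d1 = c(s1 = 2, s2 = 5, s3 = 1), d2 = c(s2 = 3, s4 = 4))
  scr <- SymptomCatalog(cat)
  for (d in c("d1", "d2"))
    expect_equal(symptomEntropy(d, scr), oracleEntropy(cat[[d]], 15))
})

test_that("symptom NMI similarity handles identical, disjoint and toy sets", {
  ids <- c("a", "b", "c")
  cat <- list(a = c(s1 = 2, s2 = 1), b = c(s1 = 2, s2 = 1), c = c(s3 = 5))
  sc <- SymptomCatalog(cat)
  dnf <- simValues(diseaseNmiSimilarity(sc, ids))
  expect_equal(dnf["a", "b"], 1)        # identical nonempty sets
  expect_equal(dnf["a", "c"], 0)        # disjoint sets
  expect_equal(unname(dnf), oracleNmi(cat, 10), tolerance = 1e-12)

  # 3-disease toy with partial overlap vs element-wise oracle, both rules
  cat2 <- list(a = c(s1 = 3, s2 = 2), b = c(s2 = 4, s3 = 1), c = c(s1 = 1, s3 = 2))
  sc2 <- SymptomCatalog(cat2)
  for (rule in c("min", "sum"))
    expect_equal(unname(simValues(diseaseNmiSimilarity(sc2, ids, rule))),
                 oracleNmi(cat2, 13, rule), tolerance = 1e-12)
})

test_that("GIP bandwidth is the raw bandwidth over the mean squared norm", {
  ones <- diag(4)                       # every profile has one 1
  expect_equal(gipBandwidth(ones)@omega, 1)
  two <- rbind(c(1, 1, 0, 0), c(1, 1, 1, 1))   # squared norms 2 and 4
  expect_equal(gipBandwidth(two)@omega, 1 / 3)
  set.seed(3)
  r <- matrix(rbinom(40, 1, 0.5), 5, 8)
  r[1, ] <- 1                           # guard against all-zero
  expect_equal(gipBandwidth(r, 2)@omega, 2 / mean(rowSums(r^2)))
  expect_error(gipBandwidth(matrix(0, 2, 3)), "all interaction profiles")
})

test_that("GIP kernel similarity matches the Gaussian profile kernel", {
  m <- AssociationMatrix(matrix(c(1, 0, 1, 0, 1, 0), 2, 3,
                                dimnames = list(c("d1", "d2"),
                                                c("m1", "m2", "m3"))))
  g <- simValues(gipSimilarity(m, "disease"))
  expect_equal(g["d1", "d1"], 1)
  # identical profiles give exactly 1
  m2 <- AssociationMatrix(matrix(c(1, 1, 0, 0), 2, 2,
                                 dimnames = list(c("d1", "d2"), c("m1", "m2"))))
  expect_equal(simValues(gipSimilarity(m2, "disease"))["d1", "d2"], 1)

  # profiles differing in one position at omega = 1 give exp(-1)
  prof <- matrix(c(1, 1, 1, 0), 2, 2,
                 dimnames = list(c("d1", "d2"), c("m1", "m2")))
  # mean squared norm = (2 + 1) / 2 = 1.5 -> use omega_prime = 1.5 so omega = 1
  got <- simValues(gipSimilarity(AssociationMatrix(prof), "disease",
                                 omega_prime = 1.5))
  expect_equal(got["d1", "d2"], exp(-1), tolerance = 1e-12)

  set.seed(9)
  M5 <- matrix(rbinom(25, 1, 0.4), 5, 5,
               dimnames = list(paste0("d", 1:5), paste0("m", 1:5)))
  M5[2, ] <- c(1, 0, 1, 0, 1)
  for (axis in c("disease", "metabolite")) {
    prof5 <- if (axis == "disease") M5 else t(M5)
    expect_equal(unname(simValues(gipSimilarity(AssociationMatrix(M5), axis))),
                 oracleGip(prof5), tolerance = 1e-12)
  }
})

test_that("integration keeps nonzero primary entries and falls back elsewhere", {
  lab <- paste0("d", 1:3)
  pv <- matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 0), 3, 3, dimnames = list(lab, lab))
  fv <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3, 3,
               dimnames = list(lab, lab))
  p <- SimilarityMatrix(pv, "disease", "nmi")
  f <- SimilarityMatrix(fv, "disease", "gip")
  out <- simValues(integrateSimilarity(p, f))
  expect_equal(unname(out), unname(ifelse(pv != 0, pv, fv)))
  # all-nonzero primary passes through; all-zero primary yields the fallback
  expect_equal(simValues(integrateSimilarity(f, p)), fv)
  z <- SimilarityMatrix(matrix(0, 3, 3, dimnames = list(lab, lab)),
                        "disease", "nmi")
  expect_equal(simValues(integrateSimilarity(z, f)), fv)
  # axis mismatch is refused
  fm <- SimilarityMatrix(fv, "metabolite", "gip")
  expect_error(integrateSimilarity(p, fm), "different axes")
})

test_that("all six similarity matrices are symmetric, bounded and unit-diagonal", {
  gen <- smallPlanted()
  ds <- gen$dataset
  mhs <- metaboliteHammingSimilarity(ds$pathways)
  dnf <- diseaseNmiSimilarity(ds$symptoms, diseaseIds(ds$assoc))
  dgs <- gipSimilarity(ds$assoc, "disease")
  mgs <- gipSimilarity(ds$assoc, "metabolite")
  ids <- integrateSimilarity(dnf, dgs)
  ims <- integrateSimilarity(mhs, mgs)
  for (s in list(mhs, dnf, dgs, mgs, ids, ims)) {
    v <- simValues(s)
    expect_lte(max(abs(v - t(v))), 1e-12)
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
  }
  expect_equal(unname(diag(simValues(mhs))), rep(1, ncol(assocMatrix(ds$assoc))))
  expect_equal(unname(diag(simValues(dgs))), rep(1, nrow(assocMatrix(ds$assoc))))
})

test_that("permuting metabolites permutes the GIP kernel identically", {
  gen <- smallPlanted(seed = 4)
  M <- assocMatrix(gen$dataset$assoc)
  set.seed(1)
  perm <- sample(ncol(M))
  K1 <- simValues(gipSimilarity(AssociationMatrix(M), "metabolite"))
  K2 <- simValues(gipSimilarity(AssociationMatrix(M[, perm]), "metabolite"))
  expect_equal(unname(K2), unname(K1[perm, perm]), tolerance = 1e-12)
})

test_that("integrating an integrated matrix changes no nonzero entry", {
  gen <- smallPlanted(seed = 5)
  ds <- gen$dataset
  dnf <- diseaseNmiSimilarity(ds$symptoms, diseaseIds(ds$assoc))
  dgs <- gipSimilarity(ds$assoc, "disease")
  ids <- integrateSimilarity(dnf, dgs)
  again <- integrateSimilarity(ids, dnf)
  nz <- simValues(ids) != 0
  expect_equal(simValues(again)[nz], simValues(ids)[nz])
})
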