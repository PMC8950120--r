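test_that("switching function hits its exact reference points", {
  expect_equal(switching_function(0, 3.5), 1.0)
  expect_equal(switching_function(3.5, 3.5), 0.75)     # n/m limit at x = 1
  expect_equal(switching_function(7.0, 3.5), 63 / 255, tolerance = 1e-12)
  # continuity across the removable singularity
  eps <- 1e-9
  expect_equal(switching_function(3.5 * (1 + eps), 3.5), 0.75, tolerance = 1e-6)
  expect_error(switching_function(1, -1), "d0")
  expect_error(switching_function(-1, 1), ">= 0")
})

test_that("switching function is strictly decreasing and bounded", {
  r <- seq(0.01, 20, by = 0.01)
  v <- switching_function(r, 3.5)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
})

test_that("coordination number reproduces saturated and d0 limits", {
  # 16 pairs: N at origin-ish, O at controlled distances
  n <- 16
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(name = c("N", "O"), resname = "GLY", resno = c(i, 100 + i),
               chain = "A", x = c(0, 0.35), y = 100 * i + c(0, 0), z = 0,
               element = c("N", "O"), stringsAsFactors = FALSE)
  }))
  at$serial <- seq_len(nrow(at))
  s <- mol_structure(at)
  pl <- atom_pairs(seq_len(n), 100 + seq_len(n), "N", "O", d0 = 3.5, label = "test")
  v <- coordination_number(s, pl)
  expect_gt(min(v$per_pair$s), 0.999)          # r = 0.1 d0: saturated
  expect_equal(v$value, sum(v$per_pair$s), tolerance = 1e-12)

  at2 <- at; at2$x[at2$name == "O"] <- 3.5     # exactly at d0
  s2 <- mol_structure(at2)
  expect_equal(coordination_number(s2, pl)$value, 0.75 * n, tolerance = 1e-9)

  bad <- atom_pairs(999, 1, "N", "O")
  expect_error(coordination_number(s, bad), "not found")
})

test_that("a brute-force double loop reproduces coordination numbers", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 50
    at <- data.frame(serial = 1:n, name = "CA", resname = "GLY", resno = 1:n,
                     chain = "A", x = runif(n, 0, 20), y = runif(n, 0, 20),
                     z = runif(n, 0, 20), element = "C", stringsAsFactors = FALSE)
    s <- mol_structure(at)
    i <- sample(1:n, 20); j <- sample(1:n, 20)
    ok <- i != j
    pl <- atom_pairs(i[ok], j[ok], "CA", "CA", d0 = 3.5)
    v <- coordination_number(s, pl)
    brute <- 0
    for (k in which(ok)) {
      d <- sqrt(sum((c(at$x[i[k]], at$y[i[k]], at$z[i[k]]) -
                     c(at$x[j[k]], at$y[j[k]], at$z[j[k]]))^2))
      x <- d / 3.5
      brute <- brute + (1 - x^6) / (1 - x^8)
    }
    expect_equal(v$value, brute, tolerance = 1e-10)
  }
})

test_that("scaling coordinates up never increases a CV; pair order is irrelevant", {
  set.seed(11)
  n <- 30
  at <- data.frame(serial = 1:n, name = "CA", resname = "GLY", resno = 1:n,
                   chain = "A", x = runif(n, 0, 15), y = runif(n, 0, 15),
                   z = runif(n, 0, 15), element = "C", stringsAsFactors = FALSE)
  s <- mol_structure(at)
  pl <- atom_pairs(1:15, 16:30, "CA", "CA", d0 = 3.5)
  v0 <- coordination_number(s, pl)$value
  for (fac in c(1.1, 1.5, 3)) {
    s2 <- s
    s2$atoms$x <- at$x * fac; s2$atoms$y <- at$y * fac; s2$atoms$z <- at$z * fac
    expect_lte(coordination_number(s2, pl)$value, v0 + 1e-12)
  }
  perm <- sample(1:15)
  plp <- atom_pairs((1:15)[perm], (16:30)[perm], "CA", "CA", d0 = 3.5)
  expect_equal(coordination_number(s, plp)$value, v0, tolerance = 1e-12)
})

test_that("frataxin pair lists carry the published row counts for every variant", {
  pls <- fxn_pairlists("WT")
  expect_equal(nrow(pls[["beta_1-4"]]$pairs), 18)
  expect_equal(nrow(pls[["alpha_1"]]$pairs), 19)
  expect_equal(nrow(pls[["alpha_2"]]$pairs), 8)
  expect_equal(pls[["beta_1-4"]]$d0, 3.5)
  # backbone selectors are mutation-invariant
  for (v in c("D104G", "A107V", "F109L", "Y123S", "S161I", "W173C", "S181F", "S202F"))
    expect_identical(fxn_pairlists(v)[["beta_1-4"]]$pairs, pls[["beta_1-4"]]$pairs)
  expect_error(fxn_pairlists("Q999X"), "unknown variant")
})

test_that("salt-bridge score handles empty, single-pair and mixed cases", {
  # no charged groups at all
  plain <- mol_structure(data.frame(serial = 1:2, name = c("CA", "CB"),
                                    resname = "ALA", resno = c(5, 5), chain = "A",
                                    x = c(0, 1), y = 0, z = 0, element = "C",
                                    stringsAsFactors = FALSE))
  expect_equal(salt_bridge_score(plain, include_termini = FALSE)$value, 0)

  # one Asp CG exactly 4 A from one Lys NZ
  pair <- mol_structure(data.frame(serial = 1:2, name = c("CG", "NZ"),
                                   resname = c("ASP", "LYS"), resno = c(1, 2),
                                   chain = "A", x = c(0, 4), y = 0, z = 0,
                                   element = c("C", "N"), stringsAsFactors = FALSE))
  expect_equal(salt_bridge_score(pair, include_termini = FALSE)$value, 0.75,
               tolerance = 1e-12)

  # both Arg NH atoms pair with every acidic centre
  at <- data.frame(serial = 1:3, name = c("CG", "NH1", "NH2"),
                   resname = c("ASP", "ARG", "ARG"), resno = c(1, 2, 2),
                   chain = "A", x = c(0, 4, 40), y = 0, z = 0,
                   element = c("C", "N", "N"), stringsAsFactors = FALSE)
  v <- salt_bridge_score(mol_structure(at), include_termini = FALSE)
  expect_equal(nrow(v$per_pair), 2)
  expect_equal(v$value, 0.75 + switching_function(40, 4), tolerance = 1e-12)
})
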