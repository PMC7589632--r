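test_that("orientation reproduces the hand-worked 3-point case", {
  m <- fod_structure(data.frame(chain = "A", seq_id = 1:3, ins = "",
                                aa = "GLY", x = c(-5, 5, 0), y = c(0, 0, 1),
                                z = c(0, 0, 0)))
  o <- orient_structure(m)
  r <- o$model$residues
  # center (0, 1/3, 0) removed; longest pair on X with residue 1 positive
  expect_equal(r$x, c(5, -5, 0), tolerance = 1e-9)
  expect_equal(r$y, c(1 / 3, 1 / 3, -2 / 3), tolerance = 1e-9)
  expect_equal(r$z, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(o$sigma[1], 5 / 3, tolerance = 1e-9)
  expect_equal(o$sigma[2], 2 / 9, tolerance = 1e-9)
  # flat point set: sigma_z collapses, T must refuse it
  expect_equal(o$sigma[3], 0)
  expect_error(theoretical_profile(o), "sigma")
  # original untouched
  expect_equal(m$residues$x, c(-5, 5, 0))

  same <- fod_structure(data.frame(chain = "A", seq_id = 1:4, ins = "",
                                   aa = "GLY", x = 1, y = 2, z = 3))
  expect_error(orient_structure(same), "degenerate")
})

test_that("a centro-symmetric point set keeps its center at the origin", {
  xyz <- rbind(c(4, 1, -2), c(-4, -1, 2), c(1, -3, 2), c(-1, 3, -2))
  m <- fod_structure(data.frame(chain = "A", seq_id = 1:4, ins = "",
                                aa = "ALA", x = xyz[, 1], y = xyz[, 2],
                                z = xyz[, 3]))
  o <- orient_structure(m)
  ctr <- colMeans(as.matrix(o$model$residues[, c("x", "y", "z")]))
  expect_equal(unname(ctr), c(0, 0, 0), tolerance = 1e-9)
})

test_that("sigma and the T profile are invariant under rigid motion", {
  for (seed in 1:6) {
    cl <- generate_cloud(synthetic_spec(30, "uniform", seed = seed))
    moved <- apply_rigid_motion(cl, seed = seed + 100)
    o1 <- orient_structure(cl); o2 <- orient_structure(moved)
    expect_equal(o1$sigma, o2$sigma, tolerance = 1e-9)
    expect_equal(theoretical_profile(o1), theoretical_profile(o2),
                 tolerance = 1e-9)
  }
})

test_that("T is a normalized Gaussian with the expected shape", {
  # residue at the center dominates
  m <- fod_structure(data.frame(chain = "A", seq_id = 1:5, ins = "",
                                aa = "ALA",
                                x = c(0, 9, -9, 0, 0), y = c(0, 1, -1, 7, -7),
                                z = c(0, 1, -1, 2, -2)))
  o <- orient_structure(m)
  Tv <- theoretical_profile(o)
  expect_equal(sum(Tv), 1, tolerance = 1e-12)
  expect_equal(which.max(Tv), 1)
  # mirror-symmetric pairs get equal density
  expect_equal(Tv[2], Tv[3], tolerance = 1e-9)
  expect_equal(Tv[4], Tv[5], tolerance = 1e-9)

  # scalar hand evaluation: 5 points, sigma (3,3,3), frozen literals
  m2 <- fod_structure(data.frame(chain = "A", seq_id = 1:5, ins = "",
                                 aa = "ALA",
                                 x = c(0, 3, 0, 0, 1), y = c(0, 0, 3, 0, 2),
                                 z = c(0, 0, 0, 3, 2)))
  fake <- structure(list(model = m2, sigma = c(3, 3, 3)),
                    class = "fod_oriented")
  expect_equal(theoretical_profile(fake),
               c(0.2918751327405783, 0.17703121681485542, 0.17703121681485542,
                 0.17703121681485542, 0.17703121681485542),
               tolerance = 1e-12)
})

test_that("the contact weight has its closed-form endpoints", {
  expect_equal(pair_weight(0), 1)
  expect_equal(pair_weight(9), 0)
  expect_equal(pair_weight(9.0001), 0)
  expect_equal(pair_weight(12, cutoff = 12), 0)
  # halfway value from scalar arithmetic: s = 1/2
  expect_equal(pair_weight(4.5),
               1 - 0.5 * (7 / 4 - 9 / 16 + 5 / 64 - 1 / 256),
               tolerance = 1e-12)
})

test_that("O matches the brute-force double loop on small random fixtures", {
  for (seed in 1:6) {
    n <- sample(4:20, 1)
    m <- random_cloud_structure(n, seed)
    sc <- default_scale()
    o_pkg <- observed_profile(m, scale = sc)
    o_ref <- brute_force_observed(as.matrix(m$residues[, c("x", "y", "z")]),
                                  unname(sc[m$residues$aa]))
    expect_equal(o_pkg, o_ref, tolerance = 1e-10)
    expect_equal(sum(o_pkg), 1, tolerance = 1e-12)
  }
})

test_that("O is rigid-motion invariant and fails cleanly with no contacts", {
  cl <- generate_cloud(synthetic_spec(25, "micelle", seed = 9))
  expect_equal(observed_profile(apply_rigid_motion(cl, 5)),
               observed_profile(cl), tolerance = 1e-10)
  # three residues pairwise farther than the cutoff: nothing to collect
  iso <- fod_structure(data.frame(chain = "A", seq_id = 1:3, ins = "",
                                  aa = "ILE", x = c(0, 9.1, 30),
                                  y = c(0, 0, 20), z = 0))
  expect_error(observed_profile(iso), "cannot be normalized")
})

test_that("KL divergence has its closed-form values and matches the oracle", {
  expect_equal(kl_divergence(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "undefined")
  expect_error(kl_divergence(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
  for (seed in 1:8) {
    set.seed(seed)
    p <- runif(10); p <- p / sum(p)
    q <- runif(10); q <- q / sum(q)
    expect_equal(kl_divergence(p, q), brute_force_kl(p, q),
                 tolerance = 1e-12)
  }
})

test_that("RD hits its limit cases and stays in [0, 1]", {
  Tv <- c(0.5, 0.3, 0.1, 0.1)
  expect_equal(relative_distance(profiles_from(Tv, Tv))$rd, 0)
  r1 <- relative_distance(profiles_from(Tv, rep(0.25, 4)))
  expect_equal(r1$rd, 1)          # O = R, non-uniform T
  expect_equal(r1$dkl_or, 0)
  for (seed in 1:10) {
    set.seed(seed)
    O <- runif(12); O <- O / sum(O)
    Tq <- runif(12) + 0.05; Tq <- Tq / sum(Tq)
    rd <- relative_distance(profiles_from(Tq, O))$rd
    expect_gte(rd, 0); expect_lte(rd, 1)
  }
  # O = T = R exactly: both divergences zero, RD undefined but flagged
  r2 <- relative_distance(profiles_from(rep(0.25, 4), rep(0.25, 4)))
  expect_true(is.na(r2$rd))
})

test_that("fragment rescoring renormalizes inside the fixed parent field", {
  cl <- generate_cloud(synthetic_spec(40, "micelle", seed = 21))
  pr <- hydro_profiles(cl)
  whole <- fragment_rd(pr, "1-40", mode = "select")
  expect_equal(whole$rd, relative_distance(pr)$rd, tolerance = 1e-12)
  expect_error(fragment_rd(pr, "200-300", mode = "select"),
               "no residues")
  expect_error(fragment_rd(pr, "1-40", mode = "eliminate"), "empties")
  # eliminating a range that hits nothing changes nothing
  none <- fragment_rd(pr, "200-300", mode = "eliminate")
  expect_equal(none$rd, relative_distance(pr)$rd, tolerance = 1e-12)

  # the Gaussian-concentrated half scores better than its complement:
  # split residues by theoretical density
  ord <- order(pr$T, decreasing = TRUE)
  core_ids <- sort(pr$seq_id[ord[1:20]])
  rim_ids <- sort(pr$seq_id[ord[21:40]])
  as_ranges <- function(ids) paste(ids, collapse = ",")
  rd_core <- fragment_rd(pr, as_ranges(core_ids), mode = "select")$rd
  rd_rim <- fragment_rd(pr, as_ranges(rim_ids), mode = "select")$rd
  expect_lt(rd_core, rd_rim)

  # elimination keeps n bookkeeping consistent
  el <- eliminate_and_rescore(pr, "1-5")
  expect_equal(el$n, 35)
})

test_that("range parsing accepts the published fragment notation", {
  expect_equal(unname(parse_ranges("35,53,55-58")[, 1]), c(35, 53, 55))
  expect_equal(unname(parse_ranges("35,53,55-58")[, 2]), c(35, 53, 58))
  expect_equal(unname(parse_ranges(list(c(12, 33), c(38, 48)))[2, ]),
               c(lo = 38, hi = 48), ignore_attr = TRUE)
  expect_error(parse_ranges("58-55"), "lo <= hi")
  expect_error(parse_ranges("abc"), "cannot parse")
})

test_that("T-O correlation has its closed-form cases", {
  Tv <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(to_correlation(profiles_from(Tv, Tv)), 1)
  neg <- 0.5 - 0.8 * Tv; neg <- neg / sum(neg)
  expect_equal(to_correlation(profiles_from(Tv, neg)), -1)
  expect_warning(r <- to_correlation(profiles_from(rep(0.25, 4), Tv)),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("moving hydrophobicity outward never decreases RD", {
  sc <- default_scale()
  for (seed in 1:8) {
    cl <- generate_cloud(synthetic_spec(40, "micelle", seed = seed))
    rd0 <- relative_distance(hydro_profiles(cl, scale = sc))$rd
    h <- unname(sc[cl$residues$aa])
    dens <- hydro_profiles(cl, scale = sc)$T
    # most hydrophobic residue at the Gaussian center vs least hydrophobic
    # on the surface (ties resolved toward the density extremes)
    hi <- order(-h, -dens)[1]
    lo <- order(h, dens)[1]
    swapped <- cl
    swapped$residues$aa[c(hi, lo)] <- cl$residues$aa[c(lo, hi)]
    rd1 <- relative_distance(hydro_profiles(swapped, scale = sc))$rd
    expect_gte(rd1, rd0 - 1e-12)
  }
})
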