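test_that("the default conformational path satisfies its zone invariants", {
  path <- default_ellipse_path()
  expect_s3_class(path, "ellipse_path")
  expect_equal(names(path$anchors), LETTERS[1:7])
  # canonical secondary-structure points land in their zones
  pr <- project_to_ellipse(c(-57, -120, 57), c(-47, 130, 47), path)
  expect_equal(assign_code(pr$t, path), c("C", "E", "G"))
  # the canonical points lie on the path itself
  expect_equal(pr$phi_e, c(-57, -120, 57), tolerance = 1e-4)
  expect_equal(pr$psi_e, c(-47, 130, 47), tolerance = 1e-4)
  # D sits between the helix and beta anchors along the path, F between
  # beta and the left-handed helix (circular arc-length betweenness)
  arcs <- sapply(path$anchors, function(t) oildrop:::arc_at(path, t))
  arc_dist <- function(a, b) {
    d <- abs(arcs[[a]] - arcs[[b]])
    min(d, path$arc_total - d)
  }
  expect_equal(arc_dist("C", "D") + arc_dist("D", "E"), arc_dist("C", "E"),
               tolerance = 1e-6)
  expect_equal(arc_dist("E", "F") + arc_dist("F", "G"), arc_dist("E", "G"),
               tolerance = 1e-6)
})

test_that("ellipse paths round-trip through their JSON representation", {
  path <- default_ellipse_path()
  f <- tempfile(fileext = ".json")
  write_ellipse_path(path, f)
  back <- read_ellipse_path(f)
  expect_equal(back$semi_axes, path$semi_axes, tolerance = 1e-12)
  expect_equal(back$anchors, path$anchors, tolerance = 1e-12)
  expect_error(ellipse_path(c(0, 0), c(-1, 10), 0,
                            setNames(1:7 * 10, LETTERS[1:7])), "positive")
})

test_that("projection returns on-path points at minimal torus distance", {
  path <- default_ellipse_path()
  set.seed(5)
  phi <- runif(25, -180, 180); psi <- runif(25, -180, 180)
  pr <- project_to_ellipse(phi, psi, path)
  # every projected point satisfies the ellipse equation
  th <- path$tilt * pi / 180
  u <- cos(th) * pr$phi_e + sin(th) * pr$psi_e
  v <- -sin(th) * pr$phi_e + cos(th) * pr$psi_e
  expect_equal((u / path$semi_axes[1])^2 + (v / path$semi_axes[2])^2,
               rep(1, 25), tolerance = 1e-6)
  # no sampled path point is closer than the returned projection
  dense <- ellipse_point(path, seq(0, 360, by = 0.05))
  for (i in 1:25) {
    dproj <- sqrt(min(oildrop:::torus_dist2(phi[i], psi[i],
                                            cbind(pr$phi_e[i], pr$psi_e[i]))))
    dmin <- sqrt(min(oildrop:::torus_dist2(phi[i], psi[i], dense)))
    expect_lte(dproj, dmin + 1e-6)
  }
  # idempotence
  pr2 <- project_to_ellipse(pr$phi_e, pr$psi_e, path)
  expect_equal(pr2$phi_e, pr$phi_e, tolerance = 1e-6)
  expect_equal(pr2$psi_e, pr$psi_e, tolerance = 1e-6)
})

test_that("projection honors periodicity and the circle closed form", {
  circle <- ellipse_path(c(0, 0), c(60, 60), 0,
                         setNames(seq(0, 360, length.out = 8)[1:7],
                                  LETTERS[1:7]))
  pr <- project_to_ellipse(10, 0, circle)
  expect_equal(c(pr$phi_e, pr$psi_e), c(60, 0), tolerance = 1e-6)
  # the center is equidistant from everything: smallest parameter wins
  prc <- project_to_ellipse(0, 0, circle)
  expect_equal(prc$t, 0)
  # periodicity: translating the query by 360 on either axis changes nothing
  path <- default_ellipse_path()
  set.seed(8)
  phi <- runif(10, -180, 180); psi <- runif(10, -180, 180)
  a <- project_to_ellipse(phi, psi, path)
  b <- project_to_ellipse(phi - 360, psi + 360, path)
  expect_equal(a$phi_e, b$phi_e, tolerance = 1e-9)
  expect_equal(a$psi_e, b$psi_e, tolerance = 1e-9)
  # and a near-boundary query is projected across the seam, not the long
  # way around: its torus distance never exceeds the naive in-plane one
  dense <- ellipse_point(path, seq(0, 360, by = 0.05))
  for (q in list(c(178, -170), c(-179, 150), c(170, 178))) {
    prq <- project_to_ellipse(q[1], q[2], path)
    dtorus <- sqrt(oildrop:::torus_dist2(q[1], q[2],
                                         cbind(prq$phi_e, prq$psi_e)))
    naive <- sqrt(min(rowSums(sweep(dense, 2, q)^2)))
    expect_lte(dtorus, naive + 1e-6)
  }
})

test_that("every dihedral pair receives exactly one code", {
  path <- default_ellipse_path()
  grid <- expand.grid(phi = seq(-175, 180, by = 25),
                      psi = seq(-175, 180, by = 25))
  pr <- project_to_ellipse(grid$phi, grid$psi, path)
  codes <- assign_code(pr$t, path)
  expect_false(any(is.na(codes)))
  expect_true(all(codes %in% LETTERS[1:7]))
  # anchor points map to their own labels
  anchor_codes <- assign_code(path$anchors, path)
  expect_equal(unname(anchor_codes), names(path$anchors))
})

test_that("backbone building inverts torsion measurement", {
  set.seed(31)
  for (k in 1:4) {
    n <- sample(5:15, 1)
    phi <- runif(n, -175, 175); psi <- runif(n, -175, 175)
    bb <- build_backbone(phi, psi)
    tor <- compute_torsions(bb)
    expect_equal(tor$phi[-1], phi[-1], tolerance = 1e-4)
    expect_equal(tor$psi[-n], psi[-n], tolerance = 1e-4)
    # build from the measured angles again: same dihedrals (identity)
    bb2 <- build_backbone(tor$phi, tor$psi)
    tor2 <- compute_torsions(bb2)
    expect_equal(tor2$phi[-1], phi[-1], tolerance = 1e-4)
    expect_equal(tor2$psi[-n], psi[-n], tolerance = 1e-4)
  }
  expect_error(build_backbone(c(-57, NaN, -57), rep(-47, 3)), "non-finite")
})

test_that("ideal-geometry chains have the expected shapes", {
  helix <- build_backbone(rep(-57, 30), rep(-47, 30))
  ca <- as.matrix(helix$atoms[helix$atoms$elety == "CA", c("x", "y", "z")])
  axis_proj <- prcomp(ca)$x[, 1]
  rise <- mean(abs(diff(axis_proj)))
  expect_equal(rise, 1.5, tolerance = 0.1)

  ext <- build_backbone(rep(-180, 8), rep(180, 8))
  cae <- as.matrix(ext$atoms[ext$atoms$elety == "CA", c("x", "y", "z")])
  d1 <- sqrt(sum((cae[2, ] - cae[1, ])^2))
  d2 <- sqrt(sum((cae[3, ] - cae[1, ])^2))
  expect_gt(d2, d1)
})

test_that("the early-stage pipeline is a fixed point on on-path structures", {
  helix <- generate_backbone(synthetic_spec(20, "ideal_helix", seed = 4))
  es <- make_early_stage(helix)
  inner <- 2:19
  expect_equal(es$assignment$phi_e[inner], rep(-57, 18), tolerance = 1e-4)
  expect_equal(es$assignment$psi_e[inner], rep(-47, 18), tolerance = 1e-4)
  expect_equal(unique(es$assignment$code[inner]), "C")
  expect_true(is.na(es$assignment$code[1]) && is.na(es$assignment$code[20]))
  tor_es <- compute_torsions(es$es_model)
  expect_equal(tor_es$phi[inner], rep(-57, 18), tolerance = 1e-4)
  expect_equal(tor_es$psi[inner], rep(-47, 18), tolerance = 1e-4)
})

test_that("mixed helix/strand chains get the hand-assigned code string", {
  mixed <- generate_backbone(synthetic_spec(16, "mixed_helix_strand",
                                            seed = 6))
  es <- make_early_stage(mixed)
  codes <- es$assignment$code
  # residues 2-8 sit at the helix anchor, 9-15 at the beta anchor
  expect_equal(codes[2:8], rep("C", 7))
  expect_equal(codes[9:15], rep("E", 7))
  expect_true(all(is.na(codes[c(1, 16)])))
})
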