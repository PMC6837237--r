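test_that("tube law vanishes at the relaxed area and matches the closed form", {
  geom <- list(stiffness = 1, area = 4e-6)
  expect_equal(tube_law_pressure(4e-6, geom, p_ext = 13.5), 13.5)
  # A = 4 A0, B = 1: p = sqrt(4 A0) - sqrt(A0) = sqrt(A0)
  geom <- list(stiffness = 1, area = 1e-5)
  expect_equal(tube_law_pressure(4e-5, geom), sqrt(1e-5))
  # direct evaluation of B (sqrt(A) - sqrt(A0)) at physiological-scale values
  geom <- list(stiffness = 1e7, area = 1e-5)
  expect_equal(tube_law_pressure(1.2e-5, geom), 3018.2395496937, tolerance = 1e-10)
  expect_error(tube_law_pressure(0, geom), "positive")
  expect_error(tube_law_pressure(-1e-6, geom), "positive")
})

test_that("tube law is strictly increasing in area", {
  geom <- list(stiffness = 3e7, area = 5e-6)
  A <- seq(5e-7, 2e-5, length.out = 200)
  p <- tube_law_pressure(A, geom, p_ext = 10)
  expect_true(all(diff(p) > 0))
})

test_that("wave speed obeys its scaling laws and the finite-difference oracle", {
  geom1 <- list(stiffness = 1e7, area = 1e-5)
  geom2 <- list(stiffness = 2e7, area = 1e-5)
  A <- 8e-6
  expect_equal(wave_speed(A, geom2), sqrt(2) * wave_speed(A, geom1))
  expect_equal(wave_speed(16 * A, geom1), 2 * wave_speed(A, geom1))
  # c = sqrt((A / rho) dp/dA) by central differences on the implemented law
  rho <- 1060
  for (A in c(2e-6, 5e-6, 1e-5, 1.8e-5)) {
    h <- A * 1e-6
    dpdA <- (tube_law_pressure(A + h, geom1) - tube_law_pressure(A - h, geom1)) / (2 * h)
    expect_equal(wave_speed(A, geom1, rho), sqrt(A / rho * dpdA),
                 tolerance = 1e-8)
  }
  expect_error(wave_speed(-1, geom1), "positive")
})

test_that("fixture generator respects topology, ranges and determinism", {
  net <- build_fixture_network(3, seed = 5)
  a <- net$arteries
  expect_equal(a$id, 1:3)
  expect_equal(a$parent, c(0L, 1L, 1L))
  expect_identical(build_fixture_network(3, seed = 5), net)
  expect_false(identical(build_fixture_network(3, seed = 6), net))

  net19 <- build_fixture_network(19, seed = 1)
  a <- net19$arteries
  expect_equal(nrow(a), 19)
  expect_true(all(a$length >= 0.026 & a$length <= 0.17))
  expect_true(all(a$area >= 1e-6 & a$area <= 1e-5))
  expect_true(all(a$beta == 1) && all(a$alpha == 1))
  # rooted-tree property: one root, every other artery has one parent edge
  expect_equal(sum(a$parent == 0), 1)
  expect_equal(sum(a$parent != 0), nrow(a) - 1)
  nkid <- table(a$parent[a$parent != 0])
  expect_true(all(nkid == 2))
  expect_error(build_fixture_network(4), "odd")
  expect_error(build_fixture_network(1), "odd")
})

test_that("network validation names the offending artery", {
  base <- data.frame(id = 1:3, parent = c(0, 1, 1), length = 0.1,
                     area = 5e-6, stiffness = 2e7)
  bad <- base; bad$length[2] <- -1
  expect_error(artery_network(bad), "artery 2")
  bad <- base; bad$parent[3] <- 9
  expect_error(artery_network(bad), "parent 9")
  bad <- rbind(base, data.frame(id = 4, parent = 1, length = 0.1,
                                area = 5e-6, stiffness = 2e7))
  expect_error(artery_network(bad), "exactly 2")
  bad <- base; bad$parent <- c(0, 1, 3)  # one child only + self-loop child
  expect_error(artery_network(bad), "children|cycle")
  expect_error(artery_network(base[base$id != 1, ]), "inlet")
})

test_that("defects multiply reference values and invert exactly", {
  net <- desk_net()
  expect_identical(apply_defect(net, NULL), net)
  same <- apply_defect(net, defect_spec(6, "stiffness", 1))
  expect_equal(same$arteries, net$arteries)

  d <- apply_defect(net, defect_spec(6, "stiffness", 0.5))
  expect_equal(d$arteries$beta[d$arteries$id == 6], 0.5)
  expect_equal(d$arteries$beta[d$arteries$id != 6], rep(1, 6))
  expect_equal(d$arteries$alpha, rep(1, 7))

  d2 <- apply_defect(net, defect_spec(6, "area", 1.5))
  expect_equal(d2$arteries$alpha[d2$arteries$id == 6], 1.5)

  restored <- apply_defect(d, defect_spec(6, "stiffness", 1))
  expect_equal(restored$arteries, net$arteries)

  expect_error(apply_defect(net, defect_spec(99, "area", 2)), "99")
  expect_error(defect_spec(1, "area", -1), "positive")
})

test_that("network config files round-trip and are validated on read", {
  net <- desk_net(9, seed = 3)
  net <- apply_defect(net, defect_spec(4, "area", 1.25))
  path <- tempfile(fileext = ".yaml")
  write_network_config(net, path)
  back <- read_network_config(path)
  expect_equal(back$arteries, net$arteries, tolerance = 1e-12)
  expect_equal(back$fluid$Kr, net$fluid$Kr)

  cfg <- yaml::read_yaml(path)
  cfg$arteries[[3]]$length <- NULL
  path2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path2)
  expect_error(read_network_config(path2), "missing field 'length'")
})
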