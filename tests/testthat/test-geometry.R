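test_that("projected angles reproduce the defining special cases", {
  pa <- projected_angles(c(1, 0, 0))
  expect_equal(pa$sagittal, 0)
  expect_equal(pa$dorsal, 0)
  expect_equal(projected_angles(c(1, 0, 1))$sagittal, 45)
  expect_equal(projected_angles(c(1, 1, 0))$dorsal, 45)
  expect_equal(projected_angles(c(0, 1, 1))$transverse, 45)
  # reported pair selection
  pa <- projected_angles(c(2, 1, 1), reported = "sagittal")
  expect_identical(names(pa$reported_values), "sagittal")
  expect_error(projected_angles(c(0, 0, 0)), class = "osic_zero_vector")
  expect_warning(projected_angles(c(0, 0, 1), reported = "dorsal"),
                 class = "osic_indeterminate_angle")
})

test_that("projected angles agree with the plane-projection oracle", {
  set.seed(31)
  for (i in 1:300) {
    v <- rnorm(3, sd = 5)
    if (sqrt(sum(v^2)) < 1e-3) next
    pa <- projected_angles(v, reported = c("sagittal", "dorsal", "transverse"))
    for (plane in c("sagittal", "dorsal", "transverse")) {
      expect_equal(abs(pa[[plane]]), oracle_projected_angle(v, plane),
                   tolerance = 1e-9)
    }
  }
})

test_that("safety angle matches its closed form and the tangent oracle", {
  I <- c(0, 0, 0); E <- c(0, 0, 10); S <- c(0, 5, 5)
  expect_equal(safety_angle(I, E, S, r = 0), 45, tolerance = 1e-12)
  expect_equal(safety_angle(I, E, S, r = 0.75),
               45 - asin(0.75 / sqrt(50)) * 180 / pi, tolerance = 1e-12)
  expect_equal(safety_angle(I, E, S, r = 0.75),
               oracle_safety_angle(I, E, S, 0.75), tolerance = 1e-6)
  expect_error(safety_angle(I, E, S, r = sqrt(50)), class = "osic_tangent_undefined")
  expect_error(safety_angle(I, I, S, r = 0), class = "osic_zero_vector")
  # safety point on the axis: alpha = 0, returns -beta with a warning
  expect_warning(
    res <- suppressWarnings(safety_angle(I, E, c(0, 0, 5), r = 1),
                            classes = "osic_narrow_corridor"),
    class = "osic_collinear_safety_point")
  expect_equal(as.numeric(res), -asin(1 / 5) * 180 / pi, tolerance = 1e-12)
})

test_that("negative safety angles are returned unclamped and flagged", {
  I <- c(0, 0, 0); E <- c(0, 0, 10); S <- c(0, 0.5, 5)
  expect_warning(res <- safety_angle(I, E, S, r = 2), class = "osic_narrow_corridor")
  expect_lt(as.numeric(res), 0)
  expect_true(attr(res, "narrow"))
})

test_that("safety angle is monotone in r and reduces to the planar angle at r = 0", {
  set.seed(32)
  for (i in 1:100) {
    I <- rnorm(3, sd = 20); E <- I + rnorm(3, sd = 10); S <- I + rnorm(3, sd = 10)
    dS <- sqrt(sum((S - I)^2))
    if (sqrt(sum((E - I)^2)) < 1e-3 || dS < 0.5) next
    u <- E - I; w <- S - I
    planar <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
    expect_equal(safety_angle(I, E, S, r = 0), planar, tolerance = 1e-9)
    rs <- seq(0, 0.9 * dS, length.out = 5)
    vals <- suppressWarnings(vapply(rs, function(r) as.numeric(safety_angle(I, E, S, r)), 0))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("corridor width matches the 2D planar oracle and flags same-side pairs", {
  I <- c(0, 0, 0); E <- c(0, 0, 10)
  expect_equal(corridor_width(I, E, list(c(0, 5, 5), c(0, -5, 5))), 10)
  set.seed(33)
  for (i in 1:200) {
    I <- rnorm(3, sd = 20); E <- I + rnorm(3, sd = 10)
    if (sqrt(sum((E - I)^2)) < 1e-3) next
    S1 <- I + rnorm(3, sd = 8); S2 <- I + rnorm(3, sd = 8)
    w_oracle <- oracle_corridor_width(I, E, S1, S2)
    w <- suppressWarnings(corridor_width(I, E, list(S1, S2)))
    expect_equal(as.numeric(w), w_oracle, tolerance = 1e-9)
  }
  expect_warning(w <- corridor_width(c(0, 0, 0), c(0, 0, 10),
                                     list(c(0, 5, 5), c(0, 3, 5))),
                 class = "osic_nonflanking_width")
  expect_false(attr(w, "flanking"))
  expect_error(corridor_width(c(0, 0, 0), c(0, 0, 10),
                              list(c(0, 0, 5), c(0, 1, 5))),
               class = "osic_degenerate_width")
})

test_that("safety_angles bundles four margins, widths and length", {
  I <- c(0, 0, 0); E <- c(0, 0, 10); P <- c(0, 0, 5)
  S <- list(P + c(0, 5, 0), P - c(0, 5, 0), P + c(5, 0, 0), P - c(5, 0, 0))
  res <- safety_angles(list(insertion = I, exit = E), list(S = S, r = 0))
  expect_equal(res$saf_a1, 45, tolerance = 1e-12)
  expect_equal(unlist(res[paste0("saf_a", 1:4)], use.names = FALSE),
               rep(45, 4), tolerance = 1e-12)
  expect_equal(res$width_plane1, 10)
  expect_equal(res$width_plane2, 10)
  expect_equal(res$implant_length, 10)
  # non-orthogonal margin planes warn
  S_bad <- list(P + c(0, 5, 0), P - c(0, 5, 0),
                P + 5 * c(sin(80 * pi / 180), cos(80 * pi / 180), 0),
                P - 5 * c(sin(80 * pi / 180), cos(80 * pi / 180), 0))
  expect_warning(safety_angles(list(insertion = I, exit = E), list(S = S_bad, r = 0)),
                 class = "osic_nonorthogonal_planes")
})

test_that("all angle and width outputs are rigid-motion invariant", {
  set.seed(34)
  for (i in 1:50) {
    I <- rnorm(3, sd = 20); E <- I + rnorm(3, sd = 10)
    if (sqrt(sum((E - I)^2)) < 1) next
    S <- I + rnorm(3, sd = 8)
    if (sqrt(sum((S - I)^2)) < 1) next
    p <- rand_pose()
    tr <- function(x) rigid_transform(x, p$R, p$t)
    a0 <- suppressWarnings(as.numeric(safety_angle(I, E, S, 0.5)))
    a1 <- suppressWarnings(as.numeric(safety_angle(tr(I), tr(E), tr(S), 0.5)))
    expect_equal(a1, a0, tolerance = 1e-7)
    S2 <- I + rnorm(3, sd = 8)
    if (sqrt(sum((S2 - I)^2)) < 1) next
    w0 <- suppressWarnings(as.numeric(corridor_width(I, E, list(S, S2))))
    w1 <- suppressWarnings(as.numeric(corridor_width(tr(I), tr(E), list(tr(S), tr(S2)))))
    expect_equal(w1, w0, tolerance = 1e-7)
  }
})

test_that("prescribed projected angles are recovered exactly (round trip)", {
  set.seed(35)
  for (i in 1:200) {
    sag <- runif(1, -88, 88); dor <- runif(1, -88, 88)
    v <- direction_from_angles(sag, dor)
    pa <- projected_angles(v)
    expect_equal(pa$sagittal, sag, tolerance = 1e-9)
    expect_equal(pa$dorsal, dor, tolerance = 1e-9)
  }
  expect_error(direction_from_angles(90, 0), class = "osic_spec_error")
})
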