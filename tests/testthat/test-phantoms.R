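test_that("tube phantom places disjoint disks at the requested concentrations", {
  conc <- c(1e-8, 1e-7, 1e-6, 1e-5)
  ph <- make_tube_phantom(conc)
  masks <- ph$masks[paste0("tube_", 1:4)]
  for (i in 1:4) {
    # map is exactly constant at the configured value on the labeled mask
    expect_equal(range(ph$maps$BphP1[masks[[i]]]), rep(conc[i], 2))
  }
  # pairwise disjoint tubes, background disjoint from tubes
  overlap <- Reduce(`+`, lapply(masks, `*`, 1))
  expect_lte(max(overlap), 1)
  expect_false(any(ph$masks$background & (overlap > 0)))
  expect_true(all(ph$maps$HbO2 == 0) && all(ph$maps$HbR == 0))
})

test_that("tube phantom edge cases: empty list, determinism, geometry errors", {
  ph0 <- make_tube_phantom(numeric(0))
  expect_true(all(ph0$maps$BphP1 == 0))
  expect_length(grep("^tube_", names(ph0$masks)), 0)
  a <- make_tube_phantom(c(1e-7, 1e-6), seed = 42)
  b <- make_tube_phantom(c(1e-7, 1e-6), seed = 42)
  expect_identical(a, b)
  expect_error(make_tube_phantom(rep(1e-6, 30), tube_radius_mm = 2),
               "overlap")
  expect_error(make_tube_phantom(-1e-7), "must be in")
  expect_error(make_tube_phantom(1e-6, placement_radius_mm = 20), "fit")
})

test_that("cross-section phantom respects organ levels and vessel config", {
  ph <- make_crosssection_phantom(organ_levels = c(liver = 1e-7), seed = 3)
  # probe support confined to the liver (within the 1-px anti-aliased rim)
  dilate1 <- function(m) {
    ny <- nrow(m); nx <- ncol(m); out <- m
    out[-1, ] <- out[-1, ] | m[-ny, ]; out[-ny, ] <- out[-ny, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -nx]; out[, -nx] <- out[, -nx] | m[, -1]
    out
  }
  expect_true(all(ph$maps$BphP1[!dilate1(dilate1(ph$masks$liver))] == 0))
  expect_true(all(ph$maps$BphP1[ph$masks$liver] == 1e-7))
  # vessels carry 80%-oxygenated 2.3 mM blood
  v <- ph$masks$vessel
  expect_true(any(v))
  expect_equal(max(abs(ph$maps$HbO2[v] - 0.8 * 2.3e-3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ph$maps$HbR[v] - 0.2 * 2.3e-3)), 0, tolerance = 1e-12)
  # no vessels -> no hemoglobin anywhere
  ph0 <- make_crosssection_phantom(organ_levels = c(liver = 1e-7),
                                   n_vessels = 0, seed = 3)
  expect_true(all(ph0$maps$HbO2 == 0) && all(ph0$maps$HbR == 0))
  # level ordering is preserved in the map means
  ph2 <- make_crosssection_phantom(
    organ_levels = c(liver = 1e-7, spleen = 5e-8, stomach = 3e-8), seed = 3)
  m <- vapply(c("liver", "spleen", "stomach"),
              function(o) mean(ph2$maps$BphP1[ph2$masks[[o]]]), numeric(1))
  expect_true(m["liver"] > m["spleen"] && m["spleen"] > m["stomach"])
  expect_error(make_crosssection_phantom(organ_levels = c(liver = -1)), ">= 0")
  expect_error(make_crosssection_phantom(organ_levels = c(kidney = 1e-7)),
               "unknown organ")
})

test_that("organ masks are pairwise disjoint and inside the body", {
  ph <- make_crosssection_phantom(
    organ_levels = c(liver = 1e-7, spleen = 1e-7, stomach = 1e-7,
                     intestine = 1e-7), seed = 5)
  organs <- ph$masks[c("liver", "spleen", "stomach", "intestine")]
  total <- Reduce(`+`, lapply(organs, `*`, 1))
  expect_lte(max(total), 1)
  for (m in organs) expect_true(all(ph$masks$body[m]))
  expect_false(any(ph$masks$background & ph$masks$body))
})

test_that("embryo phantom places the requested embryos at valid depths", {
  ph <- make_embryo_phantom(n_embryos = 7, depth_range_mm = c(1, 7), seed = 2)
  emb <- ph$masks[paste0("embryo_", 1:7)]
  expect_length(emb, 7)
  total <- Reduce(`+`, lapply(emb, `*`, 1))
  expect_lte(max(total), 1)
  # centroid depth below the upper body boundary in the same column
  for (m in emb) {
    ij <- which(m, arr.ind = TRUE)
    crow <- mean(ij[, 1]); ccol <- round(mean(ij[, 2]))
    body_rows <- which(ph$masks$body[, ccol])
    depth_mm <- (crow - min(body_rows)) * ph$grid$pixel_mm
    expect_gte(depth_mm, 1 - 0.3)
    expect_lte(depth_mm, 7 + 0.3)
    expect_equal(range(ph$maps$BphP1[m]), rep(5e-7, 2))
  }
  # maternal blood only outside embryos
  expect_true(all(ph$maps$HbO2[total > 0] == 0))
  a <- make_embryo_phantom(n_embryos = 3, seed = 9)
  b <- make_embryo_phantom(n_embryos = 3, seed = 9)
  expect_identical(a, b)
  ph0 <- make_embryo_phantom(n_embryos = 0, seed = 2)
  expect_true(all(ph0$maps$BphP1 == 0))
  expect_error(make_embryo_phantom(n_embryos = 60, seed = 2,
                                   max_tries = 200), "place")
})

test_that("total probe mass matches area x concentration to discretisation", {
  ph <- make_tube_phantom(c(2e-6), tube_radius_mm = 1.5,
                          placement_radius_mm = 0)
  pa <- ph$grid$pixel_mm^2
  mass <- sum(ph$maps$BphP1) * pa
  analytic <- pi * 1.5^2 * 2e-6
  expect_lt(abs(mass - analytic) / analytic, 0.005)
})

test_that("sinusoidal motion shifts maps rigidly and is identity at amplitude 0", {
  ph <- make_tube_phantom(1e-6, tube_radius_mm = 1.5, placement_radius_mm = 0)
  expect_identical(apply_motion(ph, 0, 1, 0.3), ph)
  # sin(pi) = 0: no displacement at half period
  ph_half <- apply_motion(ph, 0.5, 2, 1)
  expect_images_equal(ph_half$maps$BphP1, ph$maps$BphP1, tol = 1e-9)
  # quarter period: displacement equals the amplitude exactly
  moved <- apply_motion(ph, 0.3, 4, 1)
  cen <- function(m) mean(which(m, arr.ind = TRUE)[, 1])
  shift_mm <- (cen(moved$masks$tube_1) - cen(ph$masks$tube_1)) * ph$grid$pixel_mm
  expect_equal(shift_mm, 0.3, tolerance = 1e-9)
})
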