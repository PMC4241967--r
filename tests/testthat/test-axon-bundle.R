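test_that("node counting follows the internodal-distance rule", {
  geom <- bundle_geometry()
  expect_equal(nodes_per_axon(2, geom), 17.5)            # 3500/(100*2)
  expect_equal(nodes_per_axon(11, geom), 3500 / 1100)
  expect_equal(nodes_per_axon(35, geom), 1)              # one internode
  expect_error(nodes_per_axon(0, geom), "positive")
  # strictly decreasing in diameter
  d <- c(1, 2, 5, 8, 11)
  expect_true(all(diff(nodes_per_axon(d, geom)) < 0))
})

test_that("node and membrane areas are open-cylinder lateral surfaces", {
  expect_equal(round(node_surface_area(2), 2), 12.57)
  expect_equal(round(node_surface_area(5), 2), 31.42)
  expect_equal(round(node_surface_area(11), 2), 69.12)
  expect_true(all(diff(node_surface_area(c(2, 5, 8, 11))) > 0))
  expect_equal(unmyelinated_membrane_area(3, 3.5), pi * 3 * 3500)
  expect_equal(signif(unmyelinated_membrane_area(3, 3.5), 2), 33000)
  expect_error(node_surface_area(-1), "positive")
  expect_error(unmyelinated_membrane_area(0), "positive")
})

test_that("channel counts reproduce the reference bundle table", {
  bundle <- cst_bundle()
  chans <- channel_biophysics()
  my <- channel_count_myelinated(bundle, chans)
  # per-class totals as published (x 1e10): 125, 23.1, 6.2, 6.6
  expect_equal(signif(my$per_class[["2"]] / 1e10, 3), 125)
  expect_equal(signif(my$per_class[["5"]] / 1e10, 3), 23.1)
  expect_equal(signif(my$per_class[["8"]] / 1e10, 2), 6.2)
  expect_equal(signif(my$per_class[["11"]] / 1e10, 2), 6.6)
  expect_equal(signif(my$total, 3), 1.61e12)
  expect_equal(my$total, sum(my$per_class))   # conservation
  un <- channel_count_unmyelinated(bundle, chans)
  expect_equal(signif(un$total, 3), 1.98e12)
})

test_that("channel counts are linear in axon count and channel density", {
  geom <- bundle_geometry()
  b1 <- one_class_bundle(5, 1000, myelinated = TRUE, geom)
  b2 <- one_class_bundle(5, 2000, myelinated = TRUE, geom)
  ch <- channel_biophysics()
  ch2 <- channel_biophysics(rho_node = 2e4)
  expect_equal(channel_count_myelinated(b2, ch)$total,
               2 * channel_count_myelinated(b1, ch)$total)
  expect_equal(channel_count_myelinated(b1, ch2)$total,
               2 * channel_count_myelinated(b1, ch)$total)
  # unmyelinated-only bundle has zero myelinated total, not an error
  expect_equal(channel_count_myelinated(one_class_bundle(), ch)$total, 0)
  un <- channel_count_unmyelinated(
    one_class_bundle(3, 1), channel_biophysics(rho_unmyelinated = 200))
  expect_equal(un$total, pi * 3 * 3500 * 200)   # 6.6e6 for one axon
  expect_equal(
    channel_count_unmyelinated(one_class_bundle(3, 3e5),
                               channel_biophysics(rho_unmyelinated = 0))$total,
    0)
})

test_that("square-lattice packing recovers the sample-volume side", {
  side <- sample_volume_side(cst_bundle())
  expect_gt(side, 3.45)
  expect_lt(side, 3.55)
  # single axon with no interaxonal space: side = d * sqrt(pi) / 2
  b <- one_class_bundle(1000, 1, geometry = bundle_geometry(
    interaxonal_space_fraction = 0))
  expect_equal(sample_volume_side(b), 1 * sqrt(pi) / 2)
})

test_that("resident water mass uses cube volume, density and water fraction", {
  expect_equal(water_mass_in_volume(3.5, 0.9, 1), 3.5^3 * 0.9 * 1e-3)
  expect_equal(signif(water_mass_in_volume(3.5, 0.9, 1), 2), 0.039)
  expect_equal(water_mass_in_volume(3.5, 0), 0)
  expect_error(water_mass_in_volume(-1), "positive")
  expect_error(water_mass_in_volume(3.5, 1.5), "water_fraction")
})

test_that("bundle validation and file round-trip work", {
  expect_error(axon_bundle(data.frame(diameter_um = -1, count = 1,
                                      myelinated = TRUE)), "positive")
  expect_error(
    axon_bundle(data.frame(diameter_um = c(2, 3), count = c(1, 1),
                           myelinated = c(TRUE, FALSE),
                           fraction = c(0.6, 0.3))),
    "sum to 1")
  expect_error(bundle_geometry(interaxonal_space_fraction = 1), "\\[0, 1\\)")
  tmp <- tempfile(fileext = ".tsv")
  tab <- data.frame(diameter_um = c(2, 3), count = c(100, 50),
                    myelinated = c(TRUE, FALSE))
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  b <- read_bundle(tmp)
  expect_s3_class(b, "axon_bundle")
  expect_equal(b$classes$count, c(100, 50))
  # tabular mirror has one row per class and consistent channel totals
  bt <- bundle_table(cst_bundle())
  expect_equal(nrow(bt), 5)
  expect_equal(sum(bt$channels_1e10[bt$myelinated]) * 1e10,
               channel_count_myelinated(cst_bundle())$total)
})
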