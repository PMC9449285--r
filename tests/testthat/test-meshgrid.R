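# Grid-square codec: extents, encode/decode round trips, half-open tiling,
# nesting, adjacency.

test_that("cell extents match the standard subdivision scheme", {
  expect_equal(unname(mesh_extent_arcsec("1km")), c(30, 45))
  expect_equal(unname(mesh_extent_arcsec("500m")), c(15, 22.5))
  expect_equal(unname(mesh_extent_arcsec("250m")), c(7.5, 11.25))
  expect_equal(unname(mesh_extent_arcsec("100m")), c(3, 4.5))

  code <- mesh_code(38.2682, 140.8694, "1km")
  b <- mesh_bounds(code, "1km")
  expect_equal((b$north - b$south) * 3600, 30)
  expect_equal((b$east - b$west) * 3600, 45)

  b100 <- mesh_bounds(mesh_code(38.2682, 140.8694, "100m"), "100m")
  expect_equal((b100$north - b100$south) * 3600, 3)
  expect_equal((b100$east - b100$west) * 3600, 4.5)
})

test_that("encoding a point returns the cell that contains it (brute-force scan)", {
  lat <- 38.2682; lon <- 140.8694
  code <- mesh_code(lat, lon, "1km")
  expect_equal(nchar(code), 8L)
  # scan all candidate 1 km cells in a 1-degree window; exactly one contains
  # the point under the half-open convention, and it is the returned code
  cand_r <- floor((lat - 0.5) * 120):floor((lat + 0.5) * 120)
  cand_c <- floor((lon - 0.5) * 80):floor((lon + 0.5) * 80)
  grid <- expand.grid(r = cand_r, c = cand_c)
  codes <- stepscape:::.mesh_from_indices(grid$r, grid$c, "1km")
  b <- mesh_bounds(codes, "1km")
  contains <- b$south <= lat & lat < b$north & b$west <= lon & lon < b$east
  expect_equal(sum(contains), 1L)
  expect_equal(codes[contains], code)
})

test_that("round trips and nesting hold on random cells", {
  set.seed(101)
  lat <- runif(1000, 24, 45.5)
  lon <- runif(1000, 123, 149)
  for (level in mesh_levels()) {
    code <- mesh_code(lat, lon, level)
    ctr <- mesh_centroid(code, level)
    # centroid's own code equals the input code
    expect_equal(mesh_code(ctr$lat, ctr$lon, level), code)
    b <- mesh_bounds(code, level)
    expect_true(all(b$south <= lat & lat < b$north))
    expect_true(all(b$west <= lon & lon < b$east))
    expect_true(all(b$south <= ctr$lat & ctr$lat < b$north))
    # south-west corner encodes into its own cell (half-open boundary)
    expect_equal(mesh_code(b$south, b$west, level), code)
  }
  # nesting: the coarser code is a prefix of the finer code at halving
  # levels, and the 100 m code extends its 1 km parent
  c1 <- mesh_code(lat, lon, "1km")
  expect_equal(substr(mesh_code(lat, lon, "500m"), 1, 8), c1)
  expect_equal(substr(mesh_code(lat, lon, "250m"), 1, 9), mesh_code(lat, lon, "500m"))
  expect_equal(substr(mesh_code(lat, lon, "100m"), 1, 8), c1)
  # containment of the finer bounds in the coarser
  b250 <- mesh_bounds(mesh_code(lat, lon, "250m"), "250m")
  b1 <- mesh_bounds(c1, "1km")
  expect_true(all(b250$south >= b1$south & b250$north <= b1$north))
  expect_true(all(b250$west >= b1$west & b250$east <= b1$east))
})

test_that("centroid of a 100 m cell sits at the cell midpoint", {
  code <- mesh_code(38.26, 140.87, "100m")
  b <- mesh_bounds(code, "100m")
  ctr <- mesh_centroid(code, "100m")
  expect_equal(ctr$lat, (b$south + b$north) / 2)
  expect_equal(ctr$lon, (b$west + b$east) / 2)
})

test_that("queen neighborhood has 8 cells, is symmetric, and matches the geometric oracle", {
  set.seed(202)
  lat <- runif(100, 24, 45.5)
  lon <- runif(100, 123, 149)
  codes <- mesh_code(lat, lon, "250m")
  ext <- mesh_extent_arcsec("250m") / 3600
  for (code in codes) {
    nb <- mesh_neighbors(code)
    expect_length(nb, 8L)
    expect_false(code %in% nb)
    # symmetry
    for (b in nb) expect_true(code %in% mesh_neighbors(b))
    # geometric oracle: neighbors are exactly the distinct cells whose
    # bounds touch the cell's bounds (share an edge or corner)
    b0 <- mesh_bounds(code, "250m")
    cand <- expand.grid(dlat = c(-1.5, -0.5, 0.5, 1.5) * ext[["lat"]],
                        dlon = c(-1.5, -0.5, 0.5, 1.5) * ext[["lon"]])
    cand_codes <- unique(mesh_code(b0$south + ext[["lat"]] / 2 + cand$dlat,
                                   b0$west + ext[["lon"]] / 2 + cand$dlon, "250m"))
    bb <- mesh_bounds(cand_codes, "250m")
    touch <- bb$south <= b0$north & bb$north >= b0$south &
      bb$west <= b0$east & bb$east >= b0$west & cand_codes != code
    expect_setequal(nb, cand_codes[touch])
  }
})

test_that("co-residence is Chebyshev distance at most 2", {
  base <- mesh_code(38.26, 140.87, "250m")
  nb <- mesh_neighbors(base)
  expect_true(mesh_coresident(base))
  expect_true(mesh_coresident(c(base, nb[1])))
  expect_true(mesh_coresident(c(base, nb)))
  # two cells two columns apart share an adjacent cell
  idx <- stepscape:::.mesh_indices(base, "250m")
  two_over <- stepscape:::.mesh_from_indices(idx$row, idx$col + 2L, "250m")
  three_over <- stepscape:::.mesh_from_indices(idx$row, idx$col + 3L, "250m")
  expect_true(mesh_coresident(c(base, two_over)))
  expect_false(mesh_coresident(c(base, three_over)))
  # enumeration oracle: no shared neighbor between cells 3 columns apart
  expect_length(intersect(mesh_neighbors(base), mesh_neighbors(three_over)), 0L)
  # rook mode is stricter than queen on a diagonal pair at distance (2,2)
  diag2 <- stepscape:::.mesh_from_indices(idx$row + 2L, idx$col + 2L, "250m")
  expect_true(mesh_coresident(c(base, diag2), adjacency = "queen"))
  expect_false(mesh_coresident(c(base, diag2), adjacency = "rook"))
})

test_that("half-open tiling assigns every point exactly one cell per level", {
  set.seed(303)
  lat <- runif(500, 24, 45.5)
  lon <- runif(500, 123, 149)
  for (level in c("250m", "100m")) {
    code <- mesh_code(lat, lon, level)
    b <- mesh_bounds(code, level)
    expect_true(all(b$south <= lat & lat < b$north & b$west <= lon & lon < b$east))
    # shifting the point across the north edge changes the cell
    shifted <- mesh_code(b$north, lon, level)
    expect_true(all(shifted != code))
  }
})

test_that("malformed codes and out-of-domain coordinates are rejected", {
  expect_error(mesh_code(10, 140, "1km"), class = "stepscape_domain_error")
  expect_error(mesh_code(38, 160, "1km"), class = "stepscape_domain_error")
  expect_error(mesh_bounds("57403", "1km"), class = "stepscape_parse_error")
  expect_error(mesh_bounds("5740362905", "250m"), class = "stepscape_parse_error")
  expect_error(mesh_neighbors("57403629", level = "1km"),
               class = "stepscape_level_error")
})
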