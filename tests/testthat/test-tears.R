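# Tear insertion is exercised on the default-resolution meniscal mesh
# (60 circumferential x 12 radial x 2 vertical).

tear_mesh <- function() cached("tear_mesh_MM",
                               mesh_meniscus(default_geometry(), "MM",
                                             mesh_resolution(60, 12, 2, 4)))

test_that("tear specifications carry the standard sizes", {
  expect_equal(tear_spec("longitudinal", stability = "stable")$length_mm, 7)
  expect_equal(tear_spec("longitudinal", stability = "unstable")$length_mm, 14)
  expect_equal(tear_spec("radial", stability = "stable")$extent_fraction, 1 / 6)
  expect_equal(tear_spec("radial", stability = "unstable")$extent_fraction, 1 / 2)
  expect_error(tear_spec("longitudinal", length_mm = 0), "empty tear path")
  expect_error(tear_spec("radial", extent_fraction = 0), "empty tear path")
})

test_that("located tear surfaces snap to the mesh within one element", {
  m <- tear_mesh()
  s7 <- locate_tear_surface(m, tear_spec("longitudinal", "MM", "middle", "stable"))
  expect_lt(abs(s7$achieved_length_mm - 7), s7$edge_length_mm)
  s14 <- locate_tear_surface(m, tear_spec("longitudinal", "MM", "middle", "unstable"))
  expect_lt(abs(s14$achieved_length_mm - 14), s14$edge_length_mm)
  r <- locate_tear_surface(m, tear_spec("radial", "MM", "posterior", "stable"))
  expect_lt(abs(r$achieved_extent_fraction - 1 / 6), 1 / 12 + 1e-12)
  expect_equal(r$achieved_extent_fraction, 2 / 12)
  ## resolution gates
  coarse <- mesh_meniscus(default_geometry(), "MM", mesh_resolution(12, 6, 2, 4))
  expect_error(locate_tear_surface(coarse,
                                   tear_spec("longitudinal", "MM", "middle", "stable")),
               "resolution too coarse")
  coarse6 <- mesh_meniscus(default_geometry(), "MM", mesh_resolution(60, 6, 2, 4))
  expect_error(locate_tear_surface(coarse6,
                                   tear_spec("radial", "MM", "middle", "stable")),
               "resolution too coarse")
  expect_error(locate_tear_surface(m, tear_spec("longitudinal", "LM", "middle", "stable")),
               "meniscus")
})

test_that("splitting duplicates interior nodes and preserves elements", {
  m <- tear_mesh()
  nv <- m$resolution$vertical
  for (spec in list(tear_spec("longitudinal", "MM", "middle", "stable"),
                    tear_spec("longitudinal", "MM", "posterior", "unstable"),
                    tear_spec("radial", "MM", "anterior", "stable"),
                    tear_spec("radial", "MM", "middle", "unstable"))) {
    ti <- insert_tear(m, spec)
    topo <- ti$topology
    surf <- ti$surface
    ## counting oracle from the structured grid
    expected_dup <- if (spec$tear_type == "longitudinal") {
      k <- diff(surf$i_range)
      (k - 1) * (nv + 1)            # interior columns, full thickness
    } else {
      surf$layers * (nv + 1)        # inner rim through the apex column
    }
    expect_equal(nrow(topo$node_pairs), expected_dup)
    expect_equal(nrow(ti$mesh$tets), nrow(m$tets))
    expect_equal(nrow(ti$mesh$nodes), nrow(m$nodes) + expected_dup)
    ## faces coincident in the unloaded state
    np <- topo$node_pairs
    expect_equal(max(abs(ti$mesh$nodes[np[, 1], ] - ti$mesh$nodes[np[, 2], ])), 0)
    ## volume conserved
    expect_equal(mesh_volume(ti$mesh), mesh_volume(m), tolerance = 1e-12)
    ## valid mesh
    expect_gt(min(tet_volumes(ti$mesh$nodes, ti$mesh$tets)), 0)
    ## round trip reproduces the original connectivity exactly
    back <- merge_tear(ti$mesh, topo)
    expect_identical(back$tets, m$tets)
    expect_identical(back$nodes, m$nodes)
  }
})

test_that("a torn meniscus stays a single connected component", {
  m <- tear_mesh()
  ti <- insert_tear(m, tear_spec("longitudinal", "MM", "middle", "unstable"))
  tets <- ti$mesh$tets
  ## union-find over shared nodes
  parent <- seq_len(nrow(ti$mesh$nodes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(tets))) {
    r <- find(tets[e, 1])
    for (v in 2:4) { r2 <- find(tets[e, v]); if (r2 != r) parent[r2] <- r }
  }
  roots <- unique(vapply(unique(as.integer(tets)), find, integer(1)))
  expect_length(roots, 1)
})

test_that("tear faces become boundary facet sets with matched areas", {
  m <- tear_mesh()
  ti <- insert_tear(m, tear_spec("radial", "MM", "posterior", "unstable"))
  fneg <- ti$mesh$facets$tear_face_neg
  fpos <- ti$mesh$facets$tear_face_pos
  expect_gt(nrow(fneg), 0)
  expect_equal(nrow(fneg), nrow(fpos))
  an <- sum(kneefem:::facet_areas_normals(ti$mesh$nodes, fneg)$area)
  ap <- sum(kneefem:::facet_areas_normals(ti$mesh$nodes, fpos)$area)
  expect_equal(an, ap, tolerance = 1e-12)
  ## self-contact pair excludes the shared front nodes
  cp <- tear_contact_pairs(ti$topology, ti$mesh)
  expect_false(any(ti$topology$front_nodes %in% cp$follower_nodes))
})

test_that("a torn model under zero load stays at the intact zero state", {
  km <- knee_model(resolution = mesh_resolution(30, 12, 2, 6, 2),
                   loadcase = load_case(0, 0),
                   tear = tear_spec("longitudinal", "MM", "middle", "stable"),
                   resolution_other = mesh_resolution(12, 6, 2, 6, 2))
  sol <- suppressWarnings(fe_solve(km, max_iter = 10))
  expect_lt(max(abs(sol$u)), 1e-9)
  expect_true(all(vapply(sol$springs, function(s) s$force == 0, logical(1))))
})
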