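make_small_net <- function() {
  nodes <- data.frame(id = 1:4, x = c(0, 50, 90, 90), y = c(0, 0, 30, -30),
                      z = c(0, 0, 10, 10))
  seg <- function(id, a, b, mid = NULL) {
    pts <- rbind(as.numeric(nodes[a, 2:4]),
                 if (!is.null(mid)) mid,
                 as.numeric(nodes[b, 2:4]))
    list(id = id, nodes = c(a, b), points = pts,
         radii = seq(4, 6, length.out = nrow(pts)))
  }
  network_topology(nodes, list(
    seg(1L, 1, 2, c(25, 2.5, 0)),
    seg(2L, 2, 3, c(70, 15, 5)),
    seg(3L, 2, 4)
  ), voxel_size = 2)
}

test_that("SpatialGraph files round-trip the network to 1e-3 um", {
  net <- make_small_net()
  f <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(net, f)
  back <- read_spatialgraph(f)
  expect_identical(nrow(back$nodes), nrow(net$nodes))
  expect_length(back$segments, length(net$segments))
  for (i in seq_along(net$segments)) {
    expect_equal(back$segments[[i]]$points, net$segments[[i]]$points,
                 tolerance = 1e-3)
    expect_equal(back$segments[[i]]$radii, net$segments[[i]]$radii,
                 tolerance = 1e-3)
    expect_equal(back$segments[[i]]$nodes,
                 as.numeric(net$segments[[i]]$nodes))
  }
})

test_that("SpatialGraph bookkeeping: counts, loops, determinism", {
  nodes <- data.frame(id = 1:2, x = c(0, 80), y = 0, z = 0)
  one <- network_topology(nodes, list(
    list(id = 1L, nodes = c(1, 2),
         points = rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0)),
         radii = c(3, 3, 3))))
  f <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(one, f)
  txt <- readLines(f)
  expect_true("define VERTEX 2" %in% txt)
  expect_true("define EDGE 1" %in% txt)
  expect_true("define POINT 3" %in% txt)

  # self-loops survive the round trip
  ring <- network_topology(
    data.frame(id = 1, x = 0, y = 0, z = 0),
    list(list(id = 1L, nodes = c(1, 1),
              points = rbind(c(0, 0, 0), c(20, 10, 0), c(20, -10, 0),
                             c(0, 0, 0)),
              radii = rep(2, 4))))
  f2 <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(ring, f2)
  back <- read_spatialgraph(f2)
  expect_identical(back$segments[[1]]$nodes[1], back$segments[[1]]$nodes[2])

  # byte-identical output for identical input
  f3 <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(make_small_net(), f3)
  f4 <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(make_small_net(), f4)
  expect_identical(readBin(f3, "raw", file.size(f3)),
                   readBin(f4, "raw", file.size(f4)))
})

test_that("CMGUI export writes one node record per node, one element per segment", {
  net <- make_small_net()
  base <- file.path(withr::local_tempdir(), "net")
  paths <- write_cmgui(net, base)
  exnode <- readLines(paste0(base, ".exnode"))
  exelem <- readLines(paste0(base, ".exelem"))
  expect_identical(sum(grepl("^ Node:", exnode)), 4L)
  expect_identical(sum(grepl("^ Element:", exelem)), 3L)
  # contiguous node ids from 1 regardless of internal ids
  shifted <- net
  shifted$nodes$id <- shifted$nodes$id + 10
  shifted$segments <- lapply(shifted$segments, function(s) {
    s$nodes <- s$nodes + 10; s
  })
  shifted <- network_topology(shifted$nodes, shifted$segments, 2)
  base2 <- file.path(withr::local_tempdir(), "net")
  write_cmgui(shifted, base2)
  expect_identical(readLines(paste0(base2, ".exnode")), exnode)
})

test_that("JSON serialisation round-trips the graph and geometry", {
  net <- make_small_net()
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_equal(back$nodes$x, net$nodes$x)
  expect_length(back$segments, length(net$segments))
  for (i in seq_along(net$segments)) {
    expect_equal(back$segments[[i]]$points, unname(net$segments[[i]]$points))
    expect_equal(back$segments[[i]]$radii, net$segments[[i]]$radii)
  }
  # node -> segment adjacency is stored symmetrically
  doc <- jsonlite::read_json(f, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  segs_of_2 <- doc$nodes[[2]]$segs
  expect_identical(sort(unlist(segs_of_2)), c(1L, 2L, 3L))
})

test_that("attribute export writes CSV plus a per-point field", {
  net <- make_small_net()
  st <- segment_table(net)
  dia <- setNames(st$diameter, as.character(st$id))
  csv <- withr::local_tempfile(fileext = ".csv")
  am <- withr::local_tempfile(fileext = ".am")
  attribute_export(net, dia, "segment", csv, am, field_name = "diameter")
  got <- utils::read.csv(csv)
  expect_equal(got$value, unname(dia))
  txt <- readLines(am)
  expect_true(any(grepl("float diameter", txt)))
  # the @6 block holds one constant value per point of each segment
  at6 <- which(txt == "@6")
  npts <- sum(vapply(net$segments, function(s) nrow(s$points), integer(1)))
  vals <- as.numeric(txt[(at6 + 1):(at6 + npts)])
  expect_equal(vals, unlist(lapply(net$segments, function(s)
    rep(dia[as.character(s$id)], nrow(s$points)))) |> unname())

  # missing ids are an error that names them
  expect_error(attribute_export(net, dia[-2], "segment", csv), "2")

  # node attributes interpolate linearly along each segment
  bc <- setNames(c(0, 1, 2, 2), as.character(net$nodes$id))
  attribute_export(net, bc, "node", csv, am)
  txt <- readLines(am)
  at6 <- which(txt == "@6")
  vals <- as.numeric(txt[(at6 + 1):(at6 + npts)])
  expect_equal(vals[1:3], c(0, 0.5, 1))  # segment 1 has 3 points, 0 -> 1
})

test_that("ratio reports reproduce simple arithmetic", {
  total <- list(n_segments = 100L, n_nodes = 50L, mean_diameter = 10,
                mean_length = 50, total_length = 0.5, total_volume = 0.4)
  sub <- list(n_segments = 10L, n_nodes = 5L, mean_diameter = 15,
              mean_length = 100, total_length = 0.1, total_volume = 0.1)
  rep <- network_ratio_report(total, sub, organ_volume_mm3 = 4)
  expect_equal(rep$ratio_pct[rep$parameter == "segments"], 10)
  expect_equal(rep$ratio_pct[rep$parameter == "mean_diameter_um"], 150)
  expect_equal(rep$ratio_pct[rep$parameter == "organ_volume_fraction_sub"],
               2.5)
})
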