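test_that("read_tps parses landmarks, curves, metadata and applies SCALE", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=sp1"), f)
  recs <- read_tps(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$specimen_id, "sp1")
  expect_equal(recs[[1]]$landmarks$points,
               cbind(x = c(0, 1, 0), y = c(0, 0, 1)))
  expect_length(recs[[1]]$curves, 0L)

  writeLines(c("LM=0", "CURVES=1", "POINTS=4",
               "2 4", "6 4", "6 8", "2 8", "SCALE=0.5", "ID=c1"), f)
  recs <- read_tps(f)
  expect_equal(recs[[1]]$curves[[1]]$vertices[1L, ], c(x = 1, y = 2))
  expect_true(recs[[1]]$scale_applied)
  expect_equal(recs[[1]]$scale, 0.5)
})

test_that("TPS dialect: case-insensitive keys, CRLF, unknown keys, multi-record", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("lm=3\r", "0 0\r", "1 0\r", "0 1\r", "id=a",
               "COMMENT=left side", "LM=3", "0 0", "2 0", "0 2",
               "IMAGE=b.jpg", "ID=b"), f, sep = "\n")
  recs <- read_tps(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$specimen_id, "a")
  expect_equal(recs[[1]]$extra[["COMMENT"]], "left side")
  expect_equal(recs[[2]]$image_name, "b.jpg")
})

test_that("parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 zebra", "0 1", "ID=x"), f)
  expect_error(read_tps(f), "line 3")
  writeLines(c("LM=0", "CURVES=1", "POINTS=4", "0 0", "1 1"), f)
  expect_error(read_tps(f), "line")
  writeLines(c("HELLO=3"), f)
  expect_error(read_tps(f), "LM=")
})

test_that("write_tps / read_tps round-trip is the identity on records", {
  set.seed(11)
  recs <- list(
    specimen_record("s1", landmarks = random_config(5L, "s1")),
    specimen_record("s2", image_name = "img2.jpg",
                    curves = list(unit_circle_polyline(50L)),
                    extra = c(COMMENT = "note")))
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(recs, f)
  back <- read_tps(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$landmarks$points, recs[[1]]$landmarks$points,
               tolerance = 1e-9)
  expect_equal(back[[2]]$curves[[1]]$vertices,
               recs[[2]]$curves[[1]]$vertices, tolerance = 1e-9)
  expect_equal(back[[2]]$extra[["COMMENT"]], "note")
  # second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty record list gives an empty file
  write_tps(list(), f)
  expect_length(readLines(f), 0L)
  # a 50-point outline is written as CURVES=1 / POINTS=50
  lines <- { write_tps(recs[2], f); readLines(f) }
  expect_true("CURVES=1" %in% lines && "POINTS=50" %in% lines)
})

test_that("newick serialization yields correct heights and is re-parseable", {
  expect_equal(to_newick("A"), "A;")
  tree2 <- upgma(matrix(c(0, 2, 2, 0), 2L, 2L,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(to_newick(tree2), "(A:1,B:1);")
  # labels with reserved characters get quoted
  treeq <- upgma(matrix(c(0, 2, 2, 0), 2L, 2L,
                        dimnames = rep(list(c("A b", "C(1)")), 2L)))
  expect_match(to_newick(treeq), "'A b'", fixed = TRUE)

  skip_if_not_installed("ape")
  set.seed(42)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(14), 7L)))
  dimnames(m) <- rep(list(paste0("t", 1:7)), 2L)
  tree <- upgma(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, tree$labels)
  # every root-to-leaf path equals the tree height
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(depths, rep(max(tree$heights), 7L), tolerance = 1e-9)
  # re-parsed cophenetic distances match ours
  coph_ape <- ape::cophenetic.phylo(ph)[tree$labels, tree$labels]
  expect_equal(coph_ape, cophenetic_matrix(tree), tolerance = 1e-9)
})

test_that("distance-matrix and score CSV round-trips preserve values", {
  set.seed(5)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5L)))
  dimnames(m) <- rep(list(letters[1:5]), 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(m, f)
  expect_equal(read_distance_csv(f), m, tolerance = 1e-12)
  s <- matrix(stats::rnorm(6), 3L, dimnames = list(c("x", "y", "z"), NULL))
  write_scores_csv(s, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("specimen_id", "RW1", "RW2"))
  expect_equal(df$RW1, s[, 1L], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("attach_labels joins taxonomy by specimen id and flags gaps", {
  recs <- list(specimen_record("s1", landmarks = random_config(4L)),
               specimen_record("s2", landmarks = random_config(4L)))
  lab <- data.frame(specimen_id = c("s2", "s1"),
                    genus = c("Gb", "Ga"), species = c("x", "y"),
                    status = c("fossil", "extant"))
  out <- attach_labels(recs, lab)
  expect_equal(out[[1]]$genus, "Ga")
  expect_equal(out[[2]]$status, "fossil")
  expect_error(attach_labels(recs, lab[1L, ]), "missing")
})
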